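test_that("mito parameters follow the subtraction scheme", {
  p <- mito_params(c(pre = 42, post_inj1 = 13.1, post_fccp = 89, post_raa = 8),
                   arm = "CV_INHIBITED")
  expect_equal(p$basal, 34)
  expect_equal(p$atp_linked, 28.9)
  expect_equal(p$proton_leak, 5.1)
  expect_equal(p$mr, 81)
  expect_equal(p$src, 47)
  expect_equal(p$nonmito, 8)

  flat <- mito_params(c(pre = 10, post_fccp = 10, post_raa = 10), arm = "CV_FREE")
  expect_equal(c(flat$basal, flat$mr, flat$src), c(0, 0, 0))
  expect_true(is.na(flat$atp_linked) && is.na(flat$proton_leak))

  inh <- mito_params(c(pre = 42, post_inj1 = 13.1, post_fccp = 43.64,
                       post_raa = 8), arm = "CV_INHIBITED")
  expect_equal(inh$mr, 81 * (1 - 0.56), tolerance = 1e-12)

  err <- tryCatch(mito_params(c(pre = 42, post_raa = 8), arm = "CV_FREE"),
                  condition = identity)
  expect_s3_class(err, "efastress_validation")
  expect_match(conditionMessage(err), "post_fccp")
})

test_that("parameter identities hold in exact floating point", {
  set.seed(42)
  for (i in 1:25) {
    r <- c(pre = runif(1, 10, 100), post_inj1 = runif(1, 5, 50),
           post_fccp = runif(1, 10, 150), post_raa = runif(1, 0, 15))
    p <- mito_params(r, arm = "CV_INHIBITED")
    expect_identical(p$mr - p$basal, p$src)
    expect_identical(p$basal - p$atp_linked, p$proton_leak)
  }
})

test_that("the literal SRC variant retains non-mitochondrial OCR", {
  r <- c(pre = 42, post_inj1 = 13.1, post_fccp = 89, post_raa = 8)
  expect_equal(mito_params(r, "CV_INHIBITED", src_literal = TRUE)$src, 55)
  expect_equal(mito_params(r, "CV_INHIBITED")$src, 47)
})

test_that("percent underestimation matches its definition and is scale-free", {
  expect_equal(percent_underestimation(81, 35.64), 56, tolerance = 1e-12)
  expect_equal(percent_underestimation(47, 1.645), 96.5, tolerance = 1e-3)
  expect_equal(percent_underestimation(123.4, 123.4), 0)
  expect_equal(percent_underestimation(81 * 1e3, 35.64 * 1e3), 56,
               tolerance = 1e-12)
  expect_warning(u0 <- percent_underestimation(0, 5), "undefined")
  expect_true(is.na(u0))
})

test_that("noise-free pipeline reproduces the closed-form underestimations", {
  gs <- grid_scenario(us = c(0, 0.2, 0.56, 1), ratios = c(1.5, 81 / 34, 4))
  run <- simulate_run(gs$scenario, "MITO", "exp1")
  params <- mito_params_from_runs(list(run))
  u <- paired_underestimation(params) |> dplyr::arrange(.data$dose)
  for (i in seq_len(nrow(gs$combos))) {
    u_true <- gs$combos$u[i]
    mr <- gs$combos$ratio[i] * 34
    u_mr <- dplyr::filter(u, .data$dose == i, .data$parameter == "MR")$percent
    u_src <- dplyr::filter(u, .data$dose == i, .data$parameter == "SRC")$percent
    expect_equal(u_mr, 100 * u_true, tolerance = 1e-6)
    expect_equal(u_src, 100 * u_true * mr / (mr - 34), tolerance = 1e-6)
  }
})

test_that("paired underestimation skips conditions missing an arm", {
  sc <- scenario_mito_confound(seed = 8, noise = noise_free())
  run <- simulate_run(sc, "MITO", "exp1")
  params <- mito_params_from_runs(list(run))
  u <- paired_underestimation(params)
  expect_equal(dplyr::filter(u, .data$substance == "NONE",
                             .data$parameter == "MR")$percent, 56,
               tolerance = 1e-9)
  expect_equal(dplyr::filter(u, .data$substance == "LPS",
                             .data$parameter == "MR")$percent, 0,
               tolerance = 1e-9)

  onearm <- dplyr::filter(params,
                          !(.data$substance == "LPS" & .data$arm == "CV_FREE"))
  expect_warning(u2 <- paired_underestimation(onearm), "missing one arm")
  expect_false("LPS" %in% u2$substance)
})

test_that("equal arm means give zero percent for a nonzero parameter", {
  params <- tibble::tibble(
    experiment_id = "exp1", substance = "NONE", dose = 0,
    arm = rep(c("CV_FREE", "CV_INHIBITED"), each = 2),
    mr = c(50, 54, 50, 54), src = c(20, 24, 24, 20))
  u <- paired_underestimation(params)
  expect_equal(u$percent, c(0, 0))
})
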