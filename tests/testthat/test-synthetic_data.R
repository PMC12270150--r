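test_that("simulation is deterministic given scenario seed and run labels", {
  sc <- scenario_mito_confound(seed = 11)
  r1 <- simulate_run(sc, "MITO", "exp2")
  r2 <- simulate_run(sc, "MITO", "exp2")
  expect_identical(r1$records, r2$records)
  expect_identical(r1$wells, r2$wells)
  r3 <- simulate_run(sc, "MITO", "exp3")
  expect_false(identical(r1$records$ocr, r3$records$ocr))
})

test_that("noise-free runs recover the encoded condition truth exactly", {
  sc <- scenario_mito_confound(seed = 1, noise = noise_free())
  run <- simulate_run(sc, "MITO", "exp1")
  params <- mito_params_from_runs(list(run))
  ctrl <- dplyr::filter(params, .data$substance == "NONE")
  expect_equal(unique(ctrl$mr[ctrl$arm == "CV_FREE"]), 81, tolerance = 1e-9)
  expect_equal(unique(ctrl$mr[ctrl$arm == "CV_INHIBITED"]), 81 * (1 - 0.56),
               tolerance = 1e-9)
  expect_equal(unique(ctrl$basal), 34, tolerance = 1e-9)
  expect_equal(unique(ctrl$nonmito), 8, tolerance = 1e-9)
  inh <- dplyr::filter(ctrl, .data$arm == "CV_INHIBITED")
  expect_equal(unique(inh$atp_linked), 28.9, tolerance = 1e-9)
  expect_equal(unique(inh$proton_leak), 0.15 * 34, tolerance = 1e-9)
})

test_that("scenario truths encode the printed dose-response fractions", {
  sc <- scenario_mito_confound(seed = 1, noise = noise_free())
  run <- simulate_run(sc, "MITO", "exp1")
  params <- mito_params_from_runs(list(run))
  u <- paired_underestimation(params)
  u72 <- dplyr::filter(u, .data$dose == 72, .data$parameter == "MR")
  expect_equal(u72$percent, 20, tolerance = 1e-9)
  mr72 <- dplyr::filter(params, .data$dose == 72, .data$arm == "CV_FREE")
  expect_equal(unique(mr72$mr) / 81, 0.67, tolerance = 1e-9)
  lps <- dplyr::filter(u, .data$substance == "LPS", .data$parameter == "MR")
  expect_equal(lps$percent, 0, tolerance = 1e-9)
})

test_that("post-rotenone/antimycin OCR is non-negative in expectation", {
  sc <- scenario_mito_confound(seed = 9)
  run <- blank_correct(simulate_run(sc, "MITO", "exp1"))
  samples <- run$wells$well[run$wells$role == "SAMPLE"]
  raa <- dplyr::filter(run$records, .data$phase == "post_raa",
                       .data$well %in% samples)
  expect_gt(mean(raa$ocr), 0)
  expect_true(all(by(raa$ocr, raa$well, mean) > -2 * 0.5))
})

test_that("between-experiment spread of recovered MR matches the intended scale", {
  # printed SEM/mean for the headline statistic is 7/56; with default noise
  # and 4 experiments the recovered control MR must land within a factor 3
  sc <- scenario_mito_confound(seed = 21)
  runs <- simulate_runs(sc, "MITO")
  params <- mito_params_from_runs(runs)
  em <- params |>
    dplyr::filter(.data$substance == "NONE", .data$arm == "CV_FREE") |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::summarize(mr = mean(.data$mr))
  ratio <- (sd(em$mr) / sqrt(nrow(em))) / mean(em$mr)
  expect_gt(ratio, (7 / 56) / 3)
  expect_lt(ratio, (7 / 56) * 3)
})

test_that("condition cell-count multipliers shift seeded counts", {
  ct <- condition_truth("NI", 6, "ppm", nonmito = 8, basal_mito = 30,
                        leak_fraction = 0.1, max_resp = 60,
                        underestimation_mr = 0.5, cell_multiplier = 1.5)
  sc <- sim_scenario("mult", list(ct), n_experiments = 1L, replicates = 6L,
                     noise = noise_free(), seed = 1L)
  run <- simulate_run(sc, "MITO", "exp1")
  counts <- run$wells$cell_count[run$wells$role == "SAMPLE"]
  expect_true(all(counts == 1.5 * sc$nominal_cells))
})

test_that("condition truths reject inconsistent rates", {
  expect_error(condition_truth("NI", 6, nonmito = 8, basal_mito = 50,
                               leak_fraction = 0.1, max_resp = 40,
                               underestimation_mr = 0.5),
               class = "efastress_validation")
  expect_error(condition_truth("NI", 6, nonmito = 8, basal_mito = 30,
                               leak_fraction = 1, max_resp = 40,
                               underestimation_mr = 0.5),
               class = "efastress_validation")
  expect_error(condition_truth("NI", 6, nonmito = 8, basal_mito = 30,
                               leak_fraction = 0.1, max_resp = 40,
                               underestimation_mr = 1.2),
               class = "efastress_validation")
})
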