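test_that("Tukey's fences flag values outside the interpolated quartile band", {
  expect_equal(tukey_fences(c(1, 2, 3, 100)), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(tukey_fences(c(1, 2, 3, 100)),
               fences_oracle(c(1, 2, 3, 100)))
  expect_true(all(tukey_fences(rep(5, 6))))   # IQR 0: all at the bounds
  expect_true(all(tukey_fences(c(1, 2, 1e6))))  # n < 4 guard
  # wider fences keep more
  x <- c(1, 2, 3, 4, 30)
  expect_true(sum(tukey_fences(x, 10)) >= sum(tukey_fences(x, 1.5)))
})

test_that("fences agree with the brute-force oracle on random lists", {
  set.seed(99)
  for (i in 1:200) {
    x <- sample(c(0, 1, 2, 5, 9, 50), size = sample(4:10, 1), replace = TRUE)
    expect_identical(tukey_fences(x), fences_oracle(x))
  }
})

test_that("two-level aggregation yields experiment-mean SEMs", {
  df <- tidyr::expand_grid(experiment_id = paste0("exp", 1:4),
                           well = 1:6) |>
    dplyr::mutate(substance = "NONE", dose = 0, value = 42)
  s <- summarize_experiments(df, by = c("substance", "dose"))
  expect_equal(s$mean, 42)
  expect_equal(s$sem, 0)
  expect_equal(s$n, 4L)

  df2 <- tibble::tibble(experiment_id = paste0("exp", 1:4),
                        substance = "NONE", dose = 0,
                        value = c(50, 52, 54, 56))
  s2 <- summarize_experiments(df2, by = c("substance", "dose"))
  expect_equal(s2$mean, 53)
  expect_equal(s2$sem, sd(c(50, 52, 54, 56)) / 2, tolerance = 1e-12)

  # an experiment flagged by the experimental-level fences drops n
  df3 <- tibble::tibble(experiment_id = paste0("exp", 1:4),
                        substance = "NONE", dose = 0,
                        value = c(50, 52, 54, 200))
  s3 <- summarize_experiments(df3, by = c("substance", "dose"))
  expect_equal(s3$n, 3L)
  expect_equal(s3$mean, 52)
})

test_that("aggregation ignores well ordering", {
  set.seed(3)
  df <- tidyr::expand_grid(experiment_id = paste0("exp", 1:3), well = 1:6) |>
    dplyr::mutate(substance = "NI", dose = 24,
                  value = rnorm(dplyr::n(), 50, 5))
  a <- summarize_experiments(df, by = c("substance", "dose"))
  b <- summarize_experiments(df[sample(nrow(df)), ], by = c("substance", "dose"))
  expect_equal(a, b)
})

test_that("Cohen's d matches the pooled-SD formula with its t interval", {
  a <- c(7.551, 12.449, 8.4, 11.6)  # mean 10
  b <- a - 5                        # mean 5, same SD
  cd <- cohens_d(a, b)
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  d_manual <- (mean(a) - mean(b)) / sp
  expect_equal(cd$d, d_manual, tolerance = 1e-12)
  se_manual <- sqrt(8 / 16 + d_manual^2 / 12)
  expect_equal(cd$se, se_manual, tolerance = 1e-12)
  expect_equal(cd$conf_low, d_manual - qt(0.975, 6) * se_manual,
               tolerance = 1e-12)
  expect_true(cd$conf_low <= cd$d && cd$d <= cd$conf_high)

  same <- cohens_d(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$d, 0)
  expect_true(same$conf_low <= 0 && same$conf_high >= 0)

  expect_warning(flat <- cohens_d(c(2, 2, 2), c(2, 2, 2)), "pooled SD")
  expect_true(is.na(flat$d))
})

test_that("anova suite covers omnibus, post hoc and variance checks", {
  d_same <- data.frame(g = rep(c("a", "b"), each = 3), value = rep(c(1, 2, 3), 2))
  tt <- anova_suite(d_same, "value", "g", design = "t_test")
  expect_equal(tt$p, 1, tolerance = 1e-12)

  set.seed(5)
  d3 <- data.frame(g = rep(c("ctl", "lo", "hi"), each = 4),
                   value = c(rnorm(4, 0, 1), rnorm(4, 0, 1), rnorm(4, 10, 1)))
  ow <- anova_suite(d3, "value", "g", design = "one_way", control = "ctl")
  expect_lt(ow$p[ow$test == "ONE_WAY_ANOVA"], 1e-4)
  lev <- ow[ow$test == "LEVENE", ]
  expect_true(lev$p >= 0 && lev$p <= 1)
  dun <- ow[ow$test == "DUNNETT", ]
  expect_equal(nrow(dun), 2)
  expect_lt(dun$p[grepl("hi", dun$label)], 0.01)
})

test_that("Dunnett-adjusted p-values never undercut the marginal contrast p", {
  set.seed(11)
  for (i in 1:10) {
    d <- data.frame(g = rep(c("0", "6", "24", "72"), each = 4),
                    value = rnorm(16, 50, 5))
    dt <- dunnett_test(d, "value", "g", "0")
    # unadjusted p of the same contrast in the same one-way model
    raw <- 2 * pt(-abs(dt$statistic), df = dt$df2)
    expect_true(all(dt$p + 1e-9 >= raw))
  }
})

test_that("Dunnett on an all-equal-means null is far from significance", {
  set.seed(1234)
  d <- data.frame(g = rep(as.character(c(0, 6, 12, 24, 48, 72)), each = 4),
                  value = rnorm(24, 50, 5))
  dt <- dunnett_test(d, "value", "g", "0")
  expect_gt(min(dt$p), 0.2)
})

test_that("two-way design reports both factors, interaction and Tukey cells", {
  set.seed(6)
  d <- tidyr::expand_grid(arm = c("FREE", "INH"), dose = c("0", "72"),
                          rep = 1:4) |>
    dplyr::mutate(value = rnorm(dplyr::n(), 50, 3) +
                    ifelse(arm == "FREE" & dose == "72", -20, 0))
  tw <- anova_suite(d, "value", "arm", "dose", design = "two_way")
  expect_setequal(unique(tw$test),
                  c("TWO_WAY_ANOVA", "TUKEY_HSD", "LEVENE"))
  expect_equal(sum(tw$test == "TWO_WAY_ANOVA"), 3)
  expect_equal(sum(tw$test == "TUKEY_HSD"), choose(4, 2))
  inter <- tw[tw$test == "TWO_WAY_ANOVA" & grepl(":", tw$label), ]
  expect_lt(inter$p, 0.01)
})

test_that("slope test recovers exact lines and rejects degenerate input", {
  st <- suppressWarnings(slope_test(c(0, 1, 2, 3), c(0, 2, 4, 6)))
  expect_equal(st$slope, 2, tolerance = 1e-12)
  expect_equal(st$r2, 1, tolerance = 1e-12)
  expect_error(slope_test(rep(2, 5), rnorm(5)), class = "efastress_validation")
  expect_error(slope_test(c(1, 2, 1, 2), rnorm(4)),
               class = "efastress_validation")
  set.seed(8)
  stn <- slope_test(rep(c(0, 6, 24, 72), each = 4), rnorm(16))
  expect_true(stn$p > 0 && stn$p < 1)
  expect_equal(stn$df2, 14)
})
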