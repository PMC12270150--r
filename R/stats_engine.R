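# Outlier handling, replicate aggregation and inferential statistics.
#
# Observations for all between-condition tests are per-experiment means
# (biological replicates), mirroring the "means +/- SEM of N independent
# experiments" framing; technical replicates only ever enter through their
# within-experiment mean.

#' Tukey's fences inlier mask
#'
#' A value is an inlier iff it lies in `[Q1 - k*IQR, Q3 + k*IQR]`, with
#' quartiles by linear interpolation of the order statistics. Lists shorter
#' than 4 are returned all-inlier (quartiles are too unstable to fence).
#' NAs are never inliers.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (conventional 1.5).
#' @return Logical vector, TRUE for inliers.
#' @export
tukey_fences <- function(values, k = 1.5) {
  ok <- !is.na(values)
  if (sum(ok) < 4L) return(ok)
  q <- quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  ok & values >= q[1] - k * iqr & values <= q[2] + k * iqr
}

#' Aggregate well values to per-experiment means and group summaries
#'
#' Two-level aggregation with two-level outlier removal: Tukey's fences are
#' applied to technical replicates within each (group x experiment) cell,
#' the surviving wells are averaged per experiment, fences are applied again
#' to the experiment means within each group, and the survivors yield the
#' group mean, SEM (across experiment means) and n (experiments).
#'
#' @param df Data frame of well-level values.
#' @param value Name of the value column.
#' @param by Character vector of grouping columns (the condition key).
#' @param experiment Name of the experiment id column.
#' @param k Fence multiplier.
#' @param technical_fences,experimental_fences Toggle each fence level.
#' @return Tibble with the `by` columns plus `mean`, `sem`, `n`.
#' @export
summarize_experiments <- function(df, value = "value", by,
                                  experiment = "experiment_id", k = 1.5,
                                  technical_fences = TRUE,
                                  experimental_fences = TRUE) {
  d <- as_tibble(df)
  if (technical_fences) {
    d <- d |>
      group_by(across(all_of(c(by, experiment)))) |>
      filter(tukey_fences(.data[[value]], k)) |>
      ungroup()
  }
  em <- d |>
    group_by(across(all_of(c(by, experiment)))) |>
    summarize(.m = mean(.data[[value]]), .groups = "drop")
  if (experimental_fences) {
    em <- em |>
      group_by(across(all_of(by))) |>
      filter(tukey_fences(.data$.m, k)) |>
      ungroup()
  }
  em |>
    group_by(across(all_of(by))) |>
    summarize(mean = mean(.data$.m),
              sem = if (n() > 1) sd(.data$.m) / sqrt(n()) else NA_real_,
              n = n(), .groups = "drop")
}

#' Cohen's d with a 95% confidence interval
#'
#' `d = (mean_a - mean_b) / pooled SD` with
#' `SE_d = sqrt((n_a + n_b) / (n_a * n_b) + d^2 / (2 (n_a + n_b - 2)))` and a
#' t-based interval `d +/- t(0.975, n_a + n_b - 2) * SE_d`.
#'
#' @param group_a,group_b Numeric vectors (per-experiment means), each n >= 2.
#' @param conf Confidence level (default 0.95).
#' @return List with `d`, `se`, `conf_low`, `conf_high`, `n_a`, `n_b`.
#' @export
cohens_d <- function(group_a, group_b, conf = 0.95) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) {
    abort("cohens_d needs at least 2 observations per group",
          class = "efastress_validation")
  }
  sp2 <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2)
  if (sp2 == 0) {
    warn("zero pooled SD; Cohen's d undefined")
    return(list(d = NA_real_, se = NA_real_, conf_low = NA_real_,
                conf_high = NA_real_, n_a = na, n_b = nb))
  }
  d <- (mean(group_a) - mean(group_b)) / sqrt(sp2)
  se <- sqrt((na + nb) / (na * nb) + d^2 / (2 * (na + nb - 2)))
  tcrit <- qt(1 - (1 - conf) / 2, df = na + nb - 2)
  list(d = d, se = se, conf_low = d - tcrit * se, conf_high = d + tcrit * se,
       n_a = na, n_b = nb)
}

# uniform test-result row
.test_row <- function(test, label, statistic = NA_real_, df1 = NA_real_,
                      df2 = NA_real_, p = NA_real_, estimate = NA_real_,
                      conf_low = NA_real_, conf_high = NA_real_) {
  tibble(test = test, label = label, statistic = statistic, df1 = df1,
         df2 = df2, p = p, estimate = estimate, conf_low = conf_low,
         conf_high = conf_high)
}

#' Dunnett's many-to-one comparisons
#'
#' Each group is compared to the control with single-step multivariate-t
#' adjustment (via \pkg{multcomp}); the adjusted p-values are never smaller
#' than the unadjusted ones. The internal integration is seeded so results
#' are reproducible.
#'
#' @param df Data frame of observations.
#' @param value,group Column names of the response and the grouping factor.
#' @param control Control level compared against.
#' @param seed Seed for the multivariate-t integration.
#' @return Tibble of test-result rows (test `"DUNNETT"`), one per comparison,
#'   with `estimate` (difference vs control), `statistic` (t) and adjusted `p`.
#' @export
dunnett_test <- function(df, value, group, control, seed = 1L) {
  d <- data.frame(y = df[[value]], g = factor(df[[group]]))
  if (!control %in% levels(d$g)) {
    abort(paste0("control level '", control, "' not present"),
          class = "efastress_validation")
  }
  d$g <- stats::relevel(d$g, ref = control)
  if (nlevels(d$g) < 2) {
    abort("dunnett_test needs at least 2 groups", class = "efastress_validation")
  }
  fit <- aov(y ~ g, data = d)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- withr::with_seed(seed, summary(gl))
  cmp <- names(sm$test$coefficients)
  bind_rows(lapply(seq_along(cmp), function(i) {
    .test_row("DUNNETT", cmp[i],
              statistic = unname(sm$test$tstat[i]),
              df2 = fit$df.residual,
              p = unname(sm$test$pvalues[i]),
              estimate = unname(sm$test$coefficients[i]))
  }))
}

#' Levene's test for homoscedasticity (Brown-Forsythe variant)
#'
#' Absolute deviations from group medians, via \code{car::leveneTest}.
#'
#' @inheritParams dunnett_test
#' @return One test-result row (test `"LEVENE"`).
#' @export
levene_test <- function(df, value, group) {
  d <- data.frame(y = df[[value]], g = factor(df[[group]]))
  # with 2 observations per group the deviations from the group median are
  # pairwise equal and the internal F fit is degenerate; the resulting
  # NaN/near-1 p is reported as-is
  lt <- suppressWarnings(car::leveneTest(y ~ g, data = d, center = median))
  .test_row("LEVENE", paste0(value, " ~ ", group),
            statistic = lt[1, "F value"], df1 = lt[1, "Df"],
            df2 = lt[2, "Df"], p = lt[1, "Pr(>F)"])
}

#' One- and two-way ANOVA with the study's post-hoc tests
#'
#' `design = "one_way"`: omnibus F over `group`, Dunnett's comparisons
#' against `control` (when given) and a Brown-Forsythe Levene row.
#' `design = "two_way"`: omnibus F for both factors and their interaction,
#' plus Tukey HSD over the cell means of `group x group2` and a Levene row
#' on the cells. `design = "t_test"`: Student's t between the two levels of
#' `group`.
#'
#' @param df Data frame of observations (per-experiment means).
#' @param value Response column name.
#' @param group First factor column name.
#' @param group2 Second factor column name (two-way only).
#' @param design `"one_way"`, `"two_way"` or `"t_test"`.
#' @param control Control level for Dunnett (one-way only).
#' @param seed Seed for Dunnett's multivariate-t integration.
#' @return Tibble of test-result rows.
#' @export
anova_suite <- function(df, value, group, group2 = NULL,
                        design = c("one_way", "two_way", "t_test"),
                        control = NULL, seed = 1L) {
  design <- match.arg(design)
  d <- data.frame(y = df[[value]], g = factor(df[[group]]))
  if (nlevels(d$g) < 2) {
    abort("anova_suite needs at least 2 groups", class = "efastress_validation")
  }
  if (design == "t_test") {
    if (nlevels(d$g) != 2) {
      abort("t_test design needs exactly 2 groups", class = "efastress_validation")
    }
    if (all(tapply(d$y, d$g, var) == 0)) {
      warn("zero variance in both groups; t-test undefined")
      eq <- diff(tapply(d$y, d$g, mean)) == 0
      return(.test_row("T_TEST", paste(levels(d$g), collapse = " vs "),
                       p = if (eq) 1 else NA_real_,
                       estimate = unname(-diff(tapply(d$y, d$g, mean)))))
    }
    tt <- t.test(y ~ g, data = d, var.equal = TRUE)
    return(.test_row("T_TEST", paste(levels(d$g), collapse = " vs "),
                     statistic = unname(tt$statistic),
                     df2 = unname(tt$parameter), p = tt$p.value,
                     estimate = unname(diff(rev(tt$estimate))),
                     conf_low = tt$conf.int[1], conf_high = tt$conf.int[2]))
  }
  if (design == "one_way") {
    fit <- aov(y ~ g, data = d)
    an <- summary(fit)[[1]]
    rows <- .test_row("ONE_WAY_ANOVA", group,
                      statistic = an["g", "F value"], df1 = an["g", "Df"],
                      df2 = an["Residuals", "Df"], p = an["g", "Pr(>F)"])
    if (!is.null(control)) {
      rows <- bind_rows(rows, dunnett_test(df, value, group, control, seed))
    }
    return(bind_rows(rows, levene_test(df, value, group)))
  }
  # two-way
  stopifnot(!is.null(group2))
  d$h <- factor(df[[group2]])
  fit <- aov(y ~ g * h, data = d)
  an <- summary(fit)[[1]]
  term_lab <- c(g = group, h = group2, `g:h` = paste0(group, ":", group2))
  an_rows <- trimws(rownames(an))
  rows <- bind_rows(lapply(c("g", "h", "g:h"), function(tm) {
    i <- match(tm, an_rows)
    .test_row("TWO_WAY_ANOVA", unname(term_lab[tm]),
              statistic = an[i, "F value"], df1 = an[i, "Df"],
              df2 = an[match("Residuals", an_rows), "Df"],
              p = an[i, "Pr(>F)"])
  }))
  tk <- TukeyHSD(fit, "g:h")[["g:h"]]
  tk_rows <- bind_rows(lapply(rownames(tk), function(cmp) {
    .test_row("TUKEY_HSD", cmp,
              estimate = tk[cmp, "diff"], p = tk[cmp, "p adj"],
              conf_low = tk[cmp, "lwr"], conf_high = tk[cmp, "upr"],
              df2 = fit$df.residual)
  }))
  cells <- interaction(d$g, d$h, drop = TRUE)
  lev <- levene_test(data.frame(v = d$y, cell = cells), "v", "cell")
  bind_rows(rows, tk_rows, lev)
}

#' Dose-response slope with an F test against zero slope
#'
#' Ordinary least squares of `y` on `x`; reports the slope, its SE, R
#' squared and the F(1, n-2) test of zero slope.
#'
#' @param x Doses (at least 3 distinct values).
#' @param y Response (e.g. a per-experiment statistic), same length.
#' @return List with `slope`, `se`, `intercept`, `r2`, `statistic`, `df1`,
#'   `df2`, `p`, `n`.
#' @export
slope_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 3) {
    abort("slope_test needs at least 3 distinct x values",
          class = "efastress_validation")
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  slope <- coef(sm)["x", "Estimate"]
  se <- coef(sm)["x", "Std. Error"]
  fstat <- (slope / se)^2
  df2 <- fit$df.residual
  list(slope = slope, se = se, intercept = coef(fit)[[1]],
       r2 = sm$r.squared, statistic = fstat, df1 = 1, df2 = df2,
       p = pf(fstat, 1, df2, lower.tail = FALSE), n = length(x))
}
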