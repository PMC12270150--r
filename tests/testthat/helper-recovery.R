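# Simulation-recovery helpers shared by the acceptance-style tests:
# run the full pipeline on the packaged scenarios and pull out the headline
# statistics. Results are memoized per seed.

.recovery_cache <- new.env(parent = emptyenv())

confound_stats <- function(seed) {
  key <- paste0("confound", seed)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  sc <- scenario_mito_confound(seed = seed, n_experiments = 4)
  rep <- run_confound_analysis(simulate_runs(sc, "MITO"))
  u <- rep$underestimation
  eff <- rep$condition_effects
  pick_u <- function(sub, d, par) {
    dplyr::filter(u, .data$substance == sub, .data$dose == d,
                  .data$parameter == par)$mean_percent
  }
  pick_eff <- function(sub, d, par) {
    dplyr::filter(eff, .data$substance == sub, .data$dose == d,
                  .data$parameter == par)$mean_percent_decrease
  }
  out <- list(
    u_mr_ctrl = pick_u("NONE", 0, "MR"),
    u_src_ctrl = pick_u("NONE", 0, "SRC"),
    mr_decrease_72 = pick_eff("NI", 72, "mr"),
    u_mr_72 = pick_u("NI", 72, "MR"),
    u_src_72 = pick_u("NI", 72, "SRC"),
    u_mr_slope = dplyr::filter(rep$dose_response,
                               .data$parameter == "MR")$slope,
    mr_decrease_lps = pick_eff("LPS", 1, "mr"),
    src_decrease_lps = pick_eff("LPS", 1, "src"))
  .recovery_cache[[key]] <- out
  out
}

atp_stats <- function(seed) {
  key <- paste0("atp", seed)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  sc <- scenario_atp_budget(seed = seed, n_experiments = 3)
  rep <- run_atp_analysis(simulate_runs(sc, "MITO"),
                          simulate_runs(sc, "GLYCO"))
  b <- rep$atp_budget
  out <- list(
    glyco_fold_72 = dplyr::filter(b, .data$group == "NI",
                                  .data$dose == 72)$fold_glyco,
    total_fold_lps = dplyr::filter(b, .data$group == "LPS",
                                   .data$substance == "LPS")$fold_total,
    mito_atp_slope = rep$dose_response$slope)
  .recovery_cache[[key]] <- out
  out
}

# one-way Dunnett (72 ppm vs control) on experiment means, per arm
arm_dunnett_72 <- function(runs, parameter, config = efa_config()) {
  wellp <- mito_params_from_runs(runs, config)
  long <- tidyr::pivot_longer(wellp, dplyr::all_of(parameter),
                              names_to = "parameter", values_to = "value")
  em <- long |>
    dplyr::filter(.data$substance %in% c("NONE", "NI")) |>
    dplyr::group_by(.data$experiment_id, .data$dose, .data$arm) |>
    dplyr::filter(tukey_fences(.data$value, config$fences_k)) |>
    dplyr::summarize(value = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(dose_f = factor(.data$dose))
  res <- list()
  for (a in c("CV_FREE", "CV_INHIBITED")) {
    dt <- dunnett_test(dplyr::filter(em, .data$arm == a),
                       "value", "dose_f", "0")
    r <- dt[grepl("^72", dt$label), ]
    res[[a]] <- c(p = r$p, estimate = r$estimate)
  }
  res
}
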