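# Mitochondrial stress-test parameters and the paired-arm underestimation
# statistic.

#' Mitochondrial respiration parameters for one well
#'
#' From the four phase-representative OCR values:
#' non-mitochondrial OCR is the post-rotenone/antimycin A rate; basal
#' respiration is the pre-injection rate minus non-mito; maximal respiration
#' (MR) is the post-FCCP rate minus non-mito; spare respiratory capacity
#' (SRC) is MR minus basal. In the CV_INHIBITED arm (oligomycin injected),
#' ATP-linked respiration is pre minus post-oligomycin and proton
#' leak-linked respiration is post-oligomycin minus non-mito; both are
#' absent (NA) in the CV_FREE arm, where the first injection is plain
#' medium.
#'
#' By construction `mr == src + basal` and, when present,
#' `atp_linked + proton_leak == basal` in exact floating point.
#'
#' @param rates Named numeric (or list) of phase-representative OCR values
#'   with names `pre`, `post_inj1`, `post_fccp`, `post_raa` (`post_inj1`
#'   is only required for the CV_INHIBITED arm).
#' @param arm `"CV_INHIBITED"` or `"CV_FREE"`.
#' @param src_literal If TRUE, use the literal textbook subtraction
#'   `SRC = post_fccp - basal` (which retains non-mitochondrial OCR) instead
#'   of the default `SRC = MR - basal`.
#' @return A `mito_params` list: `basal`, `atp_linked`, `proton_leak`, `mr`,
#'   `src`, `nonmito`, `arm`.
#' @export
mito_params <- function(rates, arm = c("CV_INHIBITED", "CV_FREE"),
                        src_literal = FALSE) {
  arm <- match.arg(arm)
  rates <- as.list(rates)
  need <- c("pre", "post_fccp", "post_raa")
  if (arm == "CV_INHIBITED") need <- c(need, "post_inj1")
  miss <- need[!vapply(need, function(p) is.finite(rates[[p]] %||% NA_real_),
                       logical(1))]
  if (length(miss)) {
    abort(paste0("missing phase rate(s): ", paste(miss, collapse = ", ")),
          class = "efastress_validation")
  }
  nonmito <- rates$post_raa
  basal <- rates$pre - nonmito
  mr <- rates$post_fccp - nonmito
  src <- if (src_literal) rates$post_fccp - basal else mr - basal
  inhibited <- arm == "CV_INHIBITED"
  atp_linked <- if (inhibited) rates$pre - rates$post_inj1 else NA_real_
  # equal to post_inj1 - post_raa; this form keeps
  # basal == atp_linked + proton_leak exact in floating point
  proton_leak <- if (inhibited) basal - atp_linked else NA_real_
  structure(list(
    basal = basal, atp_linked = atp_linked, proton_leak = proton_leak,
    mr = mr, src = src, nonmito = nonmito, arm = arm),
    class = "mito_params")
}

#' Per-well mitochondrial parameters for a whole run
#'
#' @param rates Output of [phase_rates()] (OCR channel) for a MITO run.
#' @param wells The run's well metadata.
#' @param src_literal See [mito_params()].
#' @return Tibble with one row per SAMPLE well: metadata plus `basal`,
#'   `atp_linked`, `proton_leak`, `mr`, `src`, `nonmito`.
#' @export
mito_params_table <- function(rates, wells, src_literal = FALSE) {
  wide <- rates |>
    pivot_wider(names_from = "phase", values_from = "rate")
  need <- c("pre", "post_inj1", "post_fccp", "post_raa")
  miss <- setdiff(need, names(wide))
  if (length(miss)) {
    abort(paste0("missing phase(s) in rates: ", paste(miss, collapse = ", ")),
          class = "efastress_validation")
  }
  meta <- wells |>
    filter(.data$role == "SAMPLE") |>
    select("plate_id", "well", "experiment_id", "substance", "dose",
           "dose_unit", "arm")
  wide |>
    inner_join(meta, by = "well") |>
    mutate(
      nonmito = .data$post_raa,
      basal = .data$pre - .data$post_raa,
      mr = .data$post_fccp - .data$post_raa,
      src = if (src_literal) .data$post_fccp - .data$basal else .data$mr - .data$basal,
      atp_linked = ifelse(.data$arm == "CV_INHIBITED",
                          .data$pre - .data$post_inj1, NA_real_),
      proton_leak = .data$basal - .data$atp_linked) |>
    select("plate_id", "well", "experiment_id", "substance", "dose",
           "dose_unit", "arm", "basal", "atp_linked", "proton_leak",
           "mr", "src", "nonmito")
}

#' Percent underestimation caused by complex V inhibition
#'
#' `100 * (value_cv_free - value_cv_inhibited) / value_cv_free`: the share
#' of a parameter measured without ATP-synthase inhibition that the
#' inhibited arm fails to see. Undefined (NA, with a warning) where the
#' CV-free value is zero; invariant to rescaling both inputs.
#'
#' @param cv_free Parameter value from the arm without complex V inhibition.
#' @param cv_inhibited Same parameter from the inhibited arm.
#' @return Percent underestimation (may be negative). Vectorized.
#' @export
percent_underestimation <- function(cv_free, cv_inhibited) {
  out <- 100 * (cv_free - cv_inhibited) / cv_free
  zero <- !is.na(cv_free) & cv_free == 0
  if (any(zero)) {
    warn("percent underestimation undefined where the CV-free value is 0; returning NA")
    out[zero] <- NA_real_
  }
  out
}

#' Paired-arm underestimation records per experiment and condition
#'
#' Arms are paired at the experiment level (both arms share a plate within
#' an experiment; wells are not physically paired): per (experiment,
#' substance, dose), each arm's technical replicates are averaged and the
#' underestimation of MR and SRC computed from the two arm means.
#' Conditions missing one arm are skipped with a warning. Aggregation
#' across experiments is left to the caller.
#'
#' @param params Per-well parameter table (see [mito_params_table()]) with
#'   columns `experiment_id`, `substance`, `dose`, `arm`, `mr`, `src`.
#' @return Tibble with `experiment_id`, `substance`, `dose`, `parameter`
#'   (`"MR"`/`"SRC"`), `value_cv_free`, `value_cv_inhibited`, `percent`.
#' @export
paired_underestimation <- function(params) {
  arm_means <- params |>
    group_by(.data$experiment_id, .data$substance, .data$dose, .data$arm) |>
    summarize(mr = mean(.data$mr), src = mean(.data$src), .groups = "drop")
  both <- arm_means |>
    pivot_longer(c("mr", "src"), names_to = "parameter", values_to = "value") |>
    mutate(parameter = toupper(.data$parameter)) |>
    pivot_wider(names_from = "arm", values_from = "value")
  if (!all(c("CV_FREE", "CV_INHIBITED") %in% names(both))) {
    warn("no condition has both arms; returning empty underestimation table")
    both$CV_FREE <- both$CV_FREE %||% NA_real_
    both$CV_INHIBITED <- both$CV_INHIBITED %||% NA_real_
  }
  skipped <- both |>
    filter(is.na(.data$CV_FREE) | is.na(.data$CV_INHIBITED))
  if (nrow(skipped)) {
    warn(sprintf("skipping %d experiment x condition cell(s) missing one arm",
                 nrow(distinct(skipped, .data$experiment_id, .data$substance,
                               .data$dose))))
  }
  both |>
    filter(!is.na(.data$CV_FREE), !is.na(.data$CV_INHIBITED)) |>
    mutate(percent = percent_underestimation(.data$CV_FREE, .data$CV_INHIBITED)) |>
    select("experiment_id", "substance", "dose", "parameter",
           value_cv_free = "CV_FREE", value_cv_inhibited = "CV_INHIBITED",
           "percent")
}
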