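# ATP production rates from stress-test outputs.

#' Mitochondrial ATP production rate
#'
#' `atp_linked x 2 O per O2 x P/O`: coupled oxygen consumption converted to
#' ATP with the default P/O ratio of 2.75 (so 5.5 ATP per O2).
#'
#' @param atp_linked ATP-linked respiration (pmol O2/min, any normalization).
#' @param constants [conversion_constants()] (uses `po_ratio`).
#' @return pmol ATP/min in the input normalization. Vectorized.
#' @export
mito_atp <- function(atp_linked, constants = conversion_constants()) {
  stopifnot(inherits(constants, "conversion_constants"))
  atp_linked * 2 * constants$po_ratio
}

#' Glycolytic ATP production rate
#'
#' One ATP per lactate, one extruded proton per lactate: the glycolytic PER
#' maps 1:1 onto ATP production. Negative inputs (possible after blank
#' correction) pass through and are left to downstream QC.
#'
#' @param glyco_per Glycolytic proton efflux rate (pmol H+/min).
#' @return pmol ATP/min. Vectorized.
#' @export
glyco_atp <- function(glyco_per) {
  glyco_per
}

#' Condition-level ATP budget from separate mito and glyco experiments
#'
#' Mitochondrial and glycolytic ATP rates are aggregated independently
#' (their experiment sets may differ, as when the two stress tests are run
#' on separate groups); the total is the sum of the two condition means and
#' folds are taken against the control (substance `"NONE"`) condition.
#' Per-experiment totals are computed only for experiments present in both
#' inputs.
#'
#' @param mito_exp Per-experiment condition means with columns
#'   `experiment_id`, `substance`, `dose`, `atp_linked` (CV_INHIBITED arm).
#' @param glyco_exp Per-experiment condition means with columns
#'   `experiment_id`, `substance`, `dose`, `glyco_per` (the glycolytic
#'   parameter feeding ATP, demand-limited by default).
#' @param constants [conversion_constants()].
#' @return Tibble per condition: `substance`, `dose`, `mito_atp`, `mito_sem`,
#'   `n_mito`, `glyco_atp`, `glyco_sem`, `n_glyco`, `total_atp`,
#'   `fold_mito`, `fold_glyco`, `fold_total`; attribute `per_experiment`
#'   holds the per-experiment rates (with totals where both tests exist).
#' @export
atp_budget <- function(mito_exp, glyco_exp,
                       constants = conversion_constants()) {
  m <- mito_exp |>
    mutate(mito_atp = mito_atp(.data$atp_linked, constants)) |>
    select("experiment_id", "substance", "dose", "mito_atp")
  g <- glyco_exp |>
    mutate(glyco_atp = glyco_atp(.data$glyco_per)) |>
    select("experiment_id", "substance", "dose", "glyco_atp")

  ms <- m |>
    group_by(.data$substance, .data$dose) |>
    summarize(.sem = sd(.data$mito_atp) / sqrt(n()),
              .mean = mean(.data$mito_atp),
              n_mito = n(), .groups = "drop") |>
    rename(mito_atp = ".mean", mito_sem = ".sem")
  gs <- g |>
    group_by(.data$substance, .data$dose) |>
    summarize(.sem = sd(.data$glyco_atp) / sqrt(n()),
              .mean = mean(.data$glyco_atp),
              n_glyco = n(), .groups = "drop") |>
    rename(glyco_atp = ".mean", glyco_sem = ".sem")
  out <- full_join(ms, gs, by = c("substance", "dose"))
  if (nrow(out) == 0) {
    abort("no condition present in either input", class = "efastress_validation")
  }
  out <- out |>
    mutate(total_atp = .data$mito_atp + .data$glyco_atp)
  ctrl <- out |> filter(.data$substance == "NONE")
  if (nrow(ctrl) == 1) {
    out <- out |>
      mutate(fold_mito = .data$mito_atp / ctrl$mito_atp,
             fold_glyco = .data$glyco_atp / ctrl$glyco_atp,
             fold_total = .data$total_atp / ctrl$total_atp)
  } else {
    out <- out |>
      mutate(fold_mito = NA_real_, fold_glyco = NA_real_, fold_total = NA_real_)
  }
  per_exp <- full_join(m, g, by = c("experiment_id", "substance", "dose")) |>
    mutate(total_atp = .data$mito_atp + .data$glyco_atp)
  attr(out, "per_experiment") <- per_exp
  arrange(out, .data$substance, .data$dose)
}
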