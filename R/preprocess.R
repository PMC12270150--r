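# Blank correction, per-cell normalization and phase-representative rates.

#' Blank-correct a plate run
#'
#' Subtracts, per measurement cycle and channel, the blank-well aggregate
#' (mean by default) from every SAMPLE well. Blank records are retained
#' unchanged. Subtraction is signed: negative blanks raise sample values and
#' corrected rates are never clamped.
#'
#' @param run A [plate_run()].
#' @param stat Blank aggregation per cycle: `"mean"` (default) or the robust
#'   `"median"`.
#' @return The corrected [plate_run()] (`blank_corrected` flag set).
#' @export
blank_correct <- function(run, stat = c("mean", "median")) {
  stopifnot(inherits(run, "plate_run"))
  stat <- match.arg(stat)
  blank_wells <- run$wells$well[run$wells$role == "BLANK"]
  if (!length(blank_wells)) {
    abort("blank correction needs at least one BLANK well",
          class = "efastress_validation")
  }
  f <- if (stat == "mean") mean else median
  bl <- run$records |>
    filter(.data$well %in% blank_wells) |>
    group_by(.data$cycle_index) |>
    summarize(
      .b_ocr = f(.data$ocr[is.finite(.data$ocr)]),
      .b_ecar = if (any(is.finite(.data$ecar))) f(.data$ecar[is.finite(.data$ecar)]) else 0,
      .groups = "drop")
  is_sample <- run$records$well %in% run$wells$well[run$wells$role == "SAMPLE"]
  rec <- run$records |>
    left_join(bl, by = "cycle_index") |>
    mutate(
      ocr = ifelse(is_sample, .data$ocr - .data$.b_ocr, .data$ocr),
      ecar = ifelse(is_sample & !is.na(.data$ecar),
                    .data$ecar - .data$.b_ecar, .data$ecar)) |>
    select(-".b_ocr", -".b_ecar")
  run$records <- rec
  run$blank_corrected <- TRUE
  run
}

#' Normalize sample rates to 10^4 cells
#'
#' Scales every SAMPLE-well value by `10^4 / cell_count`, turning well-level
#' rates into per-10^4-cell rates. Negative (blank-corrected) values pass
#' through unchanged in sign; they are flagged downstream by QC, not clamped.
#'
#' @param run A blank-corrected [plate_run()].
#' @return The normalized [plate_run()] (`normalized` flag set).
#' @export
normalize_per_cell <- function(run) {
  stopifnot(inherits(run, "plate_run"))
  if (!isTRUE(run$blank_corrected)) {
    abort("normalize_per_cell expects a blank-corrected run; call blank_correct() first",
          class = "efastress_validation")
  }
  samples <- run$wells[run$wells$role == "SAMPLE", ]
  bad <- samples$well[samples$cell_count <= 0]
  if (length(bad)) {
    abort(paste0("cannot normalize SAMPLE well(s) with cell_count <= 0: ",
                 paste(bad, collapse = ", ")),
          class = "efastress_validation")
  }
  fac <- setNames(1e4 / samples$cell_count, samples$well)
  is_sample <- run$records$well %in% samples$well
  sc <- ifelse(is_sample, fac[run$records$well], 1)
  run$records <- run$records |>
    mutate(ocr = .data$ocr * sc, ecar = .data$ecar * sc)
  run$normalized <- TRUE
  run
}

#' Phase-representative rates per well
#'
#' For every SAMPLE well and protocol phase, orders that phase's cycles by
#' time, applies the phase's selection rule (all cycles, last two, or first
#' one) and returns the arithmetic mean of the selected cycles.
#'
#' @param run A blank-corrected, normalized [plate_run()].
#' @param channel `"OCR"` or `"ECAR"`.
#' @return Tibble with `well`, `phase`, `rate`; attribute `channel`.
#' @export
phase_rates <- function(run, channel = c("OCR", "ECAR")) {
  stopifnot(inherits(run, "plate_run"))
  channel <- match.arg(channel)
  col <- if (channel == "OCR") "ocr" else "ecar"
  samples <- run$wells$well[run$wells$role == "SAMPLE"]
  rec <- run$records |> filter(.data$well %in% samples)
  if (all(is.na(rec[[col]]))) {
    abort(paste0("channel ", channel, " absent from this run's records"),
          class = "efastress_validation")
  }
  sels <- .protocol_selections(run$protocol)
  out <- rec |>
    arrange(.data$well, .data$time_min) |>
    group_by(.data$well, .data$phase) |>
    summarize(rate = mean(select_cycles(.data[[col]], sels[[.data$phase[1]]])),
              .groups = "drop")
  attr(out, "channel") <- channel
  out
}
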