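# Plate-run container and canonical CSV I/O.
#
# A plate run couples a protocol with per-well metadata and the per-cycle
# OCR/ECAR records of one instrument run. Records hold the analyzer's
# level-2 output (rates), not raw sensor signals.

.WELL_RE <- "^[A-H](1[0-2]|[1-9])$"
.SUBSTANCES <- c("NONE", "NI", "LPS")
.ARMS <- c("CV_INHIBITED", "CV_FREE")

#' Conversion constants for flux analysis
#'
#' `buffering_factor` (mmol H+/L/pH) and `ccf` (the CO2 contribution factor,
#' the fraction of mitochondrial OCR appearing as medium acidification) carry
#' the assay-specific defaults 2.4 and 0.61. `chamber_volume` (uL) and `kvol`
#' are instrument constants of the 96-well analyzer; `po_ratio` is the ATP
#' produced per oxygen atom used to convert coupled respiration to ATP
#' production.
#'
#' @param buffering_factor mmol H+/L/pH unit of the assay medium.
#' @param chamber_volume Measurement micro-chamber volume, uL.
#' @param kvol Dimensionless volume scaling factor.
#' @param ccf CO2 contribution factor.
#' @param po_ratio ATP per O (P/O ratio).
#' @return A `conversion_constants` object.
#' @export
conversion_constants <- function(buffering_factor = 2.4, chamber_volume = 2.28,
                                 kvol = 1.6, ccf = 0.61, po_ratio = 2.75) {
  vals <- c(buffering_factor = buffering_factor,
            chamber_volume = chamber_volume,
            kvol = kvol, ccf = ccf, po_ratio = po_ratio)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all conversion constants must be finite and strictly positive",
          class = "efastress_config")
  }
  structure(as.list(vals), class = "conversion_constants")
}

.required_well_cols <- c("plate_id", "well", "role", "experiment_id",
                         "substance", "dose", "dose_unit", "arm", "cell_count")
.required_record_cols <- c("plate_id", "well", "cycle_index", "phase",
                           "time_min", "ocr", "ecar")

#' Construct (and validate) a plate run
#'
#' @param protocol An [efa_protocol()].
#' @param wells Tibble of well metadata: `plate_id`, `well` (A1-H12), `role`
#'   (`SAMPLE`/`BLANK`), `experiment_id`, `substance` (`NONE`/`NI`/`LPS`, NA
#'   for blanks), `dose`, `dose_unit`, `arm` (`CV_INHIBITED`/`CV_FREE`, NA
#'   allowed), `cell_count` (counted nuclei; 0 for blanks).
#' @param records Tibble of per-cycle measurements: `plate_id`, `well`,
#'   `cycle_index`, `phase`, `time_min`, `ocr` (pmol O2/min), `ecar`
#'   (mpH/min, may be NA for MITO runs).
#' @param validate Check all invariants (default TRUE).
#' @return A `plate_run` object.
#' @export
plate_run <- function(protocol, wells, records, validate = TRUE) {
  stopifnot(inherits(protocol, "efa_protocol"))
  wells <- as_tibble(wells)
  records <- as_tibble(records)
  run <- structure(list(protocol = protocol, wells = wells, records = records,
                        blank_corrected = FALSE, normalized = FALSE),
                   class = "plate_run")
  if (validate) validate_plate_run(run)
  run
}

#' Validate a plate run against its protocol
#'
#' Checks column presence, well coordinates, roles, cell counts, blank
#' presence, phase labels, completeness of the cycle grid and per-well time
#' monotonicity. Throws a classed condition (`efastress_validation` or
#' `efastress_parse`) describing every violation found.
#'
#' @param run A [plate_run()].
#' @return `run`, invisibly.
#' @export
validate_plate_run <- function(run) {
  stopifnot(inherits(run, "plate_run"))
  wells <- run$wells
  records <- run$records

  miss <- setdiff(.required_well_cols, names(wells))
  if (length(miss)) {
    abort(paste0("wells table missing column(s): ", paste(miss, collapse = ", ")),
          class = "efastress_parse")
  }
  miss <- setdiff(.required_record_cols, names(records))
  if (length(miss)) {
    abort(paste0("records table missing column(s): ", paste(miss, collapse = ", ")),
          class = "efastress_parse")
  }

  bad <- wells$well[!grepl(.WELL_RE, wells$well)]
  if (length(bad)) {
    abort(paste0("invalid well coordinate(s): ", paste(unique(bad), collapse = ", ")),
          class = "efastress_validation")
  }
  if (anyDuplicated(wells$well)) {
    abort("duplicated well coordinates in wells table",
          class = "efastress_validation")
  }
  if (!all(wells$role %in% c("SAMPLE", "BLANK"))) {
    abort("well role must be SAMPLE or BLANK", class = "efastress_validation")
  }
  if (!any(wells$role == "BLANK")) {
    abort("a plate run needs at least one BLANK well",
          class = "efastress_validation")
  }
  smp <- wells[wells$role == "SAMPLE", ]
  blk <- wells[wells$role == "BLANK", ]
  neg <- smp$well[is.na(smp$cell_count) | smp$cell_count <= 0]
  if (length(neg)) {
    abort(paste0("SAMPLE well(s) with missing/non-positive cell_count: ",
                 paste(neg, collapse = ", ")),
          class = "efastress_validation")
  }
  if (any(smp$cell_count < 0) || any(blk$cell_count != 0, na.rm = TRUE)) {
    abort("BLANK wells must have cell_count 0", class = "efastress_validation")
  }
  if (!all(is.na(smp$substance) | smp$substance %in% .SUBSTANCES)) {
    abort("substance must be one of NONE, NI, LPS",
          class = "efastress_validation")
  }
  if (any(is.na(smp$substance))) {
    abort(paste0("SAMPLE well(s) without a condition: ",
                 paste(smp$well[is.na(smp$substance)], collapse = ", ")),
          class = "efastress_validation")
  }
  if (!all(is.na(wells$arm) | wells$arm %in% .ARMS)) {
    abort("arm must be CV_INHIBITED or CV_FREE (or NA)",
          class = "efastress_validation")
  }

  cyc <- protocol_cycles(run$protocol)
  unknown <- setdiff(unique(records$phase), cyc$phase)
  if (length(unknown)) {
    abort(paste0("unknown phase label(s) for this protocol: ",
                 paste(unknown, collapse = ", ")),
          class = "efastress_parse")
  }
  map <- setNames(cyc$phase, cyc$cycle_index)
  out_of_range <- records$cycle_index < 1 | records$cycle_index > nrow(cyc)
  if (any(out_of_range)) {
    abort("record cycle_index outside the protocol's cycle range",
          class = "efastress_validation")
  }
  mism <- records$phase != map[as.character(records$cycle_index)]
  if (any(mism)) {
    ex <- records[which(mism)[1], ]
    abort(sprintf(
      "phase labels disagree with protocol (e.g. well %s cycle %d labelled '%s', protocol says '%s')",
      ex$well, ex$cycle_index, ex$phase, map[as.character(ex$cycle_index)]),
      class = "efastress_validation")
  }

  counts <- records |>
    count(.data$well, name = "n_rec")
  tab <- wells |>
    select("well") |>
    left_join(counts, by = "well") |>
    mutate(n_rec = coalesce(.data$n_rec, 0L))
  gaps <- tab$well[tab$n_rec != nrow(cyc)]
  if (length(gaps)) {
    detail <- vapply(gaps, function(w) {
      have <- records$cycle_index[records$well == w]
      missing <- setdiff(cyc$cycle_index, have)
      if (length(missing)) {
        sprintf("%s missing cycle(s) %s", w, paste(missing, collapse = ","))
      } else {
        sprintf("%s has duplicated cycles", w)
      }
    }, character(1))
    abort(paste0("incomplete cycle grid: ", paste(detail, collapse = "; ")),
          class = "efastress_validation")
  }
  stray <- setdiff(unique(records$well), wells$well)
  if (length(stray)) {
    abort(paste0("records for unknown well(s): ", paste(stray, collapse = ", ")),
          class = "efastress_validation")
  }

  nondec <- records |>
    arrange(.data$well, .data$cycle_index) |>
    group_by(.data$well) |>
    summarize(ok = all(diff(.data$time_min) > 0), .groups = "drop")
  if (!all(nondec$ok)) {
    abort(paste0("time not strictly increasing for well(s): ",
                 paste(nondec$well[!nondec$ok], collapse = ", ")),
          class = "efastress_validation")
  }
  invisible(run)
}

#' Read a plate run from canonical CSV files
#'
#' The cycles CSV has columns `plate_id, well, cycle_index, phase, time_min,
#' ocr_pmol_per_min, ecar_mpH_per_min` (the ECAR column may be empty); the
#' wells CSV has `plate_id, well, role, experiment_id, substance, dose,
#' dose_unit, arm, cell_count`.
#'
#' @param cycles_path,wells_path Paths to the two CSV files.
#' @param protocol The [efa_protocol()] the records must conform to.
#' @return A validated [plate_run()].
#' @export
read_plate_run <- function(cycles_path, wells_path, protocol) {
  for (p in c(cycles_path, wells_path)) {
    if (!file.exists(p)) {
      abort(paste0("file not found: ", p), class = "efastress_io")
    }
  }
  records <- readr::read_csv(
    cycles_path, show_col_types = FALSE,
    col_types = readr::cols(
      plate_id = readr::col_character(),
      well = readr::col_character(),
      cycle_index = readr::col_integer(),
      phase = readr::col_character(),
      time_min = readr::col_double(),
      ocr_pmol_per_min = readr::col_double(),
      ecar_mpH_per_min = readr::col_double()
    ))
  miss <- setdiff(c("ocr_pmol_per_min", "ecar_mpH_per_min"), names(records))
  if (length(miss)) {
    abort(paste0("cycles CSV missing column(s): ", paste(miss, collapse = ", ")),
          class = "efastress_parse")
  }
  records <- records |>
    rename(ocr = "ocr_pmol_per_min", ecar = "ecar_mpH_per_min")
  wells <- readr::read_csv(
    wells_path, show_col_types = FALSE,
    col_types = readr::cols(
      plate_id = readr::col_character(),
      well = readr::col_character(),
      role = readr::col_character(),
      experiment_id = readr::col_character(),
      substance = readr::col_character(),
      dose = readr::col_double(),
      dose_unit = readr::col_character(),
      arm = readr::col_character(),
      cell_count = readr::col_double()
    ))
  plate_run(protocol, wells, records)
}

#' Write a plate run to canonical CSV files
#'
#' Inverse of [read_plate_run()]: numeric fields round-trip to better than 6
#' significant digits and categorical fields exactly.
#'
#' @param run A validated [plate_run()].
#' @param cycles_path,wells_path Output paths.
#' @return `run`, invisibly.
#' @export
write_plate_run <- function(run, cycles_path, wells_path) {
  stopifnot(inherits(run, "plate_run"))
  if (nrow(run$records) == 0) {
    abort("refusing to write a plate run with no records",
          class = "efastress_validation")
  }
  validate_plate_run(run)
  out <- run$records |>
    rename(ocr_pmol_per_min = "ocr", ecar_mpH_per_min = "ecar")
  readr::write_csv(out, cycles_path, na = "")
  readr::write_csv(run$wells, wells_path, na = "")
  invisible(run)
}

#' @export
print.plate_run <- function(x, ...) {
  n_s <- sum(x$wells$role == "SAMPLE")
  n_b <- sum(x$wells$role == "BLANK")
  cat(sprintf(
    "<plate_run> %s protocol, %d sample + %d blank wells, %d records%s%s\n",
    x$protocol$kind, n_s, n_b, nrow(x$records),
    if (isTRUE(x$blank_corrected)) ", blank-corrected" else "",
    if (isTRUE(x$normalized)) ", per-10^4-cells" else ""))
  invisible(x)
}
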