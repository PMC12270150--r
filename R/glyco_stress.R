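# Glycolysis stress test: ECAR -> proton efflux rate conversion, partition
# of mitochondrial vs glycolytic acidification, and the glycolytic
# parameters.

#' Convert ECAR to a proton efflux rate
#'
#' `PER = ECAR x buffering_factor x chamber_volume x kvol`. With ECAR in
#' mpH/min and the buffering factor in mmol H+/L/pH, the microliter chamber
#' volume yields pmol H+/min. Linear and strictly monotone in `ecar`.
#'
#' @param ecar Extracellular acidification rate (mpH/min), any normalization.
#' @param constants [conversion_constants()].
#' @return Proton efflux rate (pmol H+/min, same normalization as input).
#' @export
ecar_to_per <- function(ecar, constants = conversion_constants()) {
  stopifnot(inherits(constants, "conversion_constants"))
  ecar * constants$buffering_factor * constants$chamber_volume * constants$kvol
}

#' Partition total proton efflux into mitochondrial and glycolytic parts
#'
#' Mitochondrial OCR per phase is the phase OCR minus the
#' post-rotenone/antimycin A OCR, clamped at zero (negative mitochondrial
#' CO2 production is unphysical and can arise from blank noise), and set to
#' zero for all phases at or after the rotenone/antimycin A injection.
#' The mitochondrial PER is `ccf` times that OCR; glycolytic PER is the
#' remainder of the total, so `total_per = mito_per + glyco_per` exactly.
#'
#' @param ocr_rates,ecar_rates [phase_rates()] outputs for the OCR and ECAR
#'   channels of the same GLYCO run.
#' @param constants [conversion_constants()].
#' @param protocol The run's protocol (phase order; defaults to the standard
#'   glycolysis test).
#' @return Tibble with `well`, `phase`, `total_per`, `mito_per`, `glyco_per`.
#' @export
partition_per <- function(ocr_rates, ecar_rates,
                          constants = conversion_constants(),
                          protocol = default_protocol("GLYCO")) {
  phases <- vapply(protocol$phases, `[[`, character(1), "name")
  raa_i <- match("post_raa", phases)
  if (is.na(raa_i)) {
    abort("protocol has no post_raa phase", class = "efastress_validation")
  }
  if (!"post_raa" %in% ocr_rates$phase) {
    abort("missing post_raa phase in OCR rates", class = "efastress_validation")
  }
  d <- ocr_rates |>
    rename(ocr = "rate") |>
    inner_join(ecar_rates |> rename(ecar = "rate"), by = c("well", "phase"))
  raa <- d |>
    filter(.data$phase == "post_raa") |>
    select("well", raa_ocr = "ocr")
  d |>
    inner_join(raa, by = "well") |>
    mutate(
      phase_i = match(.data$phase, phases),
      mito_ocr = ifelse(.data$phase_i < raa_i,
                        pmax(.data$ocr - .data$raa_ocr, 0), 0),
      total_per = ecar_to_per(.data$ecar, constants),
      mito_per = constants$ccf * .data$mito_ocr,
      glyco_per = .data$total_per - .data$mito_per) |>
    arrange(.data$well, .data$phase_i) |>
    select("well", "phase", "total_per", "mito_per", "glyco_per")
}

#' Glycolytic parameters for one well
#'
#' From the per-phase PER partition:
#' * basal acidification: glycolytic PER before glucose;
#' * basal glycolysis: glycolytic PER after glucose minus before glucose;
#' * ATP-demand-limited glycolysis: total PER after rotenone/antimycin A
#'   minus total PER before glucose (total PER at both ends, matching the
#'   parameter's operational definition; set `demand_from = "glyco"` for a
#'   glycolytic-only variant);
#' * maximal glycolytic capacity: total PER after monensin/FCCP minus
#'   glycolytic PER before glucose;
#' * glycolytic reserve: total PER after monensin/FCCP minus glycolytic PER
#'   after glucose (so `reserve == max_capacity - basal_glycolysis` exactly);
#' * 2-DG residual: total PER after 2-deoxy-D-glucose (mitochondria already
#'   poisoned, so all of it is glycolytic) minus the pre-glucose glycolytic
#'   PER - the glucose-dependence check, near zero when measured
#'   acidification is glucose-driven.
#'
#' @param per Tibble of one well's phases with `phase`, `total_per`,
#'   `mito_per`, `glyco_per` (a subset of [partition_per()] output).
#' @param demand_from `"total"` (default) or `"glyco"`.
#' @return A `glyco_params` list: `basal_acidification`, `basal_glycolysis`,
#'   `atp_demand_limited`, `max_capacity`, `reserve`, `dg_residual`.
#' @export
glyco_params <- function(per, demand_from = c("total", "glyco")) {
  demand_from <- match.arg(demand_from)
  need <- c("pre_glucose", "post_glucose", "post_raa", "post_monensin_fccp",
            "post_2dg")
  miss <- setdiff(need, per$phase)
  if (length(miss)) {
    abort(paste0("missing phase(s): ", paste(miss, collapse = ", ")),
          class = "efastress_validation")
  }
  g <- setNames(per$glyco_per, per$phase)
  tt <- setNames(per$total_per, per$phase)
  demand <- if (demand_from == "total") {
    tt[["post_raa"]] - tt[["pre_glucose"]]
  } else {
    g[["post_raa"]] - g[["pre_glucose"]]
  }
  structure(list(
    basal_acidification = g[["pre_glucose"]],
    basal_glycolysis = g[["post_glucose"]] - g[["pre_glucose"]],
    atp_demand_limited = demand,
    max_capacity = tt[["post_monensin_fccp"]] - g[["pre_glucose"]],
    reserve = tt[["post_monensin_fccp"]] - g[["post_glucose"]],
    dg_residual = tt[["post_2dg"]] - g[["pre_glucose"]]),
    class = "glyco_params")
}

#' Per-well glycolytic parameters for a whole run
#'
#' @param per [partition_per()] output for a GLYCO run.
#' @param wells The run's well metadata.
#' @param demand_from See [glyco_params()].
#' @return Tibble with one row per SAMPLE well: metadata plus the six
#'   glycolytic parameters.
#' @export
glyco_params_table <- function(per, wells, demand_from = c("total", "glyco")) {
  demand_from <- match.arg(demand_from)
  gl <- per |>
    pivot_wider(names_from = "phase",
                values_from = c("total_per", "mito_per", "glyco_per"))
  meta <- wells |>
    filter(.data$role == "SAMPLE") |>
    select("plate_id", "well", "experiment_id", "substance", "dose",
           "dose_unit", "arm")
  gl |>
    inner_join(meta, by = "well") |>
    mutate(
      basal_acidification = .data$glyco_per_pre_glucose,
      basal_glycolysis = .data$glyco_per_post_glucose - .data$glyco_per_pre_glucose,
      atp_demand_limited = if (demand_from == "total") {
        .data$total_per_post_raa - .data$total_per_pre_glucose
      } else {
        .data$glyco_per_post_raa - .data$glyco_per_pre_glucose
      },
      max_capacity = .data$total_per_post_monensin_fccp - .data$glyco_per_pre_glucose,
      reserve = .data$total_per_post_monensin_fccp - .data$glyco_per_post_glucose,
      dg_residual = .data$total_per_post_2dg - .data$glyco_per_pre_glucose) |>
    select("plate_id", "well", "experiment_id", "substance", "dose",
           "dose_unit", "arm", "basal_acidification", "basal_glycolysis",
           "atp_demand_limited", "max_capacity", "reserve", "dg_residual")
}
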