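# Fixtures are built in code: tiny hand-made plate runs for arithmetic
# checks, and noise-free scenarios for exact pipeline recovery.

# a minimal run: one protocol, explicit per-well cycle values
make_run <- function(protocol, sample_values, blank_values,
                     cell_counts = NULL, ecar_values = NULL,
                     arm = "CV_INHIBITED", substance = "NONE", dose = 0) {
  cyc <- protocol_cycles(protocol)
  n_cyc <- nrow(cyc)
  s_wells <- names(sample_values)
  b_wells <- names(blank_values)
  cell_counts <- cell_counts %||% setNames(rep(10000, length(s_wells)), s_wells)
  wells <- dplyr::bind_rows(
    tibble::tibble(plate_id = "P1", well = s_wells, role = "SAMPLE",
                   experiment_id = "exp1", substance = substance, dose = dose,
                   dose_unit = "ppm", arm = arm,
                   cell_count = unname(cell_counts[s_wells])),
    tibble::tibble(plate_id = "P1", well = b_wells, role = "BLANK",
                   experiment_id = "exp1", substance = NA_character_,
                   dose = NA_real_, dose_unit = NA_character_,
                   arm = NA_character_, cell_count = 0))
  mk_rec <- function(w, vals, ec) {
    tibble::tibble(plate_id = "P1", well = w, cycle_index = cyc$cycle_index,
                   phase = cyc$phase, time_min = cyc$time_min,
                   ocr = vals, ecar = ec)
  }
  recs <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(s_wells, function(w) {
      mk_rec(w, sample_values[[w]],
             if (is.null(ecar_values)) NA_real_ else ecar_values[[w]])
    })),
    dplyr::bind_rows(lapply(b_wells, function(w) {
      mk_rec(w, blank_values[[w]], if (is.null(ecar_values)) NA_real_ else 0)
    })))
  plate_run(protocol, wells, recs)
}

# single-phase MITO protocol for plain arithmetic checks
proto1 <- function(n_cycles = 1L, selection = "ALL") {
  efa_protocol("MITO", list(phase_def("pre", n_cycles, selection)))
}

# noise-free scenario over a (u, mr/basal ratio) grid; each combination gets
# a distinct NI pseudo-dose as its condition key
grid_scenario <- function(us, ratios, basal = 34, nonmito = 8, seed = 1) {
  combos <- expand.grid(u = us, ratio = ratios)
  conds <- lapply(seq_len(nrow(combos)), function(i) {
    condition_truth("NI", i, "ppm", nonmito = nonmito, basal_mito = basal,
                    leak_fraction = 0.15, max_resp = combos$ratio[i] * basal,
                    underestimation_mr = combos$u[i])
  })
  list(scenario = sim_scenario("grid", conds, n_experiments = 1L,
                               replicates = 2L, noise = noise_free(),
                               seed = seed),
       combos = combos)
}

# independent brute-force Tukey's fences oracle: quartiles by explicit
# linear interpolation of sorted order statistics
fences_oracle <- function(x, k = 1.5) {
  if (length(x) < 4) return(rep(TRUE, length(x)))
  s <- sort(x)
  n <- length(s)
  interp_q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  q1 <- interp_q(0.25)
  q3 <- interp_q(0.75)
  x >= q1 - k * (q3 - q1) & x <= q3 + k * (q3 - q1)
}

# per-well mito parameter table for a list of runs (default config)
mito_params_from_runs <- function(runs, config = efa_config()) {
  dplyr::bind_rows(lapply(runs, function(r) {
    r <- normalize_per_cell(blank_correct(r))
    mito_params_table(phase_rates(r, "OCR"), r$wells,
                      src_literal = config$src_literal)
  }))
}
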