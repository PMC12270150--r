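# Injection protocols: ordered measurement phases, cycle counts and the
# rule selecting which cycles within a phase feed parameter computation.

.PHASE_SELECTIONS <- c("ALL", "LAST_2", "FIRST_1")

#' Define one protocol phase
#'
#' A phase is the block of measurement cycles between two injections (or
#' before the first one). `selection` names the cycles whose mean is used as
#' the phase-representative rate downstream: all of them, the last two, or
#' the first one only.
#'
#' @param name Phase label, unique within a protocol.
#' @param n_cycles Number of measurement cycles in the phase (>= 1).
#' @param selection One of `"ALL"`, `"LAST_2"`, `"FIRST_1"`.
#' @param injections Free-text description of the compound(s) injected at the
#'   start of the phase (metadata only; no computation depends on it).
#' @return A `phase_def` object.
#' @export
phase_def <- function(name, n_cycles, selection = "ALL", injections = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L) {
    abort("n_cycles must be a positive integer", class = "efastress_validation")
  }
  selection <- match.arg(selection, .PHASE_SELECTIONS)
  if (selection == "LAST_2" && n_cycles < 2L) {
    abort(sprintf("phase '%s': selection LAST_2 needs at least 2 cycles", name),
          class = "efastress_validation")
  }
  structure(list(name = name, n_cycles = n_cycles, selection = selection,
                 injections = injections),
            class = "phase_def")
}

#' Assemble a stress-test protocol
#'
#' @param kind `"MITO"` or `"GLYCO"`.
#' @param phases List of [phase_def()] objects, in injection order.
#' @param cycle_interval Minutes between measurement cycles (default 6).
#' @return An `efa_protocol` object.
#' @export
efa_protocol <- function(kind, phases, cycle_interval = 6) {
  kind <- match.arg(kind, c("MITO", "GLYCO"))
  stopifnot(is.list(phases), length(phases) >= 1L,
            all(vapply(phases, inherits, logical(1), "phase_def")))
  nm <- vapply(phases, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    abort("phase names must be unique within a protocol",
          class = "efastress_validation")
  }
  stopifnot(is.numeric(cycle_interval), cycle_interval > 0)
  structure(list(kind = kind, phases = phases,
                 cycle_interval = as.numeric(cycle_interval)),
            class = "efa_protocol")
}

#' Standard mitochondrial and glycolysis stress-test protocols
#'
#' The mitochondrial test measures 3/3/3/2 cycles at 6-min intervals around
#' sequential injections of oligomycin A (1 uM; replaced by assay medium in
#' the complex-V-free arm), FCCP (2 uM with complex V inhibited, 3 uM
#' without) and rotenone + antimycin A (0.5 uM each). Phase-representative
#' rates use the last two cycles pre- and post-first-injection, the first
#' cycle post-FCCP, and both cycles post-rotenone/antimycin A.
#'
#' The glycolysis test measures 2/3/3/3/3 cycles around injections of
#' D-glucose (10 mM), rotenone + antimycin A (0.5 uM each), monensin (10 uM)
#' + FCCP (3 uM), and 2-deoxy-D-glucose (50 mM); all cycles are used except
#' post-monensin/FCCP, where the last two are.
#'
#' @param kind `"MITO"` or `"GLYCO"`.
#' @return An [efa_protocol()] object.
#' @export
default_protocol <- function(kind = c("MITO", "GLYCO")) {
  kind <- match.arg(kind)
  if (kind == "MITO") {
    phases <- list(
      phase_def("pre", 3L, "LAST_2"),
      phase_def("post_inj1", 3L, "LAST_2",
                "oligomycin A 1 uM (CV_INHIBITED arm) or assay medium (CV_FREE arm)"),
      phase_def("post_fccp", 3L, "FIRST_1",
                "FCCP 2 uM (CV_INHIBITED arm) / 3 uM (CV_FREE arm)"),
      phase_def("post_raa", 2L, "ALL",
                "rotenone 0.5 uM + antimycin A 0.5 uM")
    )
  } else {
    phases <- list(
      phase_def("pre_glucose", 2L, "ALL"),
      phase_def("post_glucose", 3L, "ALL", "D-glucose 10 mM"),
      phase_def("post_raa", 3L, "ALL",
                "rotenone 0.5 uM + antimycin A 0.5 uM"),
      phase_def("post_monensin_fccp", 3L, "LAST_2",
                "monensin 10 uM + FCCP 3 uM"),
      phase_def("post_2dg", 3L, "ALL", "2-deoxy-D-glucose 50 mM")
    )
  }
  efa_protocol(kind, phases)
}

#' Cycle table of a protocol
#'
#' @param protocol An [efa_protocol()].
#' @return Tibble with `cycle_index` (1-based, global over phases), `phase`
#'   and `time_min`.
#' @export
protocol_cycles <- function(protocol) {
  stopifnot(inherits(protocol, "efa_protocol"))
  n <- vapply(protocol$phases, `[[`, integer(1), "n_cycles")
  ph <- vapply(protocol$phases, `[[`, character(1), "name")
  total <- sum(n)
  tibble(cycle_index = seq_len(total),
         phase = rep(ph, n),
         time_min = (seq_len(total) - 1) * protocol$cycle_interval)
}

# named phase -> selection lookup
.protocol_selections <- function(protocol) {
  setNames(vapply(protocol$phases, `[[`, character(1), "selection"),
           vapply(protocol$phases, `[[`, character(1), "name"))
}

#' Apply a phase selection rule
#'
#' @param values Numeric values of one phase's cycles, in time order.
#' @param selection `"ALL"`, `"LAST_2"` or `"FIRST_1"`.
#' @return The selected subset of `values`.
#' @export
select_cycles <- function(values, selection) {
  selection <- match.arg(selection, .PHASE_SELECTIONS)
  switch(selection,
         ALL = values,
         LAST_2 = tail(values, 2L),
         FIRST_1 = values[1L])
}

#' @export
print.efa_protocol <- function(x, ...) {
  n <- vapply(x$phases, `[[`, integer(1), "n_cycles")
  cat(sprintf("<efa_protocol> %s: %d phases, %d cycles at %g-min intervals\n",
              x$kind, length(x$phases), sum(n), x$cycle_interval))
  for (p in x$phases) {
    cat(sprintf("  %-20s %d cycle(s), selection %-8s %s\n",
                p$name, p$n_cycles, p$selection, p$injections))
  }
  invisible(x)
}
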