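# Orchestration: full confound analysis, ATP budget analysis, reporting.

#' Analysis configuration
#'
#' @param constants [conversion_constants()].
#' @param fences_k Tukey's fences multiplier for both outlier levels.
#' @param technical_fences,experimental_fences Toggle fences at the
#'   technical (wells within experiment) and experimental (experiment means)
#'   level.
#' @param blank_stat Blank aggregation per cycle, `"mean"` or `"median"`.
#' @param src_literal Use the literal `SRC = post_fccp - basal` subtraction
#'   (retaining non-mitochondrial OCR) instead of `SRC = MR - basal`.
#' @param glyco_atp_from Glycolytic parameter feeding ATP rates:
#'   `"atp_demand_limited"` (default) or `"basal_glycolysis"`.
#' @param demand_from Baseline for ATP-demand-limited glycolysis: `"total"`
#'   PER (default) or `"glyco"` PER only.
#' @param seed Seed for the seeded parts of the statistics (Dunnett
#'   integration).
#' @return An `efa_config` object.
#' @export
efa_config <- function(constants = conversion_constants(), fences_k = 1.5,
                       technical_fences = TRUE, experimental_fences = TRUE,
                       blank_stat = c("mean", "median"), src_literal = FALSE,
                       glyco_atp_from = c("atp_demand_limited", "basal_glycolysis"),
                       demand_from = c("total", "glyco"), seed = 1L) {
  structure(list(constants = constants, fences_k = fences_k,
                 technical_fences = technical_fences,
                 experimental_fences = experimental_fences,
                 blank_stat = match.arg(blank_stat),
                 src_literal = src_literal,
                 glyco_atp_from = match.arg(glyco_atp_from),
                 demand_from = match.arg(demand_from),
                 seed = as.integer(seed)),
            class = "efa_config")
}

.config_plain <- function(x) {
  if (is.list(x)) lapply(unclass(x), .config_plain) else x
}

#' Write / read an analysis configuration as YAML
#'
#' @param config An [efa_config()].
#' @param path File path.
#' @return `read_efa_config` returns an [efa_config()]; `write_efa_config`
#'   returns `path` invisibly.
#' @export
write_efa_config <- function(config, path) {
  yaml::write_yaml(.config_plain(config), path)
  invisible(path)
}

#' @rdname write_efa_config
#' @export
read_efa_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cc <- do.call(conversion_constants, raw$constants)
  efa_config(constants = cc, fences_k = raw$fences_k,
             technical_fences = raw$technical_fences,
             experimental_fences = raw$experimental_fences,
             blank_stat = raw$blank_stat, src_literal = raw$src_literal,
             glyco_atp_from = raw$glyco_atp_from,
             demand_from = raw$demand_from, seed = raw$seed)
}

.config_hash <- function(config) {
  sprintf("%08x", .derive_seed(7L, yaml::as.yaml(.config_plain(config))))
}

.cond_key <- c("substance", "dose")

# preprocess one MITO run to the per-well parameter table
.mito_well_params <- function(run, config) {
  run <- blank_correct(run, config$blank_stat)
  run <- normalize_per_cell(run)
  mito_params_table(phase_rates(run, "OCR"), run$wells,
                    src_literal = config$src_literal)
}

# preprocess one GLYCO run to the per-well glycolytic parameter table
.glyco_well_params <- function(run, config) {
  run <- blank_correct(run, config$blank_stat)
  run <- normalize_per_cell(run)
  ocr <- phase_rates(run, "OCR")
  ecar <- phase_rates(run, "ECAR")
  per <- partition_per(ocr, ecar, config$constants, run$protocol)
  glyco_params_table(per, run$wells, demand_from = config$demand_from)
}

# technical fences then per-experiment means, for one value column
.exp_means <- function(df, value, by, config) {
  d <- df |> filter(!is.na(.data[[value]]))
  if (config$technical_fences) {
    d <- d |>
      group_by(across(all_of(c(by, "experiment_id")))) |>
      filter(tukey_fences(.data[[value]], config$fences_k)) |>
      ungroup()
  }
  d |>
    group_by(across(all_of(c(by, "experiment_id")))) |>
    summarize("{value}" := mean(.data[[value]]), .groups = "drop")
}

.group_label <- function(run) {
  subs <- setdiff(unique(na.omit(run$wells$substance)), "NONE")
  if (length(subs) == 1) subs else "ALL"
}

#' Full paired-arm confound analysis of mitochondrial stress-test runs
#'
#' Executes the whole pipeline on a set of MITO plate runs (one per
#' experiment, both arms on each plate): blank correction, per-cell
#' normalization, phase-representative rates, per-well respiration
#' parameters, technical- and experimental-level Tukey's fences,
#' experiment-level paired underestimation of MR and SRC, condition
#' summaries, CV-free percent effects versus the shared control, the Ni
#' dose-response slopes of the underestimation, and the inferential tests
#' (two-way ANOVA arm x dose with Tukey HSD, per-arm one-way ANOVA with
#' Dunnett, Levene, Cohen's d for the control arm contrast).
#'
#' @param runs List of MITO [plate_run()]s sharing a protocol, each holding
#'   both arms of one experiment.
#' @param config An [efa_config()].
#' @return An `efa_report` list; see [render_report()].
#' @export
run_confound_analysis <- function(runs, config = efa_config()) {
  if (!length(runs)) abort("no runs supplied", class = "efastress_validation")
  kinds <- vapply(runs, function(r) r$protocol$kind, character(1))
  if (!all(kinds == "MITO")) {
    abort("run_confound_analysis expects MITO runs", class = "efastress_validation")
  }
  wellp <- bind_rows(lapply(runs, .mito_well_params, config = config))
  long <- wellp |>
    pivot_longer(c("basal", "atp_linked", "proton_leak", "mr", "src", "nonmito"),
                 names_to = "parameter", values_to = "value") |>
    filter(!is.na(.data$value))

  by_arm <- c(.cond_key, "arm", "parameter")
  exp_means <- .exp_means(long, "value", by_arm, config)

  group_summaries <- summarize_experiments(
    exp_means, value = "value", by = by_arm, k = config$fences_k,
    technical_fences = FALSE, experimental_fences = config$experimental_fences)

  # combined per-condition summaries following the reporting convention:
  # basal averages both arms; ATP-linked and leak come from the inhibited
  # arm; MR, SRC and non-mito from the CV-free arm
  combined <- exp_means |>
    filter((.data$parameter == "basal") |
           (.data$parameter %in% c("atp_linked", "proton_leak") &
              .data$arm == "CV_INHIBITED") |
           (.data$parameter %in% c("mr", "src", "nonmito") &
              .data$arm == "CV_FREE")) |>
    group_by(.data$substance, .data$dose, .data$parameter, .data$experiment_id) |>
    summarize(value = mean(.data$value), .groups = "drop") |>
    summarize_experiments(value = "value",
                          by = c(.cond_key, "parameter"), k = config$fences_k,
                          technical_fences = FALSE,
                          experimental_fences = config$experimental_fences)

  # paired underestimation per experiment, from technically-fenced wells
  fenced_wells <- wellp
  if (config$technical_fences) {
    fenced_wells <- wellp |>
      group_by(.data$experiment_id, .data$substance, .data$dose, .data$arm) |>
      filter(tukey_fences(.data$mr, config$fences_k) &
               tukey_fences(.data$src, config$fences_k)) |>
      ungroup()
  }
  u_exp <- paired_underestimation(fenced_wells)
  u_kept <- u_exp
  if (config$experimental_fences) {
    u_kept <- u_exp |>
      group_by(.data$substance, .data$dose, .data$parameter) |>
      filter(tukey_fences(.data$percent, config$fences_k)) |>
      ungroup()
  }
  underestimation <- u_kept |>
    group_by(.data$substance, .data$dose, .data$parameter) |>
    summarize(mean_percent = mean(.data$percent),
              sem = if (n() > 1) sd(.data$percent) / sqrt(n()) else NA_real_,
              n = n(), .groups = "drop")

  # CV-free percent decrease vs the shared control, paired per experiment
  free <- exp_means |>
    filter(.data$arm == "CV_FREE", .data$parameter %in% c("mr", "src"))
  ctrl <- free |>
    filter(.data$substance == "NONE") |>
    select("experiment_id", "parameter", ctrl_value = "value")
  eff_exp <- free |>
    inner_join(ctrl, by = c("experiment_id", "parameter")) |>
    mutate(percent_decrease = 100 * (1 - .data$value / .data$ctrl_value))
  condition_effects <- eff_exp |>
    filter(.data$substance != "NONE") |>
    group_by(.data$substance, .data$dose, .data$parameter) |>
    summarize(mean_percent_decrease = mean(.data$percent_decrease),
              sem = if (n() > 1) sd(.data$percent_decrease) / sqrt(n()) else NA_real_,
              n = n(), .groups = "drop")

  # underestimation dose-response over the Ni sweep (control = 0 ppm)
  u_ni <- u_exp |> filter(.data$substance %in% c("NONE", "NI"))
  dose_response <- bind_rows(lapply(c("MR", "SRC"), function(pp) {
    d <- u_ni |> filter(.data$parameter == pp)
    st <- slope_test(d$dose, d$percent)
    tibble(parameter = pp, slope = st$slope, se = st$se, r2 = st$r2,
           statistic = st$statistic, df1 = st$df1, df2 = st$df2, p = st$p)
  }))

  # inferential tests on experiment means
  tests <- list()
  ni_means <- exp_means |>
    filter(.data$substance %in% c("NONE", "NI"),
           .data$parameter %in% c("mr", "src")) |>
    mutate(dose_f = factor(.data$dose))
  for (pp in c("mr", "src")) {
    d <- ni_means |> filter(.data$parameter == pp)
    tw <- anova_suite(d, "value", "arm", "dose_f", design = "two_way",
                      seed = config$seed) |>
      mutate(label = paste0(toupper(pp), ": ", .data$label))
    tests <- c(tests, list(tw))
    for (a in c("CV_FREE", "CV_INHIBITED")) {
      da <- d |> filter(.data$arm == a)
      ow <- anova_suite(da, "value", "dose_f", design = "one_way",
                        control = "0", seed = config$seed) |>
        mutate(label = paste0(toupper(pp), " ", a, ": ", .data$label))
      tests <- c(tests, list(ow))
    }
    ctrl_d <- exp_means |>
      filter(.data$substance == "NONE", .data$parameter == pp)
    cd <- cohens_d(ctrl_d$value[ctrl_d$arm == "CV_FREE"],
                   ctrl_d$value[ctrl_d$arm == "CV_INHIBITED"])
    tests <- c(tests, list(.test_row(
      "COHENS_D", paste0(toupper(pp), " control: CV_FREE vs CV_INHIBITED"),
      estimate = cd$d, conf_low = cd$conf_low, conf_high = cd$conf_high)))
  }
  lps_means <- exp_means |>
    filter(.data$substance %in% c("NONE", "LPS"),
           .data$parameter %in% c("mr", "src"))
  if (any(lps_means$substance == "LPS")) {
    for (pp in c("mr", "src")) {
      d <- lps_means |> filter(.data$parameter == pp)
      tw <- anova_suite(d, "value", "arm", "substance", design = "two_way",
                        seed = config$seed) |>
        mutate(label = paste0(toupper(pp), " LPS: ", .data$label))
      tests <- c(tests, list(tw))
    }
  }
  tests <- bind_rows(tests)

  structure(list(
    report_type = "confound",
    group_summaries = group_summaries,
    combined_summaries = combined,
    underestimation = underestimation,
    underestimation_per_experiment = u_exp,
    condition_effects = condition_effects,
    condition_effects_per_experiment = eff_exp,
    dose_response = dose_response,
    tests = tests,
    provenance = list(package_version = as.character(packageVersion("efastress")),
                      config_hash = .config_hash(config),
                      n_runs = length(runs),
                      plate_ids = sort(unique(wellp$plate_id)))),
    class = "efa_report")
}

#' ATP production budget analysis
#'
#' Computes mitochondrial ATP rates from the CV_INHIBITED arm of the MITO
#' runs (ATP-linked respiration x 2 x P/O) and glycolytic ATP rates from
#' the GLYCO runs (demand-limited glycolytic PER by default), aggregates
#' them per condition within each experimental group (runs are grouped by
#' the non-control substance they carry, so separately-run groups keep
#' their own controls), sums condition means into total ATP rates, takes
#' folds against each group's control and tests the Ni dose slope of the
#' mitochondrial ATP rate plus the LPS contrasts.
#'
#' @param mito_runs List of MITO [plate_run()]s.
#' @param glyco_runs List of GLYCO [plate_run()]s.
#' @param config An [efa_config()].
#' @return An `efa_report` list with an `atp_budget` table.
#' @export
run_atp_analysis <- function(mito_runs, glyco_runs, config = efa_config()) {
  if (!length(mito_runs) || !length(glyco_runs)) {
    abort("both mito_runs and glyco_runs are required",
          class = "efastress_validation")
  }
  mito_well <- bind_rows(lapply(mito_runs, function(r) {
    .mito_well_params(r, config) |> mutate(group = .group_label(r))
  })) |>
    filter(.data$arm == "CV_INHIBITED", !is.na(.data$atp_linked))
  if (!nrow(mito_well)) {
    abort("no CV_INHIBITED wells in the mito runs", class = "efastress_validation")
  }
  glyco_well <- bind_rows(lapply(glyco_runs, function(r) {
    .glyco_well_params(r, config) |> mutate(group = .group_label(r))
  }))
  gl_col <- config$glyco_atp_from

  mito_exp <- .exp_means(mito_well, "atp_linked",
                         c("group", .cond_key), config)
  glyco_exp <- .exp_means(glyco_well, gl_col, c("group", .cond_key), config) |>
    rename(glyco_per = all_of(gl_col))

  groups <- union(unique(mito_exp$group), unique(glyco_exp$group))
  group_budgets <- lapply(groups, function(g) {
    atp_budget(mito_exp |> filter(.data$group == g) |> select(-"group"),
               glyco_exp |> filter(.data$group == g) |> select(-"group"),
               config$constants)
  })
  budgets <- bind_rows(lapply(seq_along(groups), function(i) {
    group_budgets[[i]] |> mutate(group = groups[i])
  }))
  per_exp <- bind_rows(lapply(seq_along(groups), function(i) {
    attr(group_budgets[[i]], "per_experiment") |> mutate(group = groups[i])
  }))

  # Ni dose slope of per-experiment mitochondrial ATP rates
  ni <- per_exp |>
    filter(.data$substance %in% c("NONE", "NI"), !is.na(.data$mito_atp))
  dose_response <- NULL
  if (length(unique(ni$dose)) >= 3) {
    st <- slope_test(ni$dose, ni$mito_atp)
    dose_response <- tibble(parameter = "mito_atp", slope = st$slope,
                            se = st$se, r2 = st$r2, statistic = st$statistic,
                            df1 = st$df1, df2 = st$df2, p = st$p)
  }

  tests <- list()
  if (length(unique(ni$dose)) >= 3) {
    ni_f <- ni |> mutate(dose_f = factor(.data$dose))
    g_ni <- per_exp |>
      filter(.data$substance %in% c("NONE", "NI"), !is.na(.data$glyco_atp)) |>
      mutate(dose_f = factor(.data$dose))
    tests <- c(tests, list(
      anova_suite(ni_f, "mito_atp", "dose_f", design = "one_way",
                  control = "0", seed = config$seed) |>
        mutate(label = paste0("mito ATP: ", .data$label)),
      anova_suite(g_ni, "glyco_atp", "dose_f", design = "one_way",
                  control = "0", seed = config$seed) |>
        mutate(label = paste0("glyco ATP: ", .data$label))))
  }
  lps <- per_exp |> filter(.data$substance %in% c("NONE", "LPS"))
  if (any(lps$substance == "LPS")) {
    for (v in c("mito_atp", "glyco_atp", "total_atp")) {
      d <- lps |> filter(!is.na(.data[[v]]))
      if (length(unique(d$substance)) == 2) {
        tests <- c(tests, list(
          anova_suite(d, v, "substance", design = "t_test") |>
            mutate(label = paste0(v, ": ", .data$label))))
      }
    }
  }
  tests <- bind_rows(tests)

  structure(list(
    report_type = "atp",
    atp_budget = budgets,
    atp_per_experiment = per_exp,
    dose_response = dose_response,
    tests = tests,
    provenance = list(package_version = as.character(packageVersion("efastress")),
                      config_hash = .config_hash(config),
                      n_runs = length(mito_runs) + length(glyco_runs))),
    class = "efa_report")
}

.report_to_list <- function(report) {
  lapply(unclass(report), function(x) {
    if (inherits(x, "data.frame")) as.data.frame(x) else x
  })
}

#' Render an analysis report to JSON and Markdown
#'
#' Writes `report.json` (machine-readable, schema in
#' `system.file("extdata", "report-schema.json", package = "efastress")`)
#' and `report.md` (human-readable tables) into `path`. Deterministic:
#' rendering the same report twice produces byte-identical files.
#'
#' @param report An `efa_report` from [run_confound_analysis()] or
#'   [run_atp_analysis()].
#' @param path Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, path) {
  stopifnot(inherits(report, "efa_report"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(path, "report.json")
  md_path <- file.path(path, "report.md")
  jsonlite::write_json(.report_to_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)

  fmt_tbl <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 4, format = "g"))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(header, sep, body)
  }
  lines <- c("# Extracellular flux analysis report", "")
  if (identical(report$report_type, "confound")) {
    lines <- c(lines,
               "## Percent underestimation by complex V inhibition", "",
               fmt_tbl(report$underestimation), "",
               "## CV-free percent decrease vs control", "",
               fmt_tbl(report$condition_effects), "",
               "## Underestimation dose-response (Ni)", "",
               fmt_tbl(report$dose_response), "",
               "## Group summaries", "",
               fmt_tbl(report$group_summaries), "",
               "## ATP budget", "", "not computed (no glycolysis runs)", "")
  } else {
    lines <- c(lines,
               "## ATP budget", "",
               fmt_tbl(report$atp_budget), "")
    if (!is.null(report$dose_response)) {
      lines <- c(lines, "## Mitochondrial ATP dose-response (Ni)", "",
                 fmt_tbl(report$dose_response), "")
    }
  }
  lines <- c(lines, "## Tests", "", fmt_tbl(report$tests), "",
             sprintf("_efastress %s, config %s_",
                     report$provenance$package_version,
                     report$provenance$config_hash))
  writeLines(lines, md_path)
  invisible(c(json = json_path, md = md_path))
}

#' Validate a rendered report against the packaged schema
#'
#' Structural check of a parsed `report.json` (or an `efa_report`): the
#' required top-level fields of the packaged JSON schema must be present,
#' plus the fields the report type promises.
#'
#' @param x Path to a JSON file, a parsed list, or an `efa_report`.
#' @return TRUE if valid, otherwise an error describing the missing fields.
#' @export
validate_report <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  } else if (inherits(x, "efa_report")) {
    x <- .report_to_list(x)
  }
  schema <- jsonlite::fromJSON(system.file("extdata", "report-schema.json",
                                           package = "efastress"))
  need <- schema$required
  extra <- if (identical(x$report_type, "confound")) {
    schema$confound_required
  } else if (identical(x$report_type, "atp")) {
    schema$atp_required
  } else {
    abort("unknown report_type", class = "efastress_validation")
  }
  miss <- setdiff(c(need, extra), names(x))
  if (length(miss)) {
    abort(paste0("report missing field(s): ", paste(miss, collapse = ", ")),
          class = "efastress_validation")
  }
  TRUE
}
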