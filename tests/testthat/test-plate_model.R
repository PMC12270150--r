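test_that("default protocols match the standard injection schedules", {
  mito <- default_protocol("MITO")
  glyco <- default_protocol("GLYCO")
  expect_equal(sum(protocol_cycles(mito)$cycle_index > 0), 11)
  expect_equal(nrow(protocol_cycles(glyco)), 14)

  n_sel <- function(p) {
    vapply(p$phases, function(ph) {
      length(select_cycles(seq_len(ph$n_cycles), ph$selection))
    }, integer(1))
  }
  expect_equal(n_sel(mito), c(2L, 2L, 1L, 2L))
  expect_equal(n_sel(glyco), c(2L, 3L, 3L, 2L, 3L))

  sels <- vapply(mito$phases, `[[`, character(1), "selection")
  expect_equal(sels, c("LAST_2", "LAST_2", "FIRST_1", "ALL"))
  expect_equal(vapply(mito$phases, `[[`, character(1), "name"),
               c("pre", "post_inj1", "post_fccp", "post_raa"))
  expect_equal(vapply(glyco$phases, `[[`, character(1), "name"),
               c("pre_glucose", "post_glucose", "post_raa",
                 "post_monensin_fccp", "post_2dg"))
})

test_that("phase and protocol invariants are enforced", {
  expect_error(phase_def("x", 0), class = "efastress_validation")
  expect_error(phase_def("x", 1, "LAST_2"), class = "efastress_validation")
  expect_error(
    efa_protocol("MITO", list(phase_def("a", 2), phase_def("a", 2))),
    class = "efastress_validation")
})

test_that("plate runs round-trip through the canonical CSVs", {
  sc <- scenario_mito_confound(seed = 42)
  for (kind in c("MITO", "GLYCO")) {
    run <- simulate_run(sc, kind, "exp1")
    cyc_f <- withr::local_tempfile(fileext = ".csv")
    well_f <- withr::local_tempfile(fileext = ".csv")
    write_plate_run(run, cyc_f, well_f)
    back <- read_plate_run(cyc_f, well_f, default_protocol(kind))
    expect_equal(back$records$ocr, run$records$ocr, tolerance = 1e-6)
    expect_equal(back$records$ecar, run$records$ecar, tolerance = 1e-6)
    expect_identical(back$records$phase, run$records$phase)
    expect_identical(back$wells$well, run$wells$well)
    expect_identical(back$wells$role, run$wells$role)
    expect_identical(back$wells$arm, run$wells$arm)
    expect_equal(back$wells$cell_count, run$wells$cell_count)
  }
})

test_that("wells CSV carries exactly the blank rows of the run", {
  sc <- scenario_mito_confound(seed = 7)
  sc$n_blanks <- 2L
  run <- simulate_run(sc, "MITO", "exp1")
  cyc_f <- withr::local_tempfile(fileext = ".csv")
  well_f <- withr::local_tempfile(fileext = ".csv")
  write_plate_run(run, cyc_f, well_f)
  w <- readr::read_csv(well_f, show_col_types = FALSE)
  expect_equal(sum(w$role == "BLANK"), 2)
})

test_that("validation names missing cycles and rejects bad metadata", {
  sc <- scenario_mito_confound(seed = 3)
  run <- simulate_run(sc, "MITO", "exp1")

  gap <- run
  gap$records <- gap$records[!(gap$records$well == "B4" &
                                 gap$records$cycle_index == 7), ]
  err <- tryCatch(validate_plate_run(gap), error = identity)
  expect_s3_class(err, "efastress_validation")
  expect_match(conditionMessage(err), "B4")
  expect_match(conditionMessage(err), "7")

  neg <- run
  neg$wells$cell_count[neg$wells$well == "A1"] <- -5
  expect_error(validate_plate_run(neg), class = "efastress_validation")

  expect_error(plate_run(default_protocol("MITO"),
                         dplyr::filter(run$wells, .data$role == "SAMPLE"),
                         run$records),
               class = "efastress_validation")
})

test_that("GLYCO cycle files are rejected under a MITO protocol", {
  sc <- scenario_mito_confound(seed = 5)
  run <- simulate_run(sc, "GLYCO", "exp1")
  cyc_f <- withr::local_tempfile(fileext = ".csv")
  well_f <- withr::local_tempfile(fileext = ".csv")
  write_plate_run(run, cyc_f, well_f)
  expect_error(read_plate_run(cyc_f, well_f, default_protocol("MITO")),
               class = "efastress_parse")
})

test_that("writing an empty run and reading a missing file fail cleanly", {
  sc <- scenario_mito_confound(seed = 5)
  run <- simulate_run(sc, "MITO", "exp1")
  run$records <- run$records[0, ]
  expect_error(write_plate_run(run, tempfile(), tempfile()),
               class = "efastress_validation")
  expect_error(read_plate_run(tempfile(), tempfile(), default_protocol("MITO")),
               class = "efastress_io")
})
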