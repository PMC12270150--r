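test_that("ECAR to PER conversion is the buffering-chamber product", {
  cc <- conversion_constants()
  expect_equal(ecar_to_per(10, cc), 10 * 2.4 * 2.28 * 1.6)  # 87.552
  expect_equal(ecar_to_per(0, cc), 0)
  cc2 <- conversion_constants(buffering_factor = 4.8)
  expect_equal(ecar_to_per(10, cc2), 2 * ecar_to_per(10, cc))
  # linear and strictly monotone
  x <- seq(-2, 5, by = 0.5)
  expect_equal(ecar_to_per(2 * x, cc), 2 * ecar_to_per(x, cc))
  expect_true(all(diff(ecar_to_per(x, cc)) > 0))
  expect_error(conversion_constants(ccf = 0), class = "efastress_config")
})

make_per_rates <- function(ocr, ecar) {
  phases <- c("pre_glucose", "post_glucose", "post_raa",
              "post_monensin_fccp", "post_2dg")
  ocr_t <- tibble::tibble(well = "A1", phase = phases, rate = ocr)
  ecar_t <- tibble::tibble(well = "A1", phase = phases, rate = ecar)
  partition_per(ocr_t, ecar_t)
}

test_that("PER partition applies the CO2 contribution factor before rot/AA", {
  per <- make_per_rates(ocr = c(40, 40, 8, 8, 8), ecar = rep(50 / 8.7552, 5))
  pre <- dplyr::filter(per, .data$phase == "pre_glucose")
  expect_equal(pre$mito_per, 0.61 * 32)  # 19.52
  expect_equal(pre$total_per, 50, tolerance = 1e-9)
  expect_equal(pre$glyco_per, 50 - 19.52, tolerance = 1e-9)
  after <- dplyr::filter(per, .data$phase %in%
                           c("post_raa", "post_monensin_fccp", "post_2dg"))
  expect_true(all(after$mito_per == 0))
  expect_equal(per$total_per, per$mito_per + per$glyco_per, tolerance = 1e-12)
})

test_that("negative apparent mito OCR is clamped before the CCF", {
  per <- make_per_rates(ocr = c(5, 40, 8, 8, 8), ecar = rep(1, 5))
  pre <- dplyr::filter(per, .data$phase == "pre_glucose")
  expect_equal(pre$mito_per, 0)
  expect_true(all(per$glyco_per <= per$total_per + 1e-12))
})

test_that("glycolytic parameters follow their subtraction scheme", {
  per <- make_per_rates(ocr = c(40, 40, 8, 8, 8),
                        ecar = c(5 + 19.52, 29 + 19.52, 40, 60, 5) / 8.7552)
  gp <- glyco_params(per)
  expect_equal(gp$basal_acidification, 5, tolerance = 1e-9)
  expect_equal(gp$basal_glycolysis, 24, tolerance = 1e-9)
  expect_equal(gp$atp_demand_limited, 40 - 24.52, tolerance = 1e-9)
  expect_equal(gp$max_capacity, 60 - 5, tolerance = 1e-9)
  expect_lt(abs(gp$max_capacity - gp$reserve - gp$basal_glycolysis), 1e-9)
  expect_equal(gp$dg_residual, 0, tolerance = 1e-9)

  flat <- make_per_rates(ocr = rep(8, 5), ecar = rep(3, 5))
  gpf <- glyco_params(flat)
  expect_equal(gpf$basal_glycolysis, 0, tolerance = 1e-12)
  expect_equal(gpf$atp_demand_limited, 0, tolerance = 1e-12)
  expect_equal(gpf$reserve, 0, tolerance = 1e-12)

  expect_error(glyco_params(per[per$phase != "post_raa", ]),
               class = "efastress_validation")
})

test_that("noise-free glycolysis runs recover the scenario PER targets", {
  sc <- scenario_atp_budget(seed = 1, noise = noise_free())
  run <- simulate_run(sc, "GLYCO", "exp1", group = "NI")
  run <- normalize_per_cell(blank_correct(run))
  per <- partition_per(phase_rates(run, "OCR"), phase_rates(run, "ECAR"))
  gp <- glyco_params_table(per, run$wells)
  ctrl <- dplyr::filter(gp, .data$substance == "NONE")
  expect_equal(unique(round(ctrl$atp_demand_limited, 9)), 24.2,
               tolerance = 1e-6)
  expect_equal(unique(round(ctrl$basal_glycolysis, 9)), 22, tolerance = 1e-6)
  expect_equal(unique(round(ctrl$max_capacity, 9)), 40, tolerance = 1e-6)
  expect_equal(unique(round(ctrl$basal_acidification, 9)), 5, tolerance = 1e-6)
  ni72 <- dplyr::filter(gp, .data$dose == 72)
  expect_equal(unique(round(ni72$atp_demand_limited, 9)), 24.2 * 3.3,
               tolerance = 1e-6)
  # 2-DG returns glycolytic PER to its pre-glucose level
  expect_true(all(abs(gp$dg_residual) < 1e-6))
})

test_that("the glyco-only demand variant subtracts glycolytic baselines", {
  per <- make_per_rates(ocr = c(40, 40, 8, 8, 8),
                        ecar = c(5 + 19.52, 29 + 19.52, 40, 60, 5) / 8.7552)
  gp <- glyco_params(per, demand_from = "glyco")
  expect_equal(gp$atp_demand_limited, 40 - 5, tolerance = 1e-9)
})
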