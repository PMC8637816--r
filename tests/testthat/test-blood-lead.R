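test_that("the rounding helpers implement half-up and truncation", {
  expect_equal(round_half_up(0.00345144, 4), 0.0035)
  expect_equal(round_half_up(2.027934, 2), 2.03)
  expect_equal(round_half_up(0.00005, 4), 0.0001) # half rounds away from zero
  expect_equal(trunc_to(1.728475, 4), 1.7284)     # truncation, not rounding
  expect_equal(trunc_to(1.37751, 4), 1.3775)
  expect_equal(trunc_to(1.377, 4), 1.377)         # exact decimals survive
})

test_that("adult_bll decomposes additively with hand-computed terms", {
  b <- adult_bll(alm_params(), "average", "high_background",
                 "full_precision")
  # 282 * 0.4 * 0.05 * 0.12 * 220 / 365
  expect_equal(b$soil_term, 0.4079342, tolerance = 1e-6)
  # 0.05791 * 0.4 * 0.0258 * 1 * 365/365
  expect_equal(b$lip_term, 0.05791 * 0.4 * 0.0258)
  expect_identical(b$total, b$background + b$lip_term)
  expect_identical(b$background, 1.62 + b$soil_term)

  low <- adult_bll(alm_params(), "average", "low_background",
                   "full_precision")
  expect_identical(low$background, 1.62) # soil term reported, not added
  expect_equal(low$soil_term, b$soil_term)

  # zero lip concentration recovers the baseline-only model
  no_lip <- adult_bll(alm_params(PbL = 0), "average", "low_background")
  expect_equal(no_lip$total, 1.62)
  no_af <- adult_bll(alm_params(AF_L = 0), "high", "low_background")
  expect_equal(no_af$total, 1.62)
})

test_that("emulation mode reproduces the published scenario table digit for digit", {
  g <- scenario_table(rounding = "paper_emulation")
  expect_equal(g$totals$lip_term[g$totals$user == "average"][1], 0.0006)
  expect_equal(g$totals$lip_term[g$totals$user == "high"][1], 0.0035)
  key <- paste(g$totals$scenario, g$totals$user)
  totals <- stats::setNames(g$totals$total, key)
  expect_equal(totals[["low_background average"]], 1.6206)
  expect_equal(totals[["low_background high"]], 1.6235)
  expect_equal(totals[["high_background average"]], 2.0306)
  expect_equal(totals[["high_background high"]], 2.0335)

  fkey <- paste(g$fetal$scenario, g$fetal$user, g$fetal$rate)
  fetal <- stats::setNames(g$fetal$fetal, fkey)
  expect_equal(fetal[["low_background average 0.85"]], 1.3775)
  expect_equal(fetal[["low_background high 0.85"]], 1.3799)
  expect_equal(fetal[["low_background average 0.9"]], 1.4585)
  expect_equal(fetal[["low_background high 0.9"]], 1.4611)
  expect_equal(fetal[["high_background average 0.85"]], 1.7260)
  expect_equal(fetal[["high_background high 0.85"]], 1.7284)
  expect_equal(fetal[["high_background average 0.9"]], 1.8275)
  expect_equal(fetal[["high_background high 0.9"]], 1.8301)
})

test_that("emulated cells sit within the rounding granularity of full precision", {
  emu <- scenario_table(rounding = "paper_emulation")
  full <- scenario_table(rounding = "full_precision")
  # the coarsest emulation step rounds the background to 2 d.p., so the
  # displacement of any cell is bounded by half that unit (0.005 ug/dl)
  expect_true(all(abs(emu$totals$total - full$totals$total) < 5e-3))
  expect_true(all(abs(emu$fetal$fetal - full$fetal$fetal) < 5e-3))
})

test_that("maternal transfer truncates toward zero only in emulation mode", {
  expect_equal(maternal_transfer(1.6206, 0.85, "paper_emulation"), 1.3775)
  expect_equal(maternal_transfer(2.0335, 0.85, "paper_emulation"), 1.7284)
  expect_equal(maternal_transfer(2.0335, 0.85, "full_precision"), 1.728475)
  expect_equal(maternal_transfer(3.3, 1), 3.3) # rate 1 is the identity
  expect_error(maternal_transfer(1, 1.2), class = "liprisk_parameter_error")
  expect_error(maternal_transfer(-1, 0.5), class = "liprisk_validation_error")
})

test_that("maternal input means recover the published child-model inputs", {
  g <- scenario_table(rounding = "paper_emulation")
  m <- maternal_input_mean(g$fetal)
  expect_equal(unname(m["low_background"]), 1.41925)
  expect_equal(unname(m["high_background"]), 1.77800)

  four_equal <- tibble::tibble(scenario = rep("low_background", 4),
                               fetal = rep(1.5, 4))
  expect_equal(unname(maternal_input_mean(four_equal)), 1.5)
  expect_error(maternal_input_mean(g$fetal[1:5, ]),
               class = "liprisk_validation_error")
})

test_that("blood lead is monotone in every exposure parameter", {
  base <- alm_params()
  total_of <- function(p) adult_bll(p, "high", "high_background")$total
  t0 <- total_of(base)
  bumps <- list(Pbs = 300, PbL = 0.1, PbB0 = 2, BKSF = 0.5, IR_SD = 0.06,
                IR_L_high = 0.2, AF_SD = 0.2, EF_S = 300)
  for (nm in names(bumps)) {
    args <- stats::setNames(list(bumps[[nm]]), nm)
    expect_gte(total_of(do.call(alm_params, args)), t0)
  }
  # fetal value is monotone in the transfer rate
  expect_gte(maternal_transfer(t0, 0.9), maternal_transfer(t0, 0.85))
})

test_that("ALM parameters load from config files keyed by symbol", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("PbL: 0.1", "PbB0: 1.5"), yml)
  p <- read_alm_params(yml)
  expect_equal(p$PbL, 0.1)
  expect_equal(p$Pbs, 282)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("nope: 1", bad)
  expect_error(read_alm_params(bad), class = "liprisk_schema_error")
})

test_that("child lip intake reproduces the published daily intakes", {
  expect_equal(round(child_lip_intake(0.07380, 0.02578), 5), 0.00190)
  expect_equal(round(child_lip_intake(0.52470, 0.14902), 5), 0.07819)
  expect_equal(child_lip_intake(0, 0.1), 0)
  expect_error(child_lip_intake(-1, 0.1), class = "liprisk_validation_error")
})

test_that("child media uptake multiplies concentration, intake and absorption", {
  p <- child_exposure_params("1-2")
  up <- child_media_uptake(p)
  media <- stats::setNames(up$media$absorbed_ug_per_d, up$media$medium)
  expect_equal(unname(media["water"]), 0.01 * 0.5 * 0.5)   # 0.0025 ug/d
  expect_equal(unname(media["diet"]), 8 * 0.5)             # 4.0 ug/d
  expect_equal(unname(media["soil"]), 282 * 0.135 * 0.45)
  expect_equal(up$total_absorbed_ug_per_d, sum(up$media$absorbed_ug_per_d))
  expect_null(up$bll)

  # the diet background switches from 8 to 20 ug/d at age 3
  p5 <- child_exposure_params("4-5")
  expect_equal(p5$diet_ug_per_d, 20)

  zero <- child_exposure_params("1-2", air_conc = 0, water_conc = 0,
                                diet_ug_per_d = 0, soil_conc = 0,
                                lipbalm_conc = 0)
  expect_equal(child_media_uptake(zero)$total_absorbed_ug_per_d, 0)
  expect_error(child_exposure_params("9-10"),
               class = "liprisk_parameter_error")
})

test_that("uptake stops at absorbed mass unless a response function is attached", {
  up <- child_media_uptake(child_exposure_params("2-3"),
                           response = function(u) 0.1 * u)
  expect_equal(up$bll, 0.1 * up$total_absorbed_ug_per_d)
})
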