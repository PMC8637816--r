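# Adult Lead Methodology (ALM) blood-lead model and maternal transfer.
#
# The adult blood-lead level is an additive linear model
#   PbB = soil_term + lip_term + PbB0
#   soil_term = Pbs * BKSF * IR_SD * AF_SD * EF_S / AT
#   lip_term  = PbL * BKSF * IR_L  * AF_L  * EF_L / AT
# in ug/dl, with BKSF the biokinetic slope factor (ug/dl blood per ug/d
# uptake). Two background scenarios are modelled: "low_background" uses the
# reference blood lead PbB0 alone (the soil term is computed and reported
# but excluded from the total), and "high_background" adds the soil term to
# PbB0. The fetal level is the maternal total times a transfer rate (0.85
# in the ALM convention, 0.9 in the IEUBK convention).
#
# A "paper_emulation" rounding mode reproduces, digit for digit, published
# scenario tables assembled in a spreadsheet: the lip term is rounded half
# away from zero to 4 decimals and the background to 2 decimals before the
# terms are added, and the fetal product is truncated toward zero at 4
# decimals. Full precision is the default for real use.

#' Parameter set for the adult blood-lead model
#'
#' Defaults carry the published study configuration: Chinese reference soil
#' Pb 282 ug/g, lip-cosmetic Pb at the panel mean 0.05791 ug/g, baseline
#' blood lead 1.62 ug/dl, BKSF 0.4 d/dl, soil+dust intake 0.05 g/d with 12%
#' absorption over 220 d/year, lip intake 0.0258 (average user) or 0.1490
#' (high user) g/d with absorption conservatively 1 over 365 d/year.
#'
#' @param Pbs soil Pb concentration, ug/g.
#' @param PbL lip-cosmetic Pb concentration, ug/g.
#' @param PbB0 baseline (reference) blood lead, ug/dl.
#' @param BKSF biokinetic slope factor, d/dl.
#' @param IR_SD soil + dust intake, g/d.
#' @param IR_L_average,IR_L_high lip-cosmetic intake, g/d, per user type.
#' @param AF_SD,AF_L absorption fractions in \[0, 1\].
#' @param EF_S,EF_L exposure frequency, d/year (must not exceed `AT`).
#' @param AT averaging time, d/year.
#' @return An `alm_params` list.
#' @export
alm_params <- function(Pbs = 282, PbL = 0.05791, PbB0 = 1.62, BKSF = 0.4,
                       IR_SD = 0.05, IR_L_average = 0.0258,
                       IR_L_high = 0.1490, AF_SD = 0.12, AF_L = 1,
                       EF_S = 220, EF_L = 365, AT = 365) {
  p <- list(Pbs = Pbs, PbL = PbL, PbB0 = PbB0, BKSF = BKSF, IR_SD = IR_SD,
            IR_L_average = IR_L_average, IR_L_high = IR_L_high,
            AF_SD = AF_SD, AF_L = AF_L, EF_S = EF_S, EF_L = EF_L, AT = AT)
  for (nm in names(p)) assert_scalar_number(p[[nm]], nm, 0)
  assert_scalar_number(AT, "AT", 0, allow_zero = FALSE)
  if (AF_SD > 1 || AF_L > 1) {
    stop_liprisk("absorption fractions must lie in [0, 1]",
                 "liprisk_parameter_error")
  }
  if (EF_S > AT || EF_L > AT) {
    stop_liprisk("exposure frequency cannot exceed the averaging time",
                 "liprisk_parameter_error")
  }
  structure(p, class = "alm_params")
}

#' Load ALM parameters from a YAML or JSON config file
#'
#' Keys follow the model symbols accepted by [alm_params()]; omitted keys
#' keep the study defaults.
#'
#' @param file path to a `.yaml`/`.yml` or `.json` file.
#' @return An [alm_params()] object.
#' @export
read_alm_params <- function(file) {
  cfg <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  extra <- setdiff(names(cfg), names(formals(alm_params)))
  if (length(extra)) {
    stop_liprisk(sprintf("unknown ALM parameter key(s): %s",
                         paste(extra, collapse = ", ")),
                 "liprisk_schema_error")
  }
  do.call(alm_params, cfg)
}

#' Adult blood-lead level with term-wise decomposition
#'
#' @param params an [alm_params()] set.
#' @param user `"average"` or `"high"`, selecting the lip intake rate.
#' @param scenario `"low_background"` (total = PbB0 + lip term; the soil
#'   term is reported but excluded) or `"high_background"`
#'   (total = PbB0 + soil term + lip term).
#' @param rounding `"full_precision"` (default) or `"paper_emulation"` (lip
#'   term rounded half-up to 4 decimals, background to 2, before summing).
#' @return A `bll_breakdown` list with `soil_term`, `lip_term`, `baseline`,
#'   `background` (what actually enters the total), `total` (ug/dl) and the
#'   scenario/user/rounding labels. `total = background + lip_term` exactly.
#' @export
#' @examples
#' adult_bll(alm_params(), "average", "low_background", "paper_emulation")
adult_bll <- function(params = alm_params(),
                      user = c("average", "high"),
                      scenario = c("low_background", "high_background"),
                      rounding = c("full_precision", "paper_emulation")) {
  stopifnot(inherits(params, "alm_params"))
  user <- match.arg(user)
  scenario <- match.arg(scenario)
  rounding <- match.arg(rounding)

  IR_L <- switch(user, average = params$IR_L_average, high = params$IR_L_high)
  soil_term <- params$Pbs * params$BKSF * params$IR_SD * params$AF_SD *
    params$EF_S / params$AT
  lip_term <- params$PbL * params$BKSF * IR_L * params$AF_L *
    params$EF_L / params$AT
  background <- if (scenario == "high_background") {
    params$PbB0 + soil_term
  } else {
    params$PbB0
  }
  if (rounding == "paper_emulation") {
    lip_term <- round_half_up(lip_term, 4)
    background <- round_half_up(background, 2)
  }
  structure(
    list(soil_term = soil_term, lip_term = lip_term, baseline = params$PbB0,
         background = background, total = background + lip_term,
         user = user, scenario = scenario, rounding = rounding),
    class = "bll_breakdown"
  )
}

#' Maternal-to-fetal blood-lead transfer
#'
#' @param PbB maternal blood lead, ug/dl.
#' @param rate transfer fraction in \[0, 1\] (0.85 ALM, 0.9 IEUBK).
#' @param rounding `"full_precision"` or `"paper_emulation"` (product
#'   truncated toward zero at 4 decimals).
#' @return Fetal blood lead, ug/dl.
#' @export
#' @examples
#' maternal_transfer(2.0335, 0.85, "paper_emulation") # 1.7284
maternal_transfer <- function(PbB, rate,
                              rounding = c("full_precision",
                                           "paper_emulation")) {
  rounding <- match.arg(rounding)
  if (any(!is.finite(PbB) | PbB < 0)) {
    stop_liprisk("PbB must be non-negative", "liprisk_validation_error")
  }
  if (any(!is.finite(rate) | rate < 0 | rate > 1)) {
    stop_liprisk("transfer rate must lie in [0, 1]", "liprisk_parameter_error")
  }
  fetal <- rate * PbB
  if (rounding == "paper_emulation") fetal <- trunc_to(fetal, 4)
  fetal
}

#' Blood-lead scenario grid (backgrounds x users x transfer rates)
#'
#' Composes [adult_bll()] and [maternal_transfer()] over the cartesian grid
#' of background scenarios, user types and transfer rates, mirroring the
#' layout of a published ALM run table: 4 maternal totals and 8 fetal cells
#' under the defaults.
#'
#' @param params an [alm_params()] set.
#' @param backgrounds subset of `c("low_background", "high_background")`.
#' @param users subset of `c("average", "high")`.
#' @param rates transfer rates in \[0, 1\] (default `c(0.85, 0.9)`).
#' @param rounding `"full_precision"` or `"paper_emulation"`.
#' @return A list with `totals` (tibble: scenario, user, lip_term,
#'   background, total) and `fetal` (tibble adding rate and fetal ug/dl).
#' @export
scenario_table <- function(params = alm_params(),
                           backgrounds = c("low_background",
                                           "high_background"),
                           users = c("average", "high"),
                           rates = c(0.85, 0.9),
                           rounding = c("full_precision",
                                        "paper_emulation")) {
  rounding <- match.arg(rounding)
  backgrounds <- match.arg(backgrounds, several.ok = TRUE)
  users <- match.arg(users, several.ok = TRUE)

  grid <- expand.grid(user = users, scenario = backgrounds,
                      stringsAsFactors = FALSE)
  runs <- unname(Map(function(u, s) adult_bll(params, u, s, rounding),
                     grid$user, grid$scenario))
  totals <- tibble::tibble(
    scenario = grid$scenario,
    user = grid$user,
    soil_term = vapply(runs, `[[`, numeric(1), "soil_term"),
    lip_term = vapply(runs, `[[`, numeric(1), "lip_term"),
    background = vapply(runs, `[[`, numeric(1), "background"),
    total = vapply(runs, `[[`, numeric(1), "total")
  )
  fetal <- do.call(rbind, lapply(rates, function(r) {
    tibble::tibble(
      scenario = totals$scenario, user = totals$user, rate = r,
      maternal = totals$total,
      fetal = maternal_transfer(totals$total, r, rounding)
    )
  }))
  list(totals = totals, fetal = tibble::as_tibble(fetal),
       rounding = rounding)
}

#' Maternal blood-lead input per background scenario
#'
#' Summarises a fetal scenario grid into one maternal blood-lead input per
#' background for the child uptake model: the arithmetic mean of the four
#' fetal cells (2 users x 2 transfer rates) of that background.
#'
#' @param fetal the `fetal` tibble from [scenario_table()] (or any tibble
#'   with `scenario` and `fetal` columns, four rows per background).
#' @return Named numeric vector of means, one per background scenario.
#' @export
#' @examples
#' grid <- scenario_table(rounding = "paper_emulation")
#' maternal_input_mean(grid$fetal) # 1.41925, 1.77800
maternal_input_mean <- function(fetal) {
  if (!all(c("scenario", "fetal") %in% names(fetal))) {
    stop_liprisk("fetal grid needs `scenario` and `fetal` columns",
                 "liprisk_validation_error")
  }
  counts <- table(fetal$scenario)
  if (any(counts != 4L)) {
    stop_liprisk("each background must contribute exactly 4 fetal values (2 users x 2 rates)",
                 "liprisk_validation_error")
  }
  vapply(split(fetal$fetal, fetal$scenario), mean, numeric(1))
}
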