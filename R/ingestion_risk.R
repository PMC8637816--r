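# Deterministic USEPA oral-ingestion risk for Pb in lip products.
#
# The pathway is the standard three-step chain:
#   ADD = C * IR * EF * ED * CF / (BW * AT)   [mg/(kg d)]
#   HQ  = ADD / RfD                           [dimensionless]
#   LCR = ADD * SF                            [dimensionless]
# Units matter: C is mg Pb per kg of product, IR is grams of product per
# day, and CF = 0.001 bridges g -> kg of product so ADD lands in mg of Pb
# per kg body weight per day. Dropping CF is the classic 1000x slip.

#' Exposure-parameter set for the oral ingestion pathway
#'
#' Bundles the ingestion-equation symbols with their units. Two presets carry
#' the published defaults for lifetime lip-product use by a 60 kg adult:
#' `"average_user"` (IR = 0.02578 g/d) and `"high_user"` (IR = 0.14902 g/d),
#' both with EF = 365 d/a, ED = 70 a, CF = 0.001, BW = 60 kg, AT = 25550 d
#' (so EF*ED = AT and the dose is a steady-state daily rate), RfD = 4e-4
#' mg/(kg d) and SF = 0.0085 (kg d)/mg.
#'
#' @param preset `"average_user"` or `"high_user"`, or `NULL` to build from
#'   the individual arguments.
#' @param IR intake rate of lip product, g/d.
#' @param EF exposure frequency, d/a.
#' @param ED exposure duration, a.
#' @param CF unit conversion factor (g product -> kg product), 0.001.
#' @param BW body weight, kg.
#' @param AT averaging time, d.
#' @param RfD non-carcinogenic oral reference dose, mg/(kg d).
#' @param SF carcinogenic slope factor, (kg d)/mg.
#' @return An `exposure_params` list; all components strictly positive.
#' @export
#' @examples
#' exposure_params("average_user")
#' exposure_params(IR = 0.05, BW = 55)
exposure_params <- function(preset = NULL, IR = 0.02578, EF = 365, ED = 70,
                            CF = 0.001, BW = 60, AT = 25550, RfD = 0.0004,
                            SF = 0.0085) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("average_user", "high_user"))
    IR <- switch(preset, average_user = 0.02578, high_user = 0.14902)
  }
  p <- list(IR = IR, EF = EF, ED = ED, CF = CF, BW = BW, AT = AT,
            RfD = RfD, SF = SF)
  for (nm in names(p)) {
    assert_scalar_number(p[[nm]], nm, 0, allow_zero = FALSE)
  }
  p$preset <- if (is.null(preset)) NA_character_ else preset
  structure(p, class = "exposure_params")
}

#' Load exposure parameters from a YAML or JSON config file
#'
#' The file holds a mapping keyed by the equation symbols (`IR`, `EF`, `ED`,
#' `CF`, `BW`, `AT`, `RfD`, `SF`); omitted keys keep the published defaults.
#'
#' @param file path to a `.yaml`/`.yml` or `.json` file.
#' @return An [exposure_params()] object.
#' @export
read_exposure_params <- function(file) {
  cfg <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  allowed <- c("IR", "EF", "ED", "CF", "BW", "AT", "RfD", "SF")
  extra <- setdiff(names(cfg), c(allowed, "preset"))
  if (length(extra)) {
    stop_liprisk(sprintf("unknown exposure parameter key(s): %s",
                         paste(extra, collapse = ", ")),
                 "liprisk_schema_error")
  }
  do.call(exposure_params, cfg)
}

#' Average daily dose of ingested Pb
#'
#' @param C Pb concentration in the product, mg/kg; non-negative.
#' @param params an [exposure_params()] set.
#' @return ADD in mg/(kg d). With the published defaults EF*ED = AT, so the
#'   dose reduces to `C * IR * CF / BW`.
#' @export
#' @examples
#' average_daily_dose(0.05791, exposure_params("average_user"))
average_daily_dose <- function(C, params) {
  stopifnot(inherits(params, "exposure_params"))
  if (any(!is.finite(C) | C < 0)) {
    stop_liprisk("concentration C must be non-negative",
                 "liprisk_validation_error")
  }
  C * params$IR * params$EF * params$ED * params$CF / (params$BW * params$AT)
}

#' Non-carcinogenic hazard quotient
#'
#' @param ADD average daily dose, mg/(kg d).
#' @param RfD oral reference dose, mg/(kg d); must be positive.
#' @return HQ = ADD / RfD. Values strictly above 1 flag concern.
#' @export
hazard_quotient <- function(ADD, RfD) {
  assert_scalar_number(RfD, "RfD", 0, allow_zero = FALSE)
  ADD / RfD
}

#' Incremental lifetime cancer risk
#'
#' @param ADD average daily dose, mg/(kg d).
#' @param SF carcinogenic slope factor, (kg d)/mg; must be positive.
#' @return LCR = ADD * SF. Values strictly above 1e-6 flag concern.
#' @export
cancer_risk <- function(ADD, SF) {
  assert_scalar_number(SF, "SF", 0, allow_zero = FALSE)
  ADD * SF
}

#' Full deterministic risk assessment at a concentration
#'
#' Chains dose, hazard quotient and cancer risk, and classifies each metric
#' against its reference value (HQ vs 1, LCR vs 1e-6; strictly-greater
#' comparisons, so a metric exactly at its threshold is "acceptable").
#'
#' @inheritParams average_daily_dose
#' @return A tibble with columns `C, ADD, HQ, LCR, HQ_class, LCR_class`
#'   (classes in `{"acceptable", "elevated"}`), one row per element of `C`.
#' @export
#' @examples
#' assess_risk(0.05791, exposure_params("average_user"))
assess_risk <- function(C, params) {
  ADD <- average_daily_dose(C, params)
  HQ <- hazard_quotient(ADD, params$RfD)
  LCR <- cancer_risk(ADD, params$SF)
  tibble::tibble(
    C = C, ADD = ADD, HQ = HQ, LCR = LCR,
    HQ_class = ifelse(HQ > 1, "elevated", "acceptable"),
    LCR_class = ifelse(LCR > 1e-6, "elevated", "acceptable")
  )
}
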