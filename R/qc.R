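# Instrument-side quality control for ICP-MS panel determinations.
#
# QC operates on already-tabulated numbers, not raw instrument files: the
# replicate ("parallel") concentration pairs, the correlation coefficient of
# the external calibration curve, and the procedural blank measurements.

#' Construct a QC run
#'
#' @param parallel_pairs two-column numeric matrix or data frame of replicate
#'   concentration pairs (one row per parallel determination).
#' @param calibration_r correlation coefficient of the standard curve,
#'   in \[-1, 1\].
#' @param blank_values numeric vector of procedural blank measurements.
#' @param detection_limit method detection limit, same units as the blanks.
#' @return A `liprisk_qc_run` list.
#' @export
qc_run <- function(parallel_pairs, calibration_r, blank_values,
                   detection_limit) {
  pairs <- as.matrix(parallel_pairs)
  if (ncol(pairs) != 2L || !is.numeric(pairs)) {
    stop_liprisk("parallel_pairs must be a numeric two-column structure",
                 "liprisk_validation_error")
  }
  assert_scalar_number(calibration_r, "calibration_r", -1)
  if (calibration_r > 1) {
    stop_liprisk("calibration_r must lie in [-1, 1]", "liprisk_parameter_error")
  }
  assert_scalar_number(detection_limit, "detection_limit", 0,
                       allow_zero = FALSE)
  structure(
    list(parallel_pairs = unname(pairs),
         calibration_r = calibration_r,
         blank_values = as.numeric(blank_values),
         detection_limit = detection_limit),
    class = "liprisk_qc_run"
  )
}

#' Relative percent deviation of a replicate pair
#'
#' `|a - b| / mean(a, b)`, the acceptance statistic for parallel samples.
#'
#' @param a,b replicate concentrations with positive mean.
#' @return The RPD as a fraction (0.10 = 10%).
#' @export
#' @examples
#' rpd(0.10, 0.11) # 0.0952...
rpd <- function(a, b) {
  m <- (a + b) / 2
  if (any(m == 0)) {
    stop_liprisk("RPD undefined for a pair with mean 0",
                 "liprisk_degenerate_error")
  }
  abs(a - b) / m
}

#' Validate a QC run against the survey acceptance rules
#'
#' Three rules: every parallel pair's relative deviation must not exceed
#' `max_rpd` (10% in the survey protocol); the calibration-curve correlation
#' coefficient must be at least `min_r` (0.995, inclusive); every procedural
#' blank must fall below the detection limit.
#'
#' @param run a [qc_run()].
#' @param max_rpd maximum allowed relative deviation (fraction, default 0.10).
#' @param min_r minimum calibration correlation (default 0.995).
#' @return A list with per-rule results (`pairs` tibble with `rpd` and
#'   `pass`, `calibration`, `blanks`), `failures` (character vector naming
#'   each failed item) and overall `pass`.
#' @export
qc_validate <- function(run, max_rpd = 0.10, min_r = 0.995) {
  stopifnot(inherits(run, "liprisk_qc_run"))
  assert_scalar_number(max_rpd, "max_rpd", 0, allow_zero = FALSE)
  assert_scalar_number(min_r, "min_r", -1)

  pairs <- run$parallel_pairs
  n_pairs <- nrow(pairs)
  pair_rpd <- if (n_pairs) {
    vapply(seq_len(n_pairs), function(i) rpd(pairs[i, 1], pairs[i, 2]),
           numeric(1))
  } else numeric(0)
  pair_pass <- pair_rpd <= max_rpd

  cal_pass <- run$calibration_r >= min_r
  blank_pass <- all(run$blank_values < run$detection_limit)

  failures <- character(0)
  if (any(!pair_pass)) {
    failures <- c(failures, sprintf("parallel_pair_%d", which(!pair_pass)))
  }
  if (!cal_pass) failures <- c(failures, "calibration_curve")
  if (!blank_pass) failures <- c(failures, "blank_control")

  list(
    pairs = tibble::tibble(pair = seq_len(n_pairs), rpd = pair_rpd,
                           pass = pair_pass),
    calibration = list(r = run$calibration_r, min_r = min_r, pass = cal_pass),
    blanks = list(values = run$blank_values,
                  detection_limit = run$detection_limit, pass = blank_pass),
    failures = failures,
    pass = length(failures) == 0L
  )
}
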