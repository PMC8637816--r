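# Synthetic concentration panels and QC runs.
#
# No raw per-product concentrations were deposited with the survey, so the
# package ships a generator that emulates the panel's statistical structure:
# 34 products split 12/13/9 across lipsticks, lip glosses and lip balms,
# ~41% non-detects recorded as 0, and detected concentrations lognormal with
# the parameters moment-matched to the published summary statistics
# (mu = -3.5507, sigma = 1.1848). Prices are drawn within the survey's
# retail terciles (0-95, 96-266, >266 RMB). Brand/colour/country
# vocabularies are neutral placeholders, not real trademarks.

SYNTH_BRANDS <- paste0("Brand", LETTERS[1:10])
SYNTH_COLORS <- c("red", "pink", "coral", "nude", "berry", "orange", "clear")
SYNTH_COUNTRIES <- c("China", "France", "USA", "Japan", "Korea", "Italy")

#' Specification for a synthetic concentration panel
#'
#' @param n_per_category named counts per category; default
#'   `c(lipstick = 12, lip_gloss = 13, lip_balm = 9)`, the survey design.
#' @param p_zero non-detect probability in \[0, 1) (default 0.41).
#' @param mu,sigma lognormal log-scale parameters for detected values;
#'   defaults moment-matched to the published panel mean/sd.
#' @param price_bins interior tercile edges in RMB (default `c(95, 266)`);
#'   the top bracket is capped at `price_max`.
#' @param price_max upper bound for the top price bracket, RMB.
#' @param seed integer seed; the same seed yields a byte-identical panel.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_per_category = c(lipstick = 12, lip_gloss = 13,
                                          lip_balm = 9),
                       p_zero = 0.41, mu = -3.5507, sigma = 1.1848,
                       price_bins = c(95, 266), price_max = 800,
                       seed = 1) {
  if (is.null(names(n_per_category)) ||
      !all(names(n_per_category) %in% PANEL_CATEGORIES)) {
    stop_liprisk("n_per_category must be named with known categories",
                 "liprisk_parameter_error")
  }
  if (any(n_per_category < 1)) {
    stop_liprisk("each category count must be >= 1", "liprisk_parameter_error")
  }
  assert_scalar_number(p_zero, "p_zero", 0)
  if (p_zero >= 1) {
    stop_liprisk("p_zero must be < 1", "liprisk_parameter_error")
  }
  assert_scalar_number(sigma, "sigma", 0, allow_zero = FALSE)
  if (length(price_bins) != 2L || is.unsorted(price_bins) ||
      any(price_bins <= 0) || price_max <= price_bins[2]) {
    stop_liprisk("price_bins must be two increasing positive edges below price_max",
                 "liprisk_parameter_error")
  }
  structure(list(n_per_category = n_per_category, p_zero = p_zero, mu = mu,
                 sigma = sigma, price_bins = price_bins,
                 price_max = price_max, seed = seed),
            class = "panel_spec")
}

#' Generate a synthetic concentration panel
#'
#' Per record: a non-detect (concentration 0) with probability `p_zero`,
#' otherwise a lognormal(mu, sigma) draw; categories follow
#' `n_per_category`; brands, colours and countries come from placeholder
#' vocabularies; the price is uniform within a randomly chosen retail
#' tercile. Deterministic given the spec's seed.
#'
#' @param spec a [panel_spec()].
#' @return A `liprisk_panel` (see [sample_panel()]).
#' @export
#' @examples
#' generate_panel(panel_spec(seed = 7))
generate_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  counts <- spec$n_per_category
  n <- sum(counts)
  prefix <- c(lipstick = "LS", lip_gloss = "LG", lip_balm = "LB")
  category <- rep(names(counts), counts)
  ids <- unlist(lapply(names(counts), function(g) {
    paste0(prefix[[g]], seq_len(counts[[g]]))
  }), use.names = FALSE)

  with_seed(spec$seed, {
    nondetect <- stats::runif(n) < spec$p_zero
    pb <- numeric(n)
    pb[!nondetect] <- stats::rlnorm(sum(!nondetect), spec$mu, spec$sigma)
    edges <- c(0, spec$price_bins, spec$price_max)
    tercile <- sample.int(3, n, replace = TRUE)
    price <- round(stats::runif(n, edges[tercile], edges[tercile + 1]), 2)
    sample_panel(
      sample_id = ids,
      category = category,
      pb_mg_per_kg = pb,
      detected = !nondetect,
      brand = sample(SYNTH_BRANDS, n, replace = TRUE),
      production_country = sample(SYNTH_COUNTRIES, n, replace = TRUE),
      color = sample(SYNTH_COLORS, n, replace = TRUE),
      price_rmb = price
    )
  })
}

#' Specification for a synthetic QC run
#'
#' @param replicate_cv coefficient of variation of the multiplicative
#'   replicate noise (default 0.02).
#' @param calibration_r_true calibration-curve correlation to report
#'   (default 0.999).
#' @param detection_limit method detection limit, mg/kg.
#' @param seed integer seed.
#' @return A `qc_spec` list.
#' @export
qc_spec <- function(replicate_cv = 0.02, calibration_r_true = 0.999,
                    detection_limit = 0.005, seed = 1) {
  assert_scalar_number(replicate_cv, "replicate_cv", 0)
  assert_scalar_number(detection_limit, "detection_limit", 0,
                       allow_zero = FALSE)
  structure(list(replicate_cv = replicate_cv,
                 calibration_r_true = calibration_r_true,
                 detection_limit = detection_limit, seed = seed),
            class = "qc_spec")
}

#' Generate a synthetic QC run for a panel
#'
#' Each detected record yields a replicate pair: the recorded concentration
#' perturbed by two independent multiplicative lognormal errors of the given
#' coefficient of variation. Blanks are drawn uniformly below the detection
#' limit; the calibration correlation is reported at its target value.
#'
#' @param panel a `liprisk_panel`.
#' @param spec a [qc_spec()].
#' @return A [qc_run()].
#' @export
generate_qc_run <- function(panel, spec = qc_spec()) {
  stopifnot(inherits(panel, "liprisk_panel"), inherits(spec, "qc_spec"))
  conc <- panel$pb_mg_per_kg[panel$detected]
  with_seed(spec$seed, {
    noise <- function(k) {
      if (spec$replicate_cv == 0) rep(1, k)
      else {
        s2 <- log(1 + spec$replicate_cv^2)
        stats::rlnorm(k, -s2 / 2, sqrt(s2))
      }
    }
    pairs <- cbind(conc * noise(length(conc)), conc * noise(length(conc)))
    blanks <- stats::runif(3, 0, spec$detection_limit * 0.5)
    qc_run(parallel_pairs = pairs, calibration_r = spec$calibration_r_true,
           blank_values = blanks, detection_limit = spec$detection_limit)
  })
}
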