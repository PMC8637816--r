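test_that("moment matching solves the closed-form lognormal equations", {
  # sigma^2 = log(1 + (s/m)^2), mu = log(m) - sigma^2/2, by hand:
  fit <- fit_lognormal_moments(0.05791, 0.10146)
  expect_equal(fit$mu, -3.5507, tolerance = 1e-4)
  expect_equal(fit$sigma, 1.1848, tolerance = 1e-4)
})

test_that("moment-matched fits round-trip the input mean and sd", {
  set.seed(31)
  for (i in 1:10) {
    m <- stats::runif(1, 0.01, 2)
    s <- stats::runif(1, 0.005, 3)
    fit <- fit_lognormal_moments(m, s)
    mean_back <- exp(fit$mu + fit$sigma^2 / 2)
    sd_back <- mean_back * sqrt(exp(fit$sigma^2) - 1)
    expect_equal(mean_back, m, tolerance = 1e-9)
    expect_equal(sd_back, s, tolerance = 1e-9)
  }
})

test_that("log-space MLE uses the 1/n variance and the inflate policy counts zeros", {
  vals <- exp(c(0, 1, 2))
  fit <- fit_concentration_distribution(vals, method = "log_mle")
  expect_equal(fit$mu, 1)
  expect_equal(fit$sigma, sqrt(2 / 3)) # 0.8165

  with_zeros <- fit_concentration_distribution(c(0, 0, vals),
                                               method = "log_mle")
  expect_equal(with_zeros$p_zero, 2 / 5)
  expect_equal(with_zeros$mu, 1) # zeros excluded from the lognormal part
  expect_equal(with_zeros$n_fit, 3L)

  dropped <- fit_concentration_distribution(c(0, 0, vals),
                                            method = "log_mle",
                                            zero_policy = "drop_zeros")
  expect_equal(dropped$p_zero, 0)

  half_dl <- fit_concentration_distribution(c(0, vals), method = "log_mle",
                                            zero_policy = "substitute_half_dl",
                                            dl = 0.01)
  expect_equal(half_dl$p_zero, 0)
  expect_equal(half_dl$n_fit, 4L)
})

test_that("degenerate and undersized inputs are refused", {
  expect_error(fit_concentration_distribution(c(0.1, 0.1, 0.1)),
               class = "liprisk_degenerate_error")
  expect_error(fit_concentration_distribution(c(0, 0, 0.1, 0.2)),
               class = "liprisk_fit_error")
  expect_error(fit_concentration_distribution(c(-0.1, 0.2, 0.3, 0.4)),
               class = "liprisk_validation_error")
})

test_that("analytic quantile matches the hand-derived lognormal quantiles", {
  fit <- fit_lognormal_moments(0.05791, 0.10146)
  expect_equal(analytic_quantile(fit, 0.5), exp(fit$mu))
  expect_equal(analytic_quantile(fit, 0.5), 0.0287, tolerance = 1e-3)
  expect_equal(analytic_quantile(fit, 0.95), 0.2015, tolerance = 1e-3)

  inflated <- fit_lognormal_moments(0.05791, 0.10146, p_zero = 0.5)
  expect_equal(analytic_quantile(inflated, 0.4), 0)
  # above the zero mass the quantile is the rescaled lognormal quantile
  expect_equal(analytic_quantile(inflated, 0.75),
               exp(fit$mu + fit$sigma * stats::qnorm(0.5)))
  expect_error(analytic_quantile(fit, 1.2), class = "liprisk_parameter_error")
})

test_that("the sampler is seed-deterministic and leaves the caller's RNG alone", {
  fit <- fit_lognormal_moments(0.05, 0.1, p_zero = 0.4)
  a <- sample_concentrations(fit, 100, seed = 42)
  b <- sample_concentrations(fit, 100, seed = 42)
  expect_identical(a, b)

  set.seed(7)
  before <- stats::runif(1)
  set.seed(7)
  invisible(sample_concentrations(fit, 50, seed = 99))
  expect_identical(stats::runif(1), before)
})

test_that("sampled zero fraction and percentiles agree with the analytic mixture", {
  fit99 <- fit_lognormal_moments(0.05, 0.1, p_zero = 0.99)
  draws <- sample_concentrations(fit99, 20000, seed = 5)
  p_hat <- mean(draws == 0)
  expect_lt(abs(p_hat - 0.99), 3 * sqrt(0.99 * 0.01 / 20000))

  fit <- fit_lognormal_moments(0.05791, 0.10146)
  draws <- sample_concentrations(fit, 1e5, seed = 12)
  for (q in c(0.05, 0.5, 0.95)) {
    emp <- unname(stats::quantile(draws, q, type = 7))
    expect_equal(emp, analytic_quantile(fit, q), tolerance = 0.02)
  }
})

test_that("Monte Carlo summary keeps exact cross-metric and cross-preset ratios", {
  fit <- fit_lognormal_moments(0.05791, 0.10146, p_zero = 14 / 34)
  out <- probabilistic_risk(fit, cfg = mc_config(n_iter = 4000, seed = 8))
  s <- out$summary
  hq_a <- s[s$preset == "average_user" & s$metric == "HQ", ]
  hq_h <- s[s$preset == "high_user" & s$metric == "HQ", ]
  lcr_a <- s[s$preset == "average_user" & s$metric == "LCR", ]

  for (col in c("mean", "p50", "p95")) {
    # same draws for both presets -> ratio is exactly the IR ratio
    expect_equal(hq_h[[col]] / hq_a[[col]], 0.14902 / 0.02578)
    # Eq chain: LCR = HQ * RfD * SF at every percentile
    expect_equal(lcr_a[[col]] / hq_a[[col]], 3.4e-6)
  }
  # percentile columns are non-decreasing in the level
  expect_true(all(s$p5 <= s$p50 & s$p50 <= s$p95))
  expect_equal(out$seed, 8)
  expect_equal(out$n_iter, 4000L)
})

test_that("a near-point-mass fit collapses to the deterministic assessment", {
  fit <- structure(list(p_zero = 0, mu = log(0.05791), sigma = 1e-6,
                        method = "moment_match", zero_policy = "inflate",
                        n_fit = NA_integer_),
                   class = "concentration_fit")
  out <- probabilistic_risk(fit, cfg = mc_config(n_iter = 500, seed = 2))
  det <- assess_risk(0.05791, exposure_params("average_user"))
  row <- out$summary[out$summary$preset == "average_user" &
                       out$summary$metric == "HQ", ]
  expect_equal(row$p50, det$HQ, tolerance = 1e-4)
  expect_equal(row$p95, det$HQ, tolerance = 1e-4)
})

test_that("doubling all concentrations doubles every HQ/LCR percentile", {
  fit <- fit_lognormal_moments(0.05791, 0.10146, p_zero = 0.3)
  fit2 <- fit_lognormal_moments(2 * 0.05791, 2 * 0.10146, p_zero = 0.3)
  # same sigma, mu shifted by log 2: identical normal draws scale by 2
  expect_equal(fit2$sigma, fit$sigma)
  a <- probabilistic_risk(fit, cfg = mc_config(n_iter = 2000, seed = 21))
  b <- probabilistic_risk(fit2, cfg = mc_config(n_iter = 2000, seed = 21))
  for (col in c("mean", "p5", "p50", "p95")) {
    expect_equal(b$summary[[col]], 2 * a$summary[[col]], tolerance = 1e-12)
  }
})
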