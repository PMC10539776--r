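test_that("the spline rate source passes through every knot exactly", {
  B <- 10^seq(-4, 1, length.out = 9)
  T1 <- 1 / eq1_rate(B, 4, 0.5, 0.9e-9)
  d <- tibble::tibble(B_T = B, T1_s = T1)
  rf <- rate_function(d)
  expect_equal(rf(B), 1 / T1, tolerance = 1e-12)
})

test_that("the spline tracks the closed-form dispersion between knots", {
  B <- 10^seq(-4, 1.2, length.out = 25)
  d <- tibble::tibble(B_T = B, T1_s = 1 / eq1_rate(B, 4, 0.5, 0.9e-9))
  rf <- rate_function(d)
  Bq <- 10^seq(-3.9, 1.1, length.out = 200)
  expect_equal(rf(Bq), eq1_rate(Bq, 4, 0.5, 0.9e-9), tolerance = 5e-3)
})

test_that("two-point data degrade to a linear segment; out-of-range fields clamp with warning", {
  d <- tibble::tibble(B_T = c(0.01, 1), T1_s = c(0.2, 0.5))
  rf <- rate_function(d)
  mid <- sqrt(0.01 * 1)    # midpoint on the log axis
  expect_equal(rf(mid), mean(c(5, 2)), tolerance = 1e-9)
  expect_warning(v <- rf(5), "clamped")
  expect_equal(v, 2, tolerance = 1e-12)
})

test_that("attenuation factor limits: zero rates and constant rate", {
  pr <- transfer_profile(seq(0, 0.3, length.out = 50),
                         exp(seq(log(4e-3), log(9.4), length.out = 50)))
  expect_equal(attenuation_factor(pr, function(B) rep(0, length(B))), 1)
  expect_equal(attenuation_factor(pr, function(B) rep(2.5, length(B))),
               exp(2.5 * 0.3), tolerance = 1e-12)
  expect_error(attenuation_factor(pr, function(B) rep(-1, length(B))),
               "negative")
})

test_that("the 500-interval product matches an adaptive-quadrature exposure integral", {
  cfg <- synthetic_study_config()
  pr <- gen_transfer_profile(cfg, 4e-3)
  rates <- list(R1 = 4, R1inf = 0.5, tau_c = 0.9e-9)
  rf <- rate_function(rates)
  Bt <- approxfun(pr$t_s, pr$B_T, rule = 2)
  # brute-force fine trapezoidal integration of the exposure integral
  tt <- seq(0, 0.3, length.out = 2e5 + 1)
  rr <- rf(Bt(tt))
  exposure <- sum((rr[-1] + rr[-length(rr)]) / 2) * diff(tt[1:2])
  f500 <- attenuation_factor(pr, rf, 500L)
  expect_equal(f500, exp(exposure), tolerance = 1e-3)
  # refining beyond 500 intervals changes the factor by < 0.1 %
  f4000 <- attenuation_factor(pr, rf, 4000L)
  expect_equal(f500 / f4000, 1, tolerance = 1e-3)
})

test_that("attenuation factors never fall below one for non-negative rates", {
  cfg <- synthetic_study_config()
  rf <- rate_function(list(R1 = 2, R1inf = 0.3, tau_c = 1e-9))
  for (B0 in c(1e-4, 4e-3, 0.5, 5)) {
    expect_gte(attenuation_factor(gen_transfer_profile(cfg, B0), rf), 1)
  }
})

test_that("deconvolution inverts attenuation and is the identity for unit factors", {
  cfg <- synthetic_study_config(cidnp_noise = 0)
  fields <- 10^seq(log10(1e-3), log10(1), length.out = 12)
  true_curve <- cidnp_curve(fields, -exp(-(log10(fields) + 2.4)^2),
                            source = "simulated")
  rates <- list(R1 = 4, R1inf = 0.5, tau_c = 0.9e-9)
  obs <- gen_observed_cidnp(true_curve, cfg, rates = rates)
  rec <- deconvolve_curve(obs, shuttle_profiles(cfg), rates)
  expect_equal(rec$polarization, true_curve$polarization, tolerance = 1e-6)
  # all factors one -> identity
  rec0 <- deconvolve_curve(true_curve,
                           function(B) NULL,
                           function(B) rep(0, length(B)))
  expect_equal(rec0$polarization, true_curve$polarization)
})

test_that("deconvolve then re-attenuate is the identity", {
  cfg <- synthetic_study_config()
  rates <- list(R1 = 3, R1inf = 0.4, tau_c = 1e-9)
  fields <- c(2e-3, 2e-2, 0.2)
  obs <- cidnp_curve(fields, c(-0.4, -1, -0.3), source = "observed")
  rec <- deconvolve_curve(obs, shuttle_profiles(cfg), rates)
  back <- rec$polarization / rec$attenuation
  expect_equal(back, obs$polarization, tolerance = 1e-12)
  expect_true(all(rec$attenuation >= 1))
})

test_that("a missing profile is reported with the field value", {
  obs <- cidnp_curve(c(2e-3, 4e-3), c(-1, -2), source = "observed")
  profs <- list(`0.002` = gen_transfer_profile(synthetic_study_config(), 2e-3))
  expect_error(
    deconvolve_curve(obs, profs, list(R1 = 1, R1inf = 0.1, tau_c = 1e-9)),
    "0.004")
})
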