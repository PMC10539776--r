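test_that("dispersion model limits: zero field, half-amplitude point, plateau", {
  R1 <- 4; R1inf <- 0.5; tau <- 1e-9
  expect_equal(eq1_rate(0, R1, R1inf, tau), R1 + R1inf)
  expect_equal(eq1_rate(1 / (gamma_H * tau), R1, R1inf, tau),
               R1 / 2 + R1inf)
  expect_equal(eq1_rate(1e6, R1, R1inf, tau), R1inf, tolerance = 1e-6)
  # monotone non-increasing for admissible parameters
  B <- 10^seq(-4, 1.5, length.out = 100)
  for (tc in c(1e-10, 1e-9, 5e-9)) {
    expect_true(all(diff(eq1_rate(B, 3, 0.2, tc)) <= 0))
  }
})

test_that("noise-free decay fits recover T1 exactly, in both recovery directions", {
  for (T1 in c(0.1, 0.5, 2)) {
    tau <- seq(0, 5 * T1, length.out = 14)
    y <- 1 - 2 * exp(-tau / T1)     # inversion recovery, I0 = -Iinf
    f <- fit_decay(tibble::tibble(tau_vd_s = tau, intensity = y))
    expect_equal(f$T1, T1, tolerance = 1e-9)
    expect_false(f$flagged)
    # plain decay to zero plateau
    y2 <- 3 * exp(-tau / T1)
    f2 <- fit_decay(tibble::tibble(tau_vd_s = tau, intensity = y2))
    expect_equal(f2$T1, T1, tolerance = 1e-9)
  }
})

test_that("decay fit tolerates noise at the documented level", {
  set.seed(101)
  tau <- seq(0, 2, length.out = 12)
  y <- (1 - 2 * exp(-tau / 0.5)) * (1 + 0.02 * rnorm(12))
  f <- fit_decay(tibble::tibble(tau_vd_s = tau, intensity = y))
  expect_equal(f$T1, 0.5, tolerance = 0.05)
})

test_that("decay fit input contracts", {
  expect_error(fit_decay(tibble::tibble(tau_vd_s = c(0, 1, 2),
                                        intensity = 1:3)),
               "at least 4")
  expect_error(fit_decay(tibble::tibble(tau_vd_s = c(-1, 0, 1, 2),
                                        intensity = 1:4)),
               "non-negative")
})

test_that("noise-free dispersion fit recovers the generating parameters", {
  B <- 10^seq(log10(0.5), log10(16.4), length.out = 15)
  truth <- list(R1 = 3.2, R1inf = 0.45, tau_c = 0.8e-9)
  T1 <- 1 / eq1_rate(B, truth$R1, truth$R1inf, truth$tau_c)
  f <- fit_dispersion(tibble::tibble(B_T = B, T1_s = T1))
  expect_equal(f$R1, truth$R1, tolerance = 1e-6)
  expect_equal(f$R1inf, truth$R1inf, tolerance = 1e-6)
  expect_equal(f$tau_c, truth$tau_c, tolerance = 1e-6)
})

test_that("dispersion fit residuals are invariant under row reordering", {
  set.seed(3)
  B <- 10^seq(log10(0.6), log10(16), length.out = 12)
  T1 <- 1 / eq1_rate(B, 2.5, 0.5, 1e-9) * (1 + 0.03 * rnorm(12))
  d <- tibble::tibble(B_T = B, T1_s = T1)
  f1 <- fit_dispersion(d)
  f2 <- fit_dispersion(d[sample(nrow(d)), ])
  expect_equal(f1$residual_norm, f2$residual_norm, tolerance = 1e-8)
  expect_equal(f1$tau_c, f2$tau_c, tolerance = 1e-8)
})

test_that("the fit window excludes points outside it", {
  B <- c(0.1, 0.3, 10^seq(log10(0.6), log10(16), length.out = 10))
  T1 <- 1 / eq1_rate(B, 2.5, 0.5, 1e-9)
  # corrupt the low-field points: they must not affect a windowed fit
  T1[1:2] <- T1[1:2] * 10
  f <- fit_dispersion(tibble::tibble(B_T = B, T1_s = T1),
                      B_min = 0.56, B_max = 16.44)
  expect_equal(f$n, 10)
  expect_equal(f$tau_c, 1e-9, tolerance = 1e-6)
  expect_error(fit_dispersion(tibble::tibble(B_T = B[1:3], T1_s = T1[1:3]),
                              B_min = 0.56, B_max = 16.44),
               "at least 4")
})

test_that("tidy and glance methods expose the fit", {
  B <- 10^seq(log10(0.6), log10(16), length.out = 10)
  f <- fit_dispersion(tibble::tibble(B_T = B,
                                     T1_s = 1 / eq1_rate(B, 2, 0.4, 1e-9)))
  td <- tidy(f)
  expect_equal(td$term, c("R1", "R1inf", "tau_c"))
  expect_equal(td$estimate[3], 1e-9, tolerance = 1e-6)
  gl <- glance(f)
  expect_equal(gl$nobs, 10)
})

test_that("grouped decay and dispersion table fits work end to end", {
  set.seed(5)
  cfg <- synthetic_study_config(decay_noise = 0)
  fields <- 10^seq(log10(0.6), log10(16), length.out = 8)
  decays <- gen_nmrd_decays(cfg, fields)
  nmrd <- fit_decay_table(decays)
  expect_equal(nrow(nmrd), nrow(cfg$protons) * length(fields))
  disp <- fit_dispersion_table(nmrd, B_min = 0.56, B_max = 16.44)
  truth <- cfg$protons[order(cfg$protons$proton), ]
  disp <- disp[order(disp$proton), ]
  expect_equal(disp$tau_c, truth$tau_c, tolerance = 1e-5)
  expect_equal(disp$R1, truth$R1, tolerance = 1e-5)
})
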