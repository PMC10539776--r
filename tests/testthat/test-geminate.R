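# Physical properties of the simulated geminate polarization.  Most checks
# run on reduced radial grids: the properties under test are qualitative
# and grid-robust, and the default 81-node grid is exercised by the
# acceptance suite.

test_that("no symmetry breaking, no polarization", {
  m <- biradical_model(
    spins = biradical_spin_params(ga = 2.0034, gb = 2.0034, A = 0,
                                  A_add = 0, n_add = 0L),
    exchange = exchange_model(J0 = 0))
  g <- radial_grid(n_points = 15)
  # reference scale: the default-model polarization at its emissive extremum
  ref <- abs(geminate_polarization(4e-3, biradical_model(),
                                   radial_grid(n_points = 15)))
  for (B in c(1e-3, 0.1)) {
    expect_lt(abs(geminate_polarization(B, m, g)), 1e-12 * ref)
  }
})

test_that("low-field polarization at the extremum is emissive for either sign of the observed HFC", {
  g <- radial_grid(n_points = 31)
  for (A in c(-0.7, 0.7)) {
    m <- biradical_model(spins = biradical_spin_params(A = A))
    p <- geminate_polarization(8e-3, m, g)
    expect_lt(p, 0)
  }
})

test_that("high-field polarization is proportional to the observed HFC in the linear regime", {
  # zero HFC gives zero CIDNP, and the response is linear in A while the
  # singlet-triplet conversion is unsaturated; checked against a fixed-
  # distance two-level S-T0 perturbative scaling (P proportional to A)
  g <- radial_grid(n_points = 41)
  pol_at <- function(A) {
    m <- biradical_model(spins = biradical_spin_params(A = A))
    geminate_polarization(4.7, m, g)
  }
  p0 <- pol_at(0)
  p1 <- pol_at(-0.1)
  p2 <- pol_at(-0.2)
  expect_lt(abs(p0), 1e-6 * abs(p2))
  expect_equal(p2 / p1, 2, tolerance = 0.15)
})

test_that("with a point distribution and diffusion off, the extremum tracks 2|J| over a decade", {
  # delta distribution at the contact node; J set directly by the exchange
  # amplitude (slope of extremum field vs |J| = 2 within 10 %)
  g <- radial_grid(0.49, 0.59, 3)
  dist <- distance_distribution("normal", 0.49, 1e-3)
  Js <- c(-1, -3.2, -10)
  Bmax <- vapply(Js, function(J0) {
    m <- biradical_model(
      spins = biradical_spin_params(n_add = 0L, A_add = 0),
      exchange = exchange_model(J0 = J0, convention = "decay_length_nm",
                                alpha = 1e9),
      kinetics = kinetics_relaxation_params(D = 0, kp = 1e7))
    fs <- 2 * abs(J0) * 1e-3 * 10^seq(-0.35, 0.35, length.out = 29)
    crv <- field_sweep(fs, m, g, dist)
    curve_features(crv, branch = "emissive")$extremum_field
  }, 0)
  fit <- stats::lm(log(Bmax * 1e3) ~ log(abs(Js)))
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.1)  # log-log slope
  expect_equal(Bmax * 1e3 / (2 * abs(Js)), rep(1, 3), tolerance = 0.1)
})

test_that("the extremum field is consistent with twice the effective exchange at the distribution core", {
  # order-of-magnitude consistency oracle: read the extremum field B* from
  # a sweep, then check B* against 2|J(r)| evaluated within one sigma of
  # the distribution centre
  g <- radial_grid(n_points = 41)
  crv <- field_sweep(log_field_grid(5e-4, 0.2, 25), grid = g)
  ft <- curve_features(crv, branch = "emissive")
  ex <- exchange_model()
  r_star <- ex$r_contact + ex$lambda * log(2 * 2.3e8 / (ft$extremum_field * 1e3))
  expect_lt(abs(r_star - 0.89), 2 * 0.15)
})

test_that("field sweeps are deterministic and halving the radial spacing changes amplitudes little", {
  fs <- log_field_grid(1e-3, 0.1, 7)
  m <- biradical_model(additional_nuclei = "semiclassical")
  c1 <- field_sweep(fs, m, radial_grid(n_points = 41))
  c1b <- field_sweep(fs, m, radial_grid(n_points = 41))
  expect_identical(c1$polarization, c1b$polarization)
  c2 <- field_sweep(fs, m, radial_grid(n_points = 81))
  expect_equal(c1$polarization, c2$polarization,
               tolerance = 0.02)
})

test_that("a generator with no sink at all is rejected", {
  m <- biradical_model(kinetics = kinetics_relaxation_params(kp = 0, ks = 0))
  expect_error(geminate_polarization(0.01, m, radial_grid(n_points = 5)),
               "singular")
})
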