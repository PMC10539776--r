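test_that("the Hamiltonian is self-adjoint and degenerate in the trivial limit", {
  H <- build_hamiltonian(0.05, 0.89)
  expect_lt(max(abs(H - Conj(t(H)))), 1e-12 * max(abs(H)))
  # B = 0, J = 0 (far distance), A = 0: all levels degenerate
  sp0 <- biradical_spin_params(A = 0, A_add = 0, n_add = 0L)
  H0 <- build_hamiltonian(0, 50, spins = sp0)
  expect_lt(max(abs(H0)), 1e-3)   # rad/s; exchange is ~1e-290 at 50 nm
})

test_that("with A = 0 and J = 0 the eigenstates are Zeeman products and the S-T0 gap tracks ga - gb", {
  sp <- biradical_spin_params(A = 0, A_add = 0, n_add = 0L)
  muB <- 9.2740100783e-24 / 1.054571817e-34
  for (B in c(0.1, 1, 5)) {
    H <- build_hamiltonian(B, 50, spins = sp)
    expect_lt(max(abs(H - diag(diag(H)))), 1e-6 * max(abs(H)))  # diagonal
    # alpha-beta vs beta-alpha electron states differ by (ga-gb) muB B
    d <- Re(diag(H))
    # basis order: |ma mb mn>, nucleus fastest
    gap <- d[3] - d[5]   # |a_alpha b_beta n_alpha> - |a_beta b_alpha n_alpha>
    expect_equal(gap, (sp$ga - sp$gb) * muB * B, tolerance = 1e-9)
  }
})

test_that("S and T- levels cross at B ~ 2|J| for large negative fixed J", {
  # numerical eigenvalue scan vs the closed-form two-level expression
  sp <- biradical_spin_params(A = 0, A_add = 0, n_add = 0L,
                              ga = 2.0034, gb = 2.0034)
  for (J_mT in c(-5, -20)) {
    ex <- exchange_model(J0 = J_mT, convention = "decay_length_nm",
                         alpha = 1e6)   # effectively distance-independent
    gap <- function(B_T) {
      ev <- sort(Re(eigen(build_hamiltonian(B_T, 1, sp, ex),
                          only.values = TRUE)$values))
      # each electronic level is doubly degenerate in the nuclear spin;
      # ev[3] - ev[1] is the S/T- separation on either side of the crossing
      ev[3] - ev[1]
    }
    B_scan <- seq(1.2 * abs(J_mT), 2.8 * abs(J_mT), length.out = 161) * 1e-3
    gaps <- vapply(B_scan, gap, 0)
    B_c <- B_scan[which.min(gaps)]
    expect_equal(B_c * 1e3, 2 * abs(J_mT), tolerance = 0.02 * 2 * abs(J_mT))
  }
})

test_that("relaxation generator has the Lorentzian rate structure", {
  kin <- kinetics_relaxation_params()
  sp <- biradical_spin_params()
  # zero field: flip rate equals the zero-frequency spectral density G tau_u
  L0 <- build_relaxation(0, kin, sp)
  # population transfer rate |T+><T+| -> |T0-ish|: in the product basis the
  # rate from state aa to ba (flip of electron a) is the S- dissipator rate
  rho_aa <- matrix(0, 4, 4); rho_aa[1, 1] <- 1   # |alpha alpha>
  drho <- matrix(L0 %*% as.vector(rho_aa), 4, 4)
  Gtau <- kin$G * kin$tau_u
  expect_equal(drho[3, 3], Gtau, tolerance = 1e-10 * Gtau)  # flip of a
  expect_equal(drho[2, 2], Gtau, tolerance = 1e-10 * Gtau)  # flip of b
  # high field: rates fall as 1/omega^2
  B_hi <- 50  # omega tau_u ~ 8.8
  Lhi <- build_relaxation(B_hi, kin, sp)
  drho_hi <- matrix(Lhi %*% as.vector(rho_aa), 4, 4)
  om <- sp$ga * (9.2740100783e-24 / 1.054571817e-34) * B_hi
  expect_equal(drho_hi[3, 3], Gtau / (1 + (om * kin$tau_u)^2),
               tolerance = 1e-6 * Gtau)
  # G = 0 gives the zero generator
  expect_equal(max(abs(build_relaxation(1, kinetics_relaxation_params(G = 0),
                                        sp))), 0)
})

test_that("relaxation preserves the trace of populations", {
  L <- build_relaxation(0.5, kinetics_relaxation_params(),
                        biradical_spin_params())
  set.seed(7)
  for (k in 1:5) {
    v <- rnorm(4); rho <- diag(v / sum(v))
    drho <- matrix(L %*% as.vector(rho), 4, 4)
    expect_lt(abs(sum(diag(drho))), 1e-12 * max(abs(drho)))
  }
})

test_that("diffusion generator conserves probability and keeps the input distribution stationary", {
  g <- radial_grid(0.49, 1.6, 61)
  for (nm in c("sim1", "sim2", "sim3")) {
    dop <- build_diffusion_operator(g, distribution_preset(nm), 2e-7)
    scale <- max(abs(dop$W))
    expect_lt(max(abs(colSums(dop$W))), 1e-12 * scale)
    expect_lt(max(abs(dop$W %*% dop$weights)), 1e-10 * scale)
  }
  expect_error(build_diffusion_operator(g, rep(0, 61), 2e-7),
               "identically zero")
})

test_that("slowest diffusion mode of a flat distribution matches the analytic rate", {
  # cell-centred Neumann discretisation: continuum rate pi^2 D / L^2 with
  # L = n h; checked against a dense eigensolve of the generator
  g <- radial_grid(0.5, 1.5, 101)
  flat <- distance_distribution("normal", 1.0, 1e6)   # flat on the grid
  D <- 2e-7
  dop <- build_diffusion_operator(g, flat, D)
  ev <- sort(abs(Re(eigen(dop$W, only.values = TRUE)$values)))
  L <- g$n_points * g$h
  analytic <- pi^2 * (D * 1e14) / L^2
  expect_lt(ev[1], 1e-6 * analytic)            # conserved mode
  expect_equal(ev[2], analytic, tolerance = 0.02 * analytic)
})
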