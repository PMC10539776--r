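# Validation of the reduced-basis stochastic Liouville solver against an
# independently coded dense complex brute-force resolvent.

test_that("full solver agrees with the dense brute-force resolvent on a 2-node grid", {
  g <- radial_grid(0.6, 0.9, 2)
  dist <- distance_distribution("normal", 0.85, 0.1)
  w <- distribution_weights(dist, g)
  sp <- biradical_spin_params(A_add = 0, n_add = 0L)
  ex <- exchange_model()
  kin <- kinetics_relaxation_params()
  model <- biradical_model(spins = sp, exchange = ex, kinetics = kin)

  J <- exchange_coupling(g$nodes, ex)
  J <- sign(J) * pmin(abs(J), model$J_cap)
  hop <- kin$D * 1e14 / g$h^2

  for (B in c(4e-3, 0.05, 1)) {
    p_pkg <- geminate_polarization(B, model, g, dist)
    p_ref <- or_two_node_polarization(
      B, J[1], J[2], w, hop,
      or_default_spins(A = sp$A, ga = sp$ga, gb = sp$gb),
      or_default_kin(G = kin$G, tau_u = kin$tau_u, kp = kin$kp, ks = kin$ks))
    expect_equal(p_pkg, p_ref, tolerance = 1e-8)
  }
})

test_that("quantum equivalent-nuclei treatment matches a semiclassical limit check and conserves component weights", {
  dec <- cidnpr:::.equivalent_spin_decomposition(4L)
  expect_equal(dec$two_j, c(4L, 2L, 0L))
  expect_equal(dec$weight, c(5, 9, 2) / 16)
  expect_equal(sum(dec$weight), 1)
  dec1 <- cidnpr:::.equivalent_spin_decomposition(1L)
  expect_equal(dec1$two_j, 1L)
  expect_equal(dec1$weight, 1)
})

test_that("reduced-basis projection round-trips Fz-block-diagonal Hermitian matrices", {
  eng <- cidnpr:::.spin_engine(0L)
  bs <- eng$basis
  nrm <- cidnpr:::.basis_norms(bs)
  set.seed(11)
  # random Hermitian matrix projected onto the invariant subspace and back
  A <- matrix(rnorm(64) + 1i * rnorm(64), 8, 8)
  A <- (A + Conj(t(A))) / 2
  cf <- cidnpr:::.project(bs, A) / nrm
  A2 <- Reduce(`+`, lapply(seq_len(bs$n), function(k) {
    cf[k] * cidnpr:::.basis_matrix(bs, k, 8L)
  }))
  cf2 <- cidnpr:::.project(bs, A2) / nrm
  expect_equal(cf, cf2, tolerance = 1e-12)
  # the projection keeps exactly the Fz-block-diagonal part of A
  Fz_state <- c(1.5, 0.5, 0.5, -0.5, 0.5, -0.5, -0.5, -1.5)
  same_block <- outer(Fz_state, Fz_state, `==`)
  expect_equal(A2, A * same_block, tolerance = 1e-12)
})

test_that("trace bookkeeping: with kp = ks = 0 the generator conserves the total trace", {
  eng <- cidnpr:::.spin_engine(0L)
  sp <- biradical_spin_params()
  kin <- kinetics_relaxation_params(kp = 0, ks = 0)
  for (B in c(1e-3, 0.1, 5)) {
    base <- cidnpr:::.base_generator(eng, B, sp, kin, offset_mT = 0.7,
                                     quantum_hfb = FALSE)
    # exchange term is traceless too
    gen <- base + (-2 * cidnpr:::.mT) * eng$R_exch
    drift <- as.numeric(eng$v_tr %*% gen)
    expect_lt(max(abs(drift)), 1e-10 * max(abs(gen)))
  }
})

test_that("block-Thomas elimination equals a dense solve of the assembled system", {
  set.seed(42)
  ns <- 7; n <- 5
  D <- lapply(1:n, function(i) matrix(rnorm(ns^2), ns) + diag(ns) * 8)
  sub <- rnorm(n - 1); sup <- rnorm(n - 1)
  M <- matrix(0, ns * n, ns * n)
  for (i in 1:n) {
    ix <- (i - 1) * ns + 1:ns
    M[ix, ix] <- D[[i]]
    if (i < n) {
      M[ix, ix + ns] <- diag(ns) * sup[i]
      M[ix + ns, ix] <- diag(ns) * sub[i]
    }
  }
  b <- rnorm(ns * n)
  x1 <- cidnpr:::.block_thomas_solve(D, sub, sup, b)
  x2 <- solve(M, b)
  expect_equal(x1, as.numeric(x2), tolerance = 1e-10)
})

test_that("the geminate and scavenging yields account for all pairs", {
  g <- radial_grid(n_points = 21)
  out <- geminate_polarization(0.05, biradical_model(), g,
                               distribution_preset("sim1"), details = TRUE)
  expect_equal(out$recombination_yield + out$scavenging_yield, 1,
               tolerance = 1e-8)
  expect_true(out$recombination_yield > 0 && out$scavenging_yield > 0)
})
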