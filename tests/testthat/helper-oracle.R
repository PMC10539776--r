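# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: the spin
# space is built in the plain product basis, the Liouvillian as a dense
# complex matrix via vec() Kronecker identities, and the resolvent is
# solved with base::solve on the full complex system.

.or_const <- list(
  muB_hbar = 9.2740100783e-24 / 1.054571817e-34,
  gammae_mT = 1.76085963023e11 * 1e-3
)

or_spin_half <- function() {
  sz <- matrix(c(0.5, 0, 0, -0.5), 2, 2)
  sp <- matrix(c(0, 0, 1, 0), 2, 2)   # S+ |beta> = |alpha>
  list(z = sz, p = sp, m = t(sp),
       x = (sp + t(sp)) / 2, y = (sp - t(sp)) / (2i))
}

# operators on electron a x electron b x nucleus (8-dim product basis)
or_ops <- function() {
  s <- or_spin_half(); I2 <- diag(2)
  k3 <- function(a, b, c) kronecker(kronecker(a, b), c)
  ops <- list(
    Saz = k3(s$z, I2, I2), Sap = k3(s$p, I2, I2), Sam = k3(s$m, I2, I2),
    Sbz = k3(I2, s$z, I2), Sbp = k3(I2, s$p, I2), Sbm = k3(I2, s$m, I2),
    Iz = k3(I2, I2, s$z)
  )
  ops$SaSb <- k3(s$x, s$x, I2) + k3(s$y, s$y, I2) + k3(s$z, s$z, I2)
  ops$SaI <- k3(s$x, I2, s$x) + k3(s$y, I2, s$y) + k3(s$z, I2, s$z)
  ops$QS <- 0.25 * diag(8) - ops$SaSb
  ops
}

# vec(A X B) = (t(B) %x% A) vec(X), column-major stacking
or_comm <- function(H) {
  d <- nrow(H)
  -1i * (kronecker(diag(d), H) - kronecker(t(H), diag(d)))
}
or_lind <- function(L) {
  d <- nrow(L)
  Ld <- Conj(t(L)); LdL <- Ld %*% L
  kronecker(Conj(L), L) -
    0.5 * (kronecker(diag(d), LdL) + kronecker(t(LdL), diag(d)))
}
or_sink <- function(P) {
  d <- nrow(P)
  -0.5 * (kronecker(diag(d), P) + kronecker(t(P), diag(d)))
}

# full complex Liouvillian for one radial node (8-level space, no
# additional nuclei), per the same physical model as the package defaults
or_node_liouvillian <- function(B, J_mT, spins, kin, with_kp = FALSE) {
  o <- or_ops()
  wa <- spins$ga * .or_const$muB_hbar * B
  wb <- spins$gb * .or_const$muB_hbar * B
  H <- wa * o$Saz + wb * o$Sbz + spins$A * .or_const$gammae_mT * o$SaI -
    J_mT * .or_const$gammae_mT * (0.5 * diag(8) + 2 * o$SaSb)
  kfa <- kin$G * kin$tau_u / (1 + (wa * kin$tau_u)^2)
  kfb <- kin$G * kin$tau_u / (1 + (wb * kin$tau_u)^2)
  kz <- 2 * kin$G * kin$tau_u
  L <- or_comm(H) +
    kfa * (or_lind(o$Sap) + or_lind(o$Sam)) +
    kfb * (or_lind(o$Sbp) + or_lind(o$Sbm)) +
    kz * (or_lind(o$Saz) + or_lind(o$Sbz))
  if (with_kp) L <- L + kin$kp * or_sink(o$QS)
  L - kin$ks * diag(64)
}

# brute-force geminate polarization on a 2-node grid: node 1 = contact
# (recombination), node 2 carries exchange J2; hopping rates from the
# detailed-balance discretisation of the two-point distribution
or_two_node_polarization <- function(B, J1_mT, J2_mT, w, hop, spins, kin) {
  o <- or_ops()
  L1 <- or_node_liouvillian(B, J1_mT, spins, kin, with_kp = TRUE)
  L2 <- or_node_liouvillian(B, J2_mT, spins, kin, with_kp = FALSE)
  up <- hop * sqrt(w[2] / w[1])   # 1 -> 2
  dn <- hop * sqrt(w[1] / w[2])   # 2 -> 1
  I64 <- diag(64)
  M <- rbind(cbind(L1 - up * I64, dn * I64),
             cbind(up * I64, L2 - dn * I64))
  rho0 <- (diag(8) - o$QS) / 6
  b <- c(w[1] * as.vector(rho0), w[2] * as.vector(rho0))
  x <- solve(M, -b)
  obs <- o$QS %*% o$Iz
  # tr(O rho) = vec(t(O)) . vec(rho)
  Re(kin$kp * sum(as.vector(t(obs)) * x[1:64]))
}

# convenience: default-parameter lists for oracle functions
or_default_spins <- function(A = -0.7, ga = 2.0034, gb = 2.0035) {
  list(ga = ga, gb = gb, A = A)
}
or_default_kin <- function(G = 6.1e17, tau_u = 1e-12, kp = 2e10, ks = 1e5) {
  list(G = G, tau_u = tau_u, kp = kp, ks = ks)
}
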