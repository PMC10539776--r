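#' Spin Hamiltonian of the biradical at fixed distance
#'
#' Builds the coherent Hamiltonian on the 8-level space of the two radical
#' electrons and the observed spin-1/2 nucleus: Zeeman terms for both
#' electrons, the full isotropic hyperfine coupling of the observed nucleus
#' to electron a (including flip-flop terms), the exchange term
#' \eqn{-J(r)(\tfrac12 + 2 S_a\cdot S_b)}, and a static offset
#' `m_add * A_add` on electron b representing additional nuclei in a fixed
#' total projection state.
#'
#' Basis ordering: \eqn{|m_a m_b m_n\rangle} with \eqn{\alpha} before
#' \eqn{\beta}, electron a slowest, nucleus fastest.
#'
#' @param B Magnetic field, T.
#' @param r Inter-radical distance, nm.
#' @param spins A [biradical_spin_params()].
#' @param exch An [exchange_model()].
#' @param m_add Total projection of the additional nuclei (e.g. -2..2 for
#'   four spin-1/2 nuclei).
#'
#' @return An 8 x 8 complex Hermitian matrix in angular frequency units
#'   (rad/s).
#' @export
build_hamiltonian <- function(B, r, spins = biradical_spin_params(),
                              exch = exchange_model(), m_add = 0) {
  stopifnot(inherits(spins, "biradical_spin_params"),
            inherits(exch, "exchange_model"),
            is.numeric(B), length(B) == 1, is.numeric(r), length(r) == 1)
  e <- .spin_ops(1L)
  k3 <- function(a, b, c) kronecker(kronecker(a, b), c)
  I2 <- diag(2)
  Saz <- k3(e$z, I2, I2); Sap <- k3(e$p, I2, I2); Sam <- t(Sap)
  Sbz <- k3(I2, e$z, I2); Sbp <- k3(I2, e$p, I2); Sbm <- t(Sbp)
  Iz <- k3(I2, I2, e$z);  Ip <- k3(I2, I2, e$p);  Im <- t(Ip)
  SaSb <- 0.5 * (Sap %*% Sbm + Sam %*% Sbp) + Saz %*% Sbz
  SaI <- 0.5 * (Sap %*% Im + Sam %*% Ip) + Saz %*% Iz
  J <- exchange_coupling(r, exch) * .mT
  (spins$ga * .mu_B_over_hbar * B) * Saz +
    (spins$gb * .mu_B_over_hbar * B) * Sbz +
    (spins$A * .mT) * SaI +
    (spins$A_add * .mT * m_add) * Sbz -
    J * (0.5 * diag(8) + 2 * SaSb)
}

#' Electron spin relaxation generator
#'
#' Relaxation by uncorrelated fluctuating local fields at the two electrons,
#' with single-quantum flip rates given by the Lorentzian spectral density
#' \eqn{G\,\tau_u/(1+\omega^2\tau_u^2)} evaluated at each electron's Zeeman
#' frequency, plus a secular dephasing channel at the zero-frequency rate
#' \eqn{G\,\tau_u}.  Returned as a superoperator on the two-electron space
#' (column-major `vec` convention, 16 x 16).
#'
#' @param B Magnetic field, T.
#' @param kin A [kinetics_relaxation_params()].
#' @param spins A [biradical_spin_params()] supplying the g factors.
#'
#' @return A real 16 x 16 matrix `L` such that `d vec(rho)/dt = L vec(rho)`.
#' @export
build_relaxation <- function(B, kin = kinetics_relaxation_params(),
                             spins = biradical_spin_params()) {
  stopifnot(inherits(kin, "kinetics_relaxation_params"),
            is.numeric(B), length(B) == 1)
  if (kin$tau_u <= 0) stop("`tau_u` must be positive", call. = FALSE)
  e <- .spin_ops(1L)
  I2 <- diag(2)
  Sap <- kronecker(e$p, I2); Sam <- kronecker(e$m, I2)
  Sbp <- kronecker(I2, e$p); Sbm <- kronecker(I2, e$m)
  Saz <- kronecker(e$z, I2); Sbz <- kronecker(I2, e$z)
  lind <- function(L, rate) {
    Ld <- Conj(t(L)); LdL <- Ld %*% L
    rate * (kronecker(Conj(L), L) -
              0.5 * (kronecker(diag(4), LdL) + kronecker(t(LdL), diag(4))))
  }
  wa <- spins$ga * .mu_B_over_hbar * B
  wb <- spins$gb * .mu_B_over_hbar * B
  kfa <- .flip_rate(wa, kin$G, kin$tau_u)
  kfb <- .flip_rate(wb, kin$G, kin$tau_u)
  kz <- 2 * kin$G * kin$tau_u
  out <- lind(Sap, kfa) + lind(Sam, kfa) + lind(Sbp, kfb) + lind(Sbm, kfb) +
    lind(Saz, kz) + lind(Sbz, kz)
  stopifnot(max(abs(Im(out))) < 1e-8 * max(abs(Re(out)), 1e-300))
  Re(out)
}

#' Discrete Smoluchowski diffusion generator on a radial grid
#'
#' Nearest-neighbour hopping generator whose unique stationary vector is the
#' discretised distance distribution, with reflecting boundaries.  Hopping
#' rates obey detailed balance,
#' \eqn{w_{i\to i\pm1} = (D/h^2)\sqrt{p_{i\pm1}/p_i}}, so columns sum to
#' zero (probability conservation) and `W %*% p = 0` exactly.
#'
#' @param grid A [radial_grid()].
#' @param dist A [distance_distribution()], discretised internally via
#'   [distribution_weights()].
#' @param D Radial diffusion coefficient, cm\eqn{^2} s\eqn{^{-1}}.
#'
#' @return A list with `W` (n x n generator matrix, s\eqn{^{-1}}) and
#'   `weights` (the stationary distribution).
#' @export
build_diffusion_operator <- function(grid, dist, D) {
  stopifnot(inherits(grid, "radial_grid"), is.numeric(D), length(D) == 1,
            D >= 0)
  w <- if (inherits(dist, "distance_distribution")) {
    distribution_weights(dist, grid)
  } else {
    stopifnot(is.numeric(dist), length(dist) == grid$n_points)
    if (all(dist == 0)) stop("distribution is identically zero on the grid",
                             call. = FALSE)
    dist / sum(dist)
  }
  n <- grid$n_points
  hop <- (D * 1e14) / grid$h^2          # cm^2/s -> nm^2/s
  W <- matrix(0, n, n)
  # nodes with (numerically) zero stationary weight carry no population and
  # are left disconnected, which keeps the detailed-balance rates finite for
  # truncated distributions
  live <- w > 1e-13
  for (i in seq_len(n - 1L)) {
    if (!live[i] || !live[i + 1L]) next
    up <- hop * sqrt(w[i + 1L] / w[i])   # i -> i+1
    dn <- hop * sqrt(w[i] / w[i + 1L])   # i+1 -> i
    W[i + 1L, i] <- W[i + 1L, i] + up
    W[i, i] <- W[i, i] - up
    W[i, i + 1L] <- W[i, i + 1L] + dn
    W[i + 1L, i + 1L] <- W[i + 1L, i + 1L] - dn
  }
  list(W = W, weights = w)
}
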