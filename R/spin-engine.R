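# Internal spin-dynamics engine.
#
# State space: electron a x electron b x observed nucleus (spin 1/2) x
# effective additional nucleus on radical b (spin j, j from the equivalent-
# nuclei decomposition, or absent for the semiclassical path).
#
# The full Liouvillian preserves (i) hermiticity, (ii) block-diagonality in
# the total z projection Fz (every Hamiltonian term conserves Fz and every
# dissipator shifts bra and ket projections equally), and the initial state
# lies in that invariant subspace.  The density matrix is therefore expanded
# in an orthonormal real basis of Fz-block-diagonal Hermitian matrices,
# which turns the complex Liouville dynamics into a real linear system of
# dimension sum(s_k^2) over Fz blocks (20 for the 8-level space) instead of
# the complex d^2 problem.

.spin_ops <- function(two_j) {
  d <- two_j + 1L
  m <- seq(two_j / 2, -two_j / 2, by = -1)
  z <- diag(m, d, d)
  p <- matrix(0, d, d)
  if (d > 1L) {
    for (k in 2:d) {
      p[k - 1L, k] <- sqrt((two_j / 2) * (two_j / 2 + 1) - m[k] * (m[k] + 1))
    }
  }
  list(z = z, p = p, m = t(p), id = diag(d))
}

# Hermitian basis of the Fz-block-diagonal subspace, stored as triplets
# (row, col, coef) grouped by element id.  Primitive elements are |i><i|,
# X = e_ij + e_ji and Y = i e_ij - i e_ji (integer coefficients, diagonal
# Gram matrix): with dyadic coefficients every reduced operator of the
# spin-1/2 engine is exact, so structural zeros survive in floating point.
#
# Elements whose bra and ket share the observed-nucleus projection are then
# recombined pairwise with their both-indices-flipped partner into
# symmetric/antisymmetric combinations.  This aligns the nuclear-trivial
# sector (density matrices proportional to the identity on the observed
# nucleus) with coordinate axes: when every hyperfine term of that nucleus
# vanishes the generator decouples from the nuclear-polarization sector
# with exact zeros, and symmetry-protected observables vanish to the last
# bit instead of floating-point solve noise.
.block_basis <- function(Fz, flip = NULL) {
  blocks <- split(seq_along(Fz), round(2 * Fz))
  ei <- integer(0); tr_ <- integer(0); tc_ <- integer(0)
  cf <- complex(0)
  n <- 0L
  add <- function(rows, cols, coefs) {
    n <<- n + 1L
    ei <<- c(ei, rep(n, length(rows)))
    tr_ <<- c(tr_, rows); tc_ <<- c(tc_, cols); cf <<- c(cf, coefs)
  }
  prim <- list()
  for (bl in blocks) {
    for (i in bl) prim[[length(prim) + 1L]] <- list(i = i, j = i, type = "d")
    if (length(bl) > 1L) {
      for (a in seq_along(bl)) for (b in seq_along(bl)) if (a < b) {
        prim[[length(prim) + 1L]] <- list(i = bl[a], j = bl[b], type = "x")
        prim[[length(prim) + 1L]] <- list(i = bl[a], j = bl[b], type = "y")
      }
    }
  }
  trip <- function(p) {
    switch(p$type,
      d = list(r = p$i, c = p$i, v = 1 + 0i),
      x = list(r = c(p$i, p$j), c = c(p$j, p$i), v = c(1 + 0i, 1 + 0i)),
      y = list(r = c(p$i, p$j), c = c(p$j, p$i), v = c(1i, -1i)))
  }
  if (is.null(flip)) {
    for (p in prim) { t <- trip(p); add(t$r, t$c, t$v) }
  } else {
    key <- vapply(prim, function(p) paste(p$i, p$j, p$type), "")
    done <- logical(length(prim))
    for (k in seq_along(prim)) {
      if (done[k]) next
      p <- prim[[k]]
      same_n <- flip$nuc[p$i] == flip$nuc[p$j]
      if (!same_n) {
        t <- trip(p); add(t$r, t$c, t$v); done[k] <- TRUE
        next
      }
      i2 <- flip$partner[p$i]; j2 <- flip$partner[p$j]
      k2 <- match(paste(min(i2, j2), max(i2, j2), p$type), key)
      if (is.na(k2) || k2 == k) {
        t <- trip(p); add(t$r, t$c, t$v); done[k] <- TRUE
        next
      }
      t1 <- trip(p); t2 <- trip(prim[[k2]])
      add(c(t1$r, t2$r), c(t1$c, t2$c), c(t1$v, t2$v))
      add(c(t1$r, t2$r), c(t1$c, t2$c), c(t1$v, -t2$v))
      done[k] <- TRUE; done[k2] <- TRUE
    }
  }
  list(ei = ei, row = tr_, col = tc_, coef = cf, n = n)
}

.basis_matrix <- function(bs, k, d) {
  E <- matrix(0 + 0i, d, d)
  sel <- bs$ei == k
  E[cbind(bs$row[sel], bs$col[sel])] <- bs$coef[sel]
  E
}

.basis_norms <- function(bs) {
  as.numeric(rowsum(abs(bs$coef)^2, bs$ei)[, 1])
}

# dual projection: out_k = Re tr(E_k M) = Re sum_t coef_t M[col_t, row_t]
.project <- function(bs, M) {
  vals <- Re(bs$coef * M[cbind(bs$col, bs$row)])
  as.numeric(rowsum(vals, bs$ei)[, 1])
}

# reduce a superoperator (function on d x d matrices) to the real basis;
# entries that vanish analytically but pick up ~1e-17-relative residue from
# the irrational basis normalisation are chopped, so structural symmetries
# (e.g. no nuclear-polarization pathway when every hyperfine term is zero)
# hold exactly
.reduce_superop <- function(bs, d, f) {
  R <- matrix(0, bs$n, bs$n)
  nrm <- .basis_norms(bs)
  for (k in seq_len(bs$n)) {
    R[, k] <- .project(bs, f(.basis_matrix(bs, k, d))) / nrm
  }
  top <- max(abs(R))
  if (top > 0) R[abs(R) < 1e-13 * top] <- 0
  R
}

.comm_gen <- function(H) function(rho) -1i * (H %*% rho - rho %*% H)
.lind_gen <- function(L) {
  Ld <- Conj(t(L)); LdL <- Ld %*% L
  function(rho) L %*% rho %*% Ld - 0.5 * (LdL %*% rho + rho %*% LdL)
}
.sink_gen <- function(P) function(rho) -0.5 * (P %*% rho + rho %*% P)

# Build (and cache) the reduced operator set for additional-nucleus spin
# two_jb/2.  All couplings are per unit angular frequency; rates per unit
# rate constant.
.engine_cache <- new.env(parent = emptyenv())

.spin_engine <- function(two_jb) {
  key <- as.character(two_jb)
  if (!is.null(.engine_cache[[key]])) return(.engine_cache[[key]])

  ea <- .spin_ops(1L); nb <- .spin_ops(as.integer(two_jb))
  k4 <- function(a, b, c, d) kronecker(kronecker(kronecker(a, b), c), d)
  I2 <- diag(2)
  d <- 8L * (two_jb + 1L)

  Saz <- k4(ea$z, I2, I2, nb$id); Sap <- k4(ea$p, I2, I2, nb$id)
  Sbz <- k4(I2, ea$z, I2, nb$id); Sbp <- k4(I2, ea$p, I2, nb$id)
  Iaz <- k4(I2, I2, ea$z, nb$id); Iap <- k4(I2, I2, ea$p, nb$id)
  Ibz <- k4(I2, I2, I2, nb$z);    Ibp <- k4(I2, I2, I2, nb$p)
  Sam <- t(Sap); Sbm <- t(Sbp); Iam <- t(Iap); Ibm <- t(Ibp)

  SaSb <- 0.5 * (Sap %*% Sbm + Sam %*% Sbp) + Saz %*% Sbz
  SaIa <- 0.5 * (Sap %*% Iam + Sam %*% Iap) + Saz %*% Iaz
  SbIb <- 0.5 * (Sbp %*% Ibm + Sbm %*% Ibp) + Sbz %*% Ibz
  QS <- 0.25 * diag(d) - SaSb          # singlet projector

  Fz <- diag(Saz + Sbz + Iaz + Ibz)
  db <- two_jb + 1L
  s <- seq_len(d)
  nuc <- ((s - 1L) %/% db) %% 2L          # observed-nucleus projection index
  bs <- .block_basis(Fz, flip = list(nuc = nuc,
                                     partner = s + db * (1L - 2L * nuc)))

  red <- function(f) .reduce_superop(bs, d, f)
  eng <- list(
    dim = d, n = bs$n, basis = bs,
    # coherent parts, per unit angular frequency of the coefficient
    R_za   = red(.comm_gen(Saz)),
    R_zb   = red(.comm_gen(Sbz)),
    R_hfa  = red(.comm_gen(SaIa)),
    R_hfb  = red(.comm_gen(SbIb)),
    R_exch = red(.comm_gen(0.5 * diag(d) + 2 * SaSb)),
    # dissipators, per unit rate
    R_fap = red(.lind_gen(Sap)), R_fam = red(.lind_gen(Sam)),
    R_fbp = red(.lind_gen(Sbp)), R_fbm = red(.lind_gen(Sbm)),
    R_dza = red(.lind_gen(Saz)), R_dzb = red(.lind_gen(Sbz)),
    # singlet-projected recombination sink, per unit rate
    R_sink = red(.sink_gen(QS)),
    # observables / states as coordinate vectors
    v_obs  = .project(bs, QS %*% Iaz),
    v_iz   = .project(bs, Iaz),
    v_tr   = .project(bs, diag(d) + 0i),
    v_qs   = .project(bs, QS + 0i),
    rho0   = .project(bs, (diag(d) - QS) / (6 * (two_jb + 1))) /
      .basis_norms(bs)
  )
  .engine_cache[[key]] <- eng
  eng
}

# decomposition of n equivalent spin-1/2 nuclei into total-spin multiplets:
# returns two_j values and their statistical weights (multiplicity x state
# count / 2^n)
.equivalent_spin_decomposition <- function(n) {
  if (n == 0L) return(list(two_j = 0L, weight = 1))
  two_j <- seq(n %% 2L, n, by = 2L)
  mult <- vapply(two_j, function(tj) {
    k <- (n - tj) / 2
    choose(n, k) - if (k >= 1) choose(n, k - 1) else 0
  }, 0)
  list(two_j = as.integer(rev(two_j)),
       weight = rev(mult * (two_j + 1)) / 2^n)
}

# spectral density of the fluctuating local field; rates per the
# Lorentzian G * tau / (1 + (omega tau)^2)
.flip_rate <- function(omega, G, tau) G * tau / (1 + (omega * tau)^2)

# per-field spin-space generator (reduced basis), excluding exchange,
# diffusion and sinks, for one engine and one semiclassical offset (mT)
.base_generator <- function(eng, B, spins, kin, offset_mT = 0,
                            quantum_hfb = FALSE) {
  wa <- spins$ga * .mu_B_over_hbar * B
  wb <- spins$gb * .mu_B_over_hbar * B
  kfa <- .flip_rate(wa, kin$G, kin$tau_u)
  kfb <- .flip_rate(wb, kin$G, kin$tau_u)
  kz <- 2 * kin$G * kin$tau_u
  base <- wa * eng$R_za + wb * eng$R_zb + spins$A * .mT * eng$R_hfa +
    kfa * (eng$R_fap + eng$R_fam) + kfb * (eng$R_fbp + eng$R_fbm) +
    kz * (eng$R_dza + eng$R_dzb)
  if (quantum_hfb) base <- base + spins$A_add * .mT * eng$R_hfb
  if (offset_mT != 0) base <- base + offset_mT * .mT * eng$R_zb
  base
}
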