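# Physical constants (CODATA 2018), internal units: angular frequency in rad/s,
# magnetic field in tesla, couplings accepted in millitesla.

# Bohr magneton over hbar: rad s^-1 T^-1 per unit g factor
.mu_B_over_hbar <- 9.2740100783e-24 / 1.054571817e-34

# free-electron gyromagnetic ratio, rad s^-1 T^-1 (used to convert couplings
# quoted in field units to angular frequency)
.gamma_e <- 1.76085963023e11

#' Proton gyromagnetic ratio
#'
#' Constant \eqn{\gamma_H = 2.6752218744 \times 10^8} rad s\eqn{^{-1}}
#' T\eqn{^{-1}}, used throughout the NMRD dispersion model.
#'
#' @format A length-one numeric.
#' @export
gamma_H <- 2.6752218744e8

# rad/s per mT for a coupling quoted in field units
.mT <- .gamma_e * 1e-3
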