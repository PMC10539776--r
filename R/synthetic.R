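#' Configuration of a synthetic field-cycling study
#'
#' Ground truths and noise levels used by the synthetic-data generators,
#' emulating the statistical structure of a fast-field-cycling CIDNP/NMRD
#' experiment: mono-exponential inversion-recovery decays obeying the
#' Lorentzian dispersion model, a monotone shuttle field--time profile from
#' millitesla fields to the detection field, and noisy emissive CIDNP
#' curves.
#'
#' The default proton set mirrors the aromatic/ribityl protons followed in
#' the FAD study (A8, A2, F6, F9, F5'5''), with distinct sub-nanosecond
#' correlation times of the same order so that site-specificity is
#' meaningful, and the A8 proton given the fastest low-field relaxation
#' (its transfer losses are of order one half).
#'
#' @param protons Tibble with columns `proton`, `R1`, `R1inf` (s\eqn{^{-1}})
#'   and `tau_c` (s): per-proton dispersion truths.
#' @param decay_noise Relative (multiplicative Gaussian) noise on decay
#'   intensities.
#' @param cidnp_noise Relative noise on observed CIDNP intensities.
#' @param detection_field Detection field of the spectrometer, T.
#' @param transfer_duration Shuttle transfer time, s.  Chosen comparable to
#'   the proton T1 values so relaxation losses during transfer matter.
#' @param n_profile_points Number of samples in a generated transfer
#'   profile.
#' @param seed Default seed used by the generators.
#'
#' @return A list of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(
    protons = tibble::tibble(
      proton = c("A8", "A2", "F6", "F9", "F5p"),
      R1 = c(4.0, 2.5, 3.0, 2.0, 1.5),
      R1inf = c(0.5, 0.4, 0.6, 0.5, 0.9),
      tau_c = c(0.9, 0.85, 0.95, 0.8, 0.7) * 1e-9),
    decay_noise = 0.03,
    cidnp_noise = 0.02,
    detection_field = 9.4,
    transfer_duration = 0.3,
    n_profile_points = 201L,
    seed = 1L) {
  stopifnot(is.data.frame(protons),
            all(c("proton", "R1", "R1inf", "tau_c") %in% names(protons)),
            decay_noise >= 0, cidnp_noise >= 0,
            transfer_duration > 0, detection_field > 0)
  structure(
    list(protons = tibble::as_tibble(protons), decay_noise = decay_noise,
         cidnp_noise = cidnp_noise, detection_field = detection_field,
         transfer_duration = transfer_duration,
         n_profile_points = as.integer(n_profile_points),
         seed = as.integer(seed)),
    class = "synthetic_study_config"
  )
}

# run code with a private RNG stream so generators are pure in (config, seed)
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate synthetic inversion-recovery decay series
#'
#' For every proton in the configuration and every requested relaxation
#' field, draws a mono-exponential inversion-recovery decay with
#' \eqn{T_1(B) = 1/R_1^{tot}(B)} from the configured dispersion truths and
#' multiplicative Gaussian noise.  Twelve delays span 0 to three times the
#' local T1.
#'
#' @param cfg A [synthetic_study_config()].
#' @param fields Relaxation fields, T.
#' @param n_delays Delays per decay.
#' @param seed Seed (defaults to `cfg$seed`); same seed, same output.
#'
#' @return A tibble with columns `proton`, `B_T`, `tau_vd_s`, `intensity`.
#'   The ground-truth table is attached as attribute `"truth"`.
#' @export
gen_nmrd_decays <- function(cfg, fields, n_delays = 12L, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_study_config"), is.numeric(fields),
            all(fields >= 0), n_delays >= 4)
  .with_seed(seed, {
    out <- purrr::pmap_dfr(cfg$protons, function(proton, R1, R1inf, tau_c) {
      purrr::map_dfr(fields, function(B) {
        T1 <- 1 / eq1_rate(B, R1, R1inf, tau_c)
        tau <- seq(0, 3 * T1, length.out = n_delays)
        ideal <- 1 - 2 * exp(-tau / T1)
        tibble::tibble(
          proton = proton, B_T = B, tau_vd_s = tau,
          intensity = ideal * (1 + cfg$decay_noise *
                                 stats::rnorm(length(tau))))
      })
    })
    attr(out, "truth") <- cfg$protons
    out
  })
}

#' Generate a shuttle transfer field--time profile
#'
#' Parametric model of the mechanical sample shuttle: the sample moves from
#' the low-field position to the detection position with constant
#' acceleration over the first half of the transfer and constant
#' deceleration over the second half, through the stray field of the
#' magnet, which decays exponentially along the bore.  The decay length is
#' set per start field so the profile runs exactly from `B_start` to the
#' detection field; `B(t)` is monotone non-decreasing.
#'
#' @param cfg A [synthetic_study_config()].
#' @param B_start Field at the start position, T, below the detection
#'   field.
#'
#' @return A [transfer_profile()].
#' @export
gen_transfer_profile <- function(cfg, B_start) {
  stopifnot(inherits(cfg, "synthetic_study_config"),
            is.numeric(B_start), length(B_start) == 1, B_start > 0)
  if (B_start >= cfg$detection_field) {
    stop("`B_start` must be below the detection field", call. = FALSE)
  }
  tt <- seq(0, cfg$transfer_duration, length.out = cfg$n_profile_points)
  u <- tt / cfg$transfer_duration
  s <- ifelse(u < 0.5, 2 * u^2, 1 - 2 * (1 - u)^2)   # fractional bore position
  B <- B_start * (cfg$detection_field / B_start)^s
  transfer_profile(tt, B, start_field = B_start)
}

#' Transfer-profile source for a configuration
#'
#' Returns a function mapping a start field to its [gen_transfer_profile()],
#' suitable as the `profiles` argument of [deconvolve_curve()].  Fields at
#' or above the detection field map to `NULL` (no transfer, no
#' attenuation).
#'
#' @param cfg A [synthetic_study_config()].
#' @return A function `B_start -> transfer_profile` (or `NULL`).
#' @export
shuttle_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_study_config"))
  function(B) {
    if (B >= cfg$detection_field) NULL else gen_transfer_profile(cfg, B)
  }
}

#' Generate an observed (attenuated, noisy) CIDNP curve
#'
#' The inverse of [deconvolve_curve()]: divides the true polarization at
#' every field by the attenuation factor of that field's transfer profile
#' and adds multiplicative Gaussian noise.
#'
#' @param true_curve A [cidnp_curve()] of true polarizations.
#' @param cfg A [synthetic_study_config()].
#' @param rates Rate source for the observed proton (defaults to the A8
#'   dispersion truth in `cfg`).
#' @param n_intervals Passed to [attenuation_factor()].
#' @param seed Seed (defaults to `cfg$seed`).
#'
#' @return A [cidnp_curve()] with the observed intensities; the true curve
#'   and attenuation factors are attached as attributes `"truth"` and
#'   `"attenuation"`.
#' @export
gen_observed_cidnp <- function(true_curve, cfg, rates = NULL,
                               n_intervals = 500L, seed = cfg$seed) {
  stopifnot(inherits(true_curve, "data.frame"),
            all(c("field_T", "polarization") %in% names(true_curve)),
            inherits(cfg, "synthetic_study_config"))
  if (is.null(rates)) {
    a8 <- cfg$protons[cfg$protons$proton == "A8", ]
    if (nrow(a8) == 0) {
      stop("no A8 truth in the configuration: pass `rates` explicitly",
           call. = FALSE)
    }
    rates <- list(R1 = a8$R1, R1inf = a8$R1inf, tau_c = a8$tau_c)
  }
  rf <- if (is.function(rates)) rates else rate_function(rates)
  fac <- vapply(true_curve$field_T, function(B) {
    if (B >= cfg$detection_field) return(1)
    attenuation_factor(gen_transfer_profile(cfg, B), rf, n_intervals)
  }, 0)
  .with_seed(seed, {
    noise <- 1 + cfg$cidnp_noise * stats::rnorm(nrow(true_curve))
    out <- cidnp_curve(
      field_T = true_curve$field_T,
      polarization = true_curve$polarization / fac * noise,
      nucleus = true_curve$nucleus %||% "A8",
      source = "observed")
    attr(out, "truth") <- true_curve
    attr(out, "attenuation") <- fac
    out
  })
}
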