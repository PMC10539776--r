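#' Sample-transfer field--time profile
#'
#' The magnetic field experienced by the sample as a function of time while
#' it is shuttled from the polarization field to the detection field.
#'
#' @param t_s Times since transfer start, s, strictly increasing from 0.
#' @param B_T Fields, T, positive; the last value is the detection field.
#' @param start_field Optional label of the starting field (defaults to
#'   `B_T[1]`).
#'
#' @return A tibble of class `transfer_profile` with columns `t_s`, `B_T`.
#' @export
transfer_profile <- function(t_s, B_T, start_field = NULL) {
  stopifnot(is.numeric(t_s), is.numeric(B_T), length(t_s) == length(B_T),
            length(t_s) >= 2)
  if (t_s[1] != 0) stop("profile must start at t = 0", call. = FALSE)
  if (is.unsorted(t_s, strictly = TRUE)) {
    stop("`t_s` must be strictly increasing", call. = FALSE)
  }
  if (any(B_T <= 0)) stop("fields must be positive", call. = FALSE)
  out <- tibble::tibble(t_s = t_s, B_T = B_T)
  class(out) <- c("transfer_profile", class(out))
  attr(out, "start_field") <- start_field %||% B_T[1]
  attr(out, "duration") <- t_s[length(t_s)]
  out
}

#' Relaxation-rate source from NMRD data or model parameters
#'
#' Builds a function `R1(B)` used by the deconvolution.  For a measured
#' NMRD table the rate is a natural cubic spline through the knots
#' `(log10 B, 1/T1)` (exact at every knot; fields span several decades, so
#' the spline is conditioned on the log-field axis).  Outside the data
#' range the rate is clamped to the end values with a warning.  For model
#' parameters the closed-form [eq1_rate()] is used.
#'
#' @param rates Either a data frame with columns `B_T`, `T1_s` (one proton)
#'   or a list with elements `R1`, `R1inf`, `tau_c` (e.g. from
#'   [fit_dispersion()]).
#'
#' @return A function mapping field (T) to relaxation rate (s\eqn{^{-1}}).
#' @export
rate_function <- function(rates) {
  if (is.data.frame(rates)) {
    stopifnot(all(c("B_T", "T1_s") %in% names(rates)))
    if (any(rates$T1_s <= 0)) stop("T1 values must be positive",
                                   call. = FALSE)
    ord <- order(rates$B_T)
    lb <- log10(rates$B_T[ord]); rr <- 1 / rates$T1_s[ord]
    if (anyDuplicated(lb)) stop("duplicate fields in NMRD data",
                                call. = FALSE)
    if (length(lb) == 2) {
      fun <- stats::approxfun(lb, rr, rule = 2)
    } else {
      fun <- stats::splinefun(lb, rr, method = "natural")
    }
    rng <- range(lb)
    function(B) {
      stopifnot(all(B > 0))
      x <- log10(B)
      if (any(x < rng[1] - 1e-9) || any(x > rng[2] + 1e-9)) {
        warning("field outside NMRD data range: rate clamped to end value",
                call. = FALSE)
      }
      pmax(fun(pmin(pmax(x, rng[1]), rng[2])), 0)
    }
  } else if (is.list(rates) &&
             all(c("R1", "R1inf", "tau_c") %in% names(rates))) {
    function(B) eq1_rate(B, rates$R1, rates$R1inf, rates$tau_c)
  } else {
    stop("`rates` must be an NMRD data frame or a list with R1, R1inf, tau_c",
         call. = FALSE)
  }
}

#' Interpolated relaxation rate at a field
#'
#' Convenience wrapper around [rate_function()].
#'
#' @inheritParams rate_function
#' @param B Field(s), T.
#' @return Rate(s), s\eqn{^{-1}}.
#' @export
interpolate_rate <- function(rates, B) {
  rate_function(rates)(B)
}

#' Relaxation attenuation factor for one transfer
#'
#' Splits the transfer profile into `n_intervals` equal time intervals, holds
#' the field constant within each interval (value at the interval midpoint,
#' linearly interpolated from the profile), and accumulates
#' \eqn{\prod_n \exp(R_n \Delta t_n)} -- the factor by which the polarization
#' generated at the start field must be multiplied to undo relaxation losses
#' during the transfer.
#'
#' @param profile A [transfer_profile()].
#' @param rates A rate source accepted by [rate_function()], or a function
#'   `B -> rate`.
#' @param n_intervals Number of intervals (default 500).
#'
#' @return Attenuation factor, >= 1 for non-negative rates.
#' @export
attenuation_factor <- function(profile, rates, n_intervals = 500L) {
  stopifnot(inherits(profile, "data.frame"),
            all(c("t_s", "B_T") %in% names(profile)), n_intervals >= 1)
  Tdur <- profile$t_s[nrow(profile)]
  if (Tdur <= 0) stop("profile duration must be positive", call. = FALSE)
  rf <- if (is.function(rates)) rates else rate_function(rates)
  dt <- Tdur / n_intervals
  mid <- (seq_len(n_intervals) - 0.5) * dt
  Bmid <- stats::approx(profile$t_s, profile$B_T, xout = mid, rule = 2)$y
  Rn <- rf(Bmid)
  if (any(Rn < 0)) stop("negative relaxation rate encountered",
                        call. = FALSE)
  exp(sum(Rn * dt))
}

#' Reconstruct the true CIDNP field dependence
#'
#' Multiplies every point of an observed CIDNP curve by the attenuation
#' factor of its transfer profile, undoing relaxation losses during sample
#' shuttling.  Uncertainties, when present, are scaled by the same factor.
#'
#' @param observed A [cidnp_curve()] (or data frame with `field_T`,
#'   `polarization`).
#' @param profiles Either a single function `B_start -> transfer_profile`
#'   (e.g. from [gen_transfer_profile()]), or a named list of
#'   [transfer_profile()]s keyed by the observed fields (names are matched
#'   numerically with tolerance 1e-9 relative).
#' @param rates A rate source accepted by [rate_function()].
#' @param n_intervals Passed to [attenuation_factor()].
#'
#' @return A [cidnp_curve()] of the same length with corrected
#'   polarizations; the attenuation factors are stored in the
#'   `attenuation` column.
#' @export
deconvolve_curve <- function(observed, profiles, rates,
                             n_intervals = 500L) {
  stopifnot(inherits(observed, "data.frame"),
            all(c("field_T", "polarization") %in% names(observed)))
  rf <- if (is.function(rates)) rates else rate_function(rates)
  get_profile <- if (is.function(profiles)) {
    profiles
  } else {
    nm <- suppressWarnings(as.numeric(names(profiles)))
    if (anyNA(nm)) {
      stop("profile list must be named by start field (numeric)",
           call. = FALSE)
    }
    function(B) {
      k <- which(abs(nm - B) <= 1e-9 * pmax(abs(nm), abs(B)))
      if (length(k) == 0) {
        stop(sprintf("no transfer profile for field %.6g T", B),
             call. = FALSE)
      }
      profiles[[k[1]]]
    }
  }
  fac <- vapply(observed$field_T, function(B) {
    pr <- get_profile(B)
    # a NULL profile means no transfer happens at this field (observation
    # at the detection field itself): no attenuation
    if (is.null(pr)) 1 else attenuation_factor(pr, rf, n_intervals)
  }, 0)
  out <- observed
  out$polarization <- observed$polarization * fac
  if ("uncertainty" %in% names(out)) {
    out$uncertainty <- out$uncertainty * fac
  }
  out$attenuation <- fac
  if (!inherits(out, "cidnp_curve")) {
    class(out) <- c("cidnp_curve", class(out))
  }
  attr(out, "source") <- attr(observed, "source") %||% "observed"
  out
}
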