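#' CIDNP field-dependence curve
#'
#' A tibble subclass holding polarization versus magnetic field for one
#' nucleus, with strictly increasing, duplicate-free fields.
#'
#' @param field_T Magnetic fields, T, strictly increasing.
#' @param polarization Signed polarization, arbitrary units (negative =
#'   emissive by package convention).
#' @param nucleus Nucleus label (recycled).
#' @param uncertainty Optional per-point uncertainty.
#' @param source `"simulated"` or `"observed"`.
#'
#' @return A tibble of class `cidnp_curve` with columns `field_T`,
#'   `polarization`, `nucleus` (and `uncertainty` if given).
#' @export
cidnp_curve <- function(field_T, polarization, nucleus = "A8",
                        uncertainty = NULL,
                        source = c("simulated", "observed")) {
  source <- match.arg(source)
  stopifnot(is.numeric(field_T), is.numeric(polarization),
            length(field_T) == length(polarization))
  if (is.unsorted(field_T, strictly = TRUE)) {
    stop("`field_T` must be strictly increasing with no duplicates",
         call. = FALSE)
  }
  out <- tibble::tibble(field_T = field_T, polarization = polarization,
                        nucleus = nucleus)
  if (!is.null(uncertainty)) {
    stopifnot(is.numeric(uncertainty),
              length(uncertainty) == length(field_T))
    out$uncertainty <- uncertainty
  }
  class(out) <- c("cidnp_curve", class(out))
  attr(out, "source") <- source
  out
}

.as_cidnp_curve <- function(df, source = "observed") {
  cidnp_curve(df$field_T, df$polarization,
              nucleus = df$nucleus %||% "A8",
              uncertainty = df$uncertainty, source = source)
}

#' Locate and characterise the extremum of a CIDNP field dependence
#'
#' Finds interior extrema of the signed curve, reports the dominant one
#' (largest `|polarization|`; optionally restricted to the emissive branch),
#' refines its position by a local quadratic fit in log10(field), and
#' measures the full width at half maximum by linear interpolation of the
#' half-extremum crossings of `|polarization|` on the log-field axis.
#'
#' @param curve A [cidnp_curve()] with at least 5 points spanning the
#'   extremum.
#' @param branch `"dominant"` (default), `"emissive"` (most negative) or
#'   `"absorptive"` (most positive).
#'
#' @return A list of class `curve_features`: `extremum_field` (T),
#'   `extremum_amplitude` (signed), `fwhm` (T), `sign` (`"emissive"` or
#'   `"absorptive"`), and `n_extrema`, the number of interior extrema of
#'   the signed curve.
#' @export
curve_features <- function(curve, branch = c("dominant", "emissive",
                                             "absorptive")) {
  branch <- match.arg(branch)
  stopifnot(inherits(curve, "data.frame"),
            all(c("field_T", "polarization") %in% names(curve)))
  B <- curve$field_T; p <- curve$polarization
  n <- length(B)
  if (n < 5) stop("need at least 5 points", call. = FALSE)

  dp <- diff(p)
  turns <- which(dp[-1] * dp[-(n - 1)] < 0) + 1L   # strict interior turns
  flats <- which(dp == 0)
  n_extrema <- length(turns) + length(flats)
  if (n_extrema == 0) {
    stop("curve is monotone: no interior extremum", call. = FALSE)
  }

  cand <- turns
  if (branch == "emissive") cand <- cand[p[cand] < 0]
  if (branch == "absorptive") cand <- cand[p[cand] > 0]
  if (length(cand) == 0) {
    stop("no interior extremum on the requested branch", call. = FALSE)
  }
  i <- cand[which.max(abs(p[cand]))]

  # quadratic refinement around the grid optimum; exact for a symmetric
  # triangle or parabola sampled with the vertex on the grid
  sel <- max(1L, i - 1L):min(n, i + 1L)
  fit <- stats::lm.fit(cbind(1, B[sel], B[sel]^2), p[sel])
  cf <- unname(fit$coefficients)
  x0 <- if (is.finite(cf[3]) && cf[3] != 0) -cf[2] / (2 * cf[3]) else B[i]
  if (x0 < B[max(1L, i - 1L)] || x0 > B[min(n, i + 1L)]) x0 <- B[i]
  extremum_field <- x0
  extremum_amplitude <- sum(cf * c(1, x0, x0^2))

  # FWHM: linear interpolation of the half-extremum crossings of the
  # extremum branch of the signed curve
  ap <- p * sign(p[i])             # fold so the extremum branch is positive
  half <- abs(extremum_amplitude) / 2
  lo <- NA_real_; hi <- NA_real_
  if (i > 1L) for (k in seq(i, 2L)) {
    if (ap[k - 1L] < half && ap[k] >= half) {
      lo <- stats::approx(ap[(k - 1L):k], B[(k - 1L):k], xout = half)$y
      break
    }
  }
  if (i < n) for (k in seq(i, n - 1L)) {
    if (ap[k + 1L] < half && ap[k] >= half) {
      hi <- stats::approx(ap[(k + 1L):k], B[(k + 1L):k], xout = half)$y
      break
    }
  }
  fwhm <- if (is.na(lo) || is.na(hi)) NA_real_ else hi - lo

  structure(
    list(extremum_field = extremum_field,
         extremum_amplitude = extremum_amplitude,
         fwhm = fwhm,
         sign = if (extremum_amplitude < 0) "emissive" else "absorptive",
         n_extrema = n_extrema),
    class = "curve_features"
  )
}

#' @export
print.curve_features <- function(x, ...) {
  cat(sprintf("<curve_features> %s extremum at %.4g mT, amplitude %.4g, FWHM %.4g mT (%d interior extrema)\n",
              x$sign, x$extremum_field * 1e3, x$extremum_amplitude,
              x$fwhm * 1e3, x$n_extrema))
  invisible(x)
}
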