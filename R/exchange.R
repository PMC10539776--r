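#' Distance dependence of the exchange interaction
#'
#' The exchange coupling between the two radical electrons decays
#' exponentially with the inter-radical distance,
#' \eqn{J(r) = J_0 e^{-\alpha r}}.  The decay parameter printed for the
#' flavin--adenine biradical (0.214 nm) is dimensionally ambiguous, so three
#' conventions are supported:
#'
#' * `"decay_length_from_contact"` (default):
#'   \eqn{J(r) = J_0 \exp(-(r - r_c)/\lambda)} with decay length
#'   \eqn{\lambda} = `alpha`/10 nm and contact distance `r_contact`.  With
#'   the published amplitude \eqn{J_0 = -2.3\times 10^8} mT,
#'   \eqn{\lambda = 0.0214} nm and \eqn{r_c = 0.49} nm this reproduces an
#'   effective exchange of about \eqn{-2} mT at the 0.89 nm centre of the
#'   distance distribution;
#' * `"decay_length_nm"`: \eqn{J(r) = J_0 \exp(-r/\alpha)} with `alpha`
#'   read literally as a decay length in nm;
#' * `"inverse_length_per_nm"`: \eqn{J(r) = J_0 \exp(-\alpha r)} with
#'   `alpha` read as an inverse length in nm\eqn{^{-1}}.
#'
#' @param J0 Exchange amplitude in mT (signed; negative for the
#'   flavin--adenine biradical).
#' @param alpha Distance decay parameter as printed (0.214).
#' @param convention One of the three conventions above.
#' @param r_contact Contact distance in nm (used by the default convention).
#' @param lambda Decay length in nm for the default convention; defaults to
#'   `alpha / 10` (0.0214 nm), the calibration that reproduces the
#'   effective millitesla-scale coupling at 0.89 nm.
#'
#' @return An object of class `exchange_model`.
#' @examples
#' ex <- exchange_model()
#' exchange_coupling(0.89, ex)
#' @export
exchange_model <- function(J0 = -2.3e8, alpha = 0.214,
                           convention = c("decay_length_from_contact",
                                          "decay_length_nm",
                                          "inverse_length_per_nm"),
                           r_contact = 0.49, lambda = alpha / 10) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(J0), length(J0) == 1, is.numeric(alpha),
            length(alpha) == 1, alpha > 0,
            is.numeric(lambda), length(lambda) == 1, lambda > 0,
            is.numeric(r_contact), length(r_contact) == 1, r_contact >= 0)
  structure(
    list(J0 = J0, alpha = alpha, convention = convention,
         r_contact = r_contact, lambda = lambda),
    class = "exchange_model"
  )
}

#' Evaluate the exchange coupling at a distance
#'
#' @param r Distance(s) in nm, non-negative.
#' @param model An [exchange_model()].
#'
#' @return Signed exchange coupling in mT, same sign as `J0` everywhere and
#'   with magnitude non-increasing in `r`.
#' @export
exchange_coupling <- function(r, model = exchange_model()) {
  stopifnot(inherits(model, "exchange_model"), is.numeric(r))
  if (any(r < 0)) stop("distance `r` must be non-negative", call. = FALSE)
  switch(model$convention,
    decay_length_from_contact =
      model$J0 * exp(-(r - model$r_contact) / model$lambda),
    decay_length_nm = model$J0 * exp(-r / model$alpha),
    inverse_length_per_nm = model$J0 * exp(-model$alpha * r)
  )
}

#' @export
print.exchange_model <- function(x, ...) {
  cat(sprintf("<exchange_model> J0 = %.4g mT, alpha = %.4g (%s, contact %.3g nm)\n",
              x$J0, x$alpha, x$convention, x$r_contact))
  invisible(x)
}
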