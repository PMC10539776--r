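#' Plot a CIDNP field dependence
#'
#' @param object A [cidnp_curve()].
#' @param ... Unused.
#' @return A ggplot: polarization versus field on a logarithmic field axis.
#' @export
autoplot.cidnp_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$field_T * 1e3,
                               y = .data$polarization)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3,
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "magnetic field (mT)",
                  y = "polarization (a.u.)",
                  title = paste0("CIDNP field dependence (",
                                 attr(object, "source") %||% "curve", ")")) +
    ggplot2::theme_minimal()
}

#' Plot an NMRD dispersion fit
#'
#' @param object An [fit_dispersion()] result.
#' @param ... Unused.
#' @return A ggplot of measured T1 versus field with the fitted dispersion.
#' @export
autoplot.nmrd_fit <- function(object, ...) {
  d <- object$data
  bb <- 10^seq(log10(min(d$B_T)), log10(max(d$B_T)), length.out = 200)
  fit <- tibble::tibble(B_T = bb,
                        T1_s = 1 / eq1_rate(bb, object$R1, object$R1inf,
                                            object$tau_c))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$B_T, y = .data$T1_s)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fit, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "magnetic field (T)", y = "T1 (s)",
                  title = sprintf("NMRD dispersion fit (tau_c = %.3g ns)",
                                  object$tau_c * 1e9)) +
    ggplot2::theme_minimal()
}

#' Plot a model-ranking report
#'
#' @param object A [rank_models()] report.
#' @param ... Unused.
#' @return A ggplot bar chart of q values by candidate distribution.
#' @export
autoplot.q_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$model, .data$q),
                               y = .data$q)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "distance distribution model",
                  y = "q (sum of squared deviations)") +
    ggplot2::theme_minimal()
}

#' Plot a transfer profile
#'
#' @param object A [transfer_profile()].
#' @param ... Unused.
#' @return A ggplot of field versus time on a log field axis.
#' @export
autoplot.transfer_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_s, y = .data$B_T)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time since transfer start (s)",
                  y = "magnetic field (T)") +
    ggplot2::theme_minimal()
}
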