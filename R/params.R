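#' Spin parameters of the biradical
#'
#' Static magnetic parameters of the two radical electrons and their
#' nuclei.  Radical "a" carries the observed spin-1/2 nucleus with isotropic
#' hyperfine coupling `A`; radical "b" carries `n_add` additional equivalent
#' spin-1/2 nuclei with coupling `A_add` each.
#'
#' @param ga,gb g factors of radicals a and b (positive).
#' @param A Isotropic hyperfine coupling of the observed nucleus, mT.
#' @param A_add Isotropic hyperfine coupling of each additional nucleus, mT.
#' @param n_add Number of additional equivalent spin-1/2 nuclei (>= 0).
#'
#' @return An object of class `biradical_spin_params`.
#' @export
biradical_spin_params <- function(ga = 2.0034, gb = 2.0035, A = -0.7,
                                  A_add = 1.67, n_add = 4L) {
  stopifnot(is.numeric(ga), ga > 0, is.numeric(gb), gb > 0,
            is.numeric(A), length(A) == 1,
            is.numeric(A_add), length(A_add) == 1)
  n_add <- as.integer(n_add)
  if (n_add < 0) stop("`n_add` must be non-negative", call. = FALSE)
  structure(list(ga = ga, gb = gb, A = A, A_add = A_add, n_add = n_add),
            class = "biradical_spin_params")
}

#' Kinetic and relaxation parameters of the biradical
#'
#' @param D Effective radial diffusion coefficient, cm\eqn{^2} s\eqn{^{-1}}.
#' @param G Mean-square fluctuating local field at each electron,
#'   s\eqn{^{-2}}.
#' @param tau_u Correlation time of the fluctuating local field, s.
#' @param tau_rot Rotational diffusion correlation time, s.  Recorded with
#'   the parameter set; the default relaxation model does not use it (see
#'   the methods vignette).
#' @param kp Recombination rate constant from the singlet state at contact,
#'   s\eqn{^{-1}}.
#' @param ks Scavenging rate to minor products, s\eqn{^{-1}}, applied
#'   uniformly at all distances and spin states.
#'
#' @return An object of class `kinetics_relaxation_params`.
#' @export
kinetics_relaxation_params <- function(D = 2e-7, G = 6.1e17, tau_u = 1e-12,
                                       tau_rot = 800e-12, kp = 2e10,
                                       ks = 1e5) {
  vals <- c(D = D, G = G, tau_u = tau_u, tau_rot = tau_rot, kp = kp, ks = ks)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all kinetic/relaxation parameters must be finite and non-negative",
         call. = FALSE)
  }
  structure(as.list(vals), class = "kinetics_relaxation_params")
}

#' Assemble a full biradical model
#'
#' Bundles the spin parameters, exchange law and kinetics into one object
#' consumed by [geminate_polarization()] and [field_sweep()].  The defaults
#' reproduce the published parameter table for the flavin--adenine biradical
#' of FAD.
#'
#' @param spins A [biradical_spin_params()].
#' @param exchange An [exchange_model()].
#' @param kinetics A [kinetics_relaxation_params()].
#' @param additional_nuclei How the `n_add` equivalent nuclei on radical b
#'   are treated: `"quantum"` (default) couples them exactly as one
#'   effective spin per total-spin multiplet, with multiplicity weights;
#'   `"semiclassical"` replaces them by static field offsets
#'   \eqn{m A_{add}} with binomial weights.
#' @param J_cap Magnitude cap applied to the exchange coupling (mT) when
#'   building the Liouvillian.  The exponential law reaches astronomically
#'   large values at contact; couplings beyond the cap are dynamically
#'   indistinguishable (singlet-triplet mixing is fully suppressed, and the
#'   level crossing lies far above any swept field) while degrading the
#'   conditioning of the linear solve.  Default 1e4 mT, i.e. the crossing
#'   of capped nodes sits at 20 T, above the 9.4 T detection field.
#'
#' @return An object of class `biradical_model`.
#' @examples
#' m <- biradical_model()
#' @export
biradical_model <- function(spins = biradical_spin_params(),
                            exchange = exchange_model(),
                            kinetics = kinetics_relaxation_params(),
                            additional_nuclei = c("quantum", "semiclassical"),
                            J_cap = 1e4) {
  stopifnot(inherits(spins, "biradical_spin_params"),
            inherits(exchange, "exchange_model"),
            inherits(kinetics, "kinetics_relaxation_params"),
            is.numeric(J_cap), J_cap > 0)
  additional_nuclei <- match.arg(additional_nuclei)
  structure(
    list(spins = spins, exchange = exchange, kinetics = kinetics,
         additional_nuclei = additional_nuclei, J_cap = J_cap),
    class = "biradical_model"
  )
}

#' @export
print.biradical_model <- function(x, ...) {
  s <- x$spins; k <- x$kinetics
  cat("<biradical_model>\n")
  cat(sprintf("  ga = %.5g, gb = %.5g, A = %.3g mT, A_add = %.3g mT x %d (%s)\n",
              s$ga, s$gb, s$A, s$A_add, s$n_add, x$additional_nuclei))
  cat(sprintf("  J0 = %.3g mT (%s), D = %.3g cm^2/s, kp = %.3g /s, ks = %.3g /s\n",
              x$exchange$J0, x$exchange$convention, k$D, k$kp, k$ks))
  cat(sprintf("  G = %.3g s^-2, tau_u = %.3g s, tau_rot = %.3g s (unused by default)\n",
              k$G, k$tau_u, k$tau_rot))
  invisible(x)
}

#' Read or write a flat key-value model parameter file
#'
#' The file format is plain text, one `key = value` pair per line, with
#' `#` comments.  Keys follow the published parameter table: `ga`, `gb`,
#' `A`, `A_add`, `n_add`, `J0`, `alpha`, `D`, `G`, `tau_u`, `tau_rot`,
#' `kp`, `ks`, plus `convention`, `r_contact`, `lambda`,
#' `additional_nuclei` and `J_cap`.
#'
#' @param path File path.
#' @return `read_model_params()` returns a [biradical_model()];
#'   `write_model_params()` returns `path` invisibly.
#' @export
read_model_params <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop("malformed parameter line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  p <- stats::setNames(as.list(vals), keys)
  num <- function(key, default) {
    if (is.null(p[[key]])) return(default)
    x <- suppressWarnings(as.numeric(p[[key]]))
    if (is.na(x)) stop("non-numeric value for `", key, "`", call. = FALSE)
    x
  }
  chr <- function(key, default) p[[key]] %||% default
  exch <- exchange_model(
    J0 = num("J0", -2.3e8), alpha = num("alpha", 0.214),
    convention = chr("convention", "decay_length_from_contact"),
    r_contact = num("r_contact", 0.49))
  if (!is.null(p[["lambda"]])) exch$lambda <- num("lambda", exch$lambda)
  biradical_model(
    spins = biradical_spin_params(
      ga = num("ga", 2.0034), gb = num("gb", 2.0035), A = num("A", -0.7),
      A_add = num("A_add", 1.67), n_add = num("n_add", 4)),
    exchange = exch,
    kinetics = kinetics_relaxation_params(
      D = num("D", 2e-7), G = num("G", 6.1e17), tau_u = num("tau_u", 1e-12),
      tau_rot = num("tau_rot", 800e-12), kp = num("kp", 2e10),
      ks = num("ks", 1e5)),
    additional_nuclei = chr("additional_nuclei", "quantum"),
    J_cap = num("J_cap", 1e4))
}

#' @param model A [biradical_model()] to write.
#' @rdname read_model_params
#' @export
write_model_params <- function(model, path) {
  stopifnot(inherits(model, "biradical_model"))
  s <- model$spins; k <- model$kinetics; e <- model$exchange
  lines <- c(
    "# biradical model parameters",
    sprintf("ga = %.10g", s$ga), sprintf("gb = %.10g", s$gb),
    sprintf("A = %.10g", s$A), sprintf("A_add = %.10g", s$A_add),
    sprintf("n_add = %d", s$n_add),
    sprintf("J0 = %.10g", e$J0), sprintf("alpha = %.10g", e$alpha),
    sprintf("convention = %s", e$convention),
    sprintf("r_contact = %.10g", e$r_contact),
    sprintf("lambda = %.10g", e$lambda),
    sprintf("D = %.10g", k$D), sprintf("G = %.10g", k$G),
    sprintf("tau_u = %.10g", k$tau_u), sprintf("tau_rot = %.10g", k$tau_rot),
    sprintf("kp = %.10g", k$kp), sprintf("ks = %.10g", k$ks),
    sprintf("additional_nuclei = %s", model$additional_nuclei),
    sprintf("J_cap = %.10g", model$J_cap))
  writeLines(lines, path)
  invisible(path)
}
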