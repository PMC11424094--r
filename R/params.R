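#' Physical parameters of a two-phase droplet system
#'
#' Bundles the physical parameters that every continuum computation
#' consumes: droplet radius, dense- and dilute-phase diffusion
#' coefficients and equilibrium concentrations, and the interface
#' conductance \eqn{\kappa}.
#'
#' Units are micrometres and seconds throughout the continuum module;
#' concentrations may be in any single consistent unit, since only the
#' ratio \code{c_den/c_dil} enters the theory.
#'
#' @param R droplet radius (um), > 0.
#' @param D_den dense-phase diffusion coefficient (um^2/s), > 0.
#' @param D_dil dilute-phase diffusion coefficient (um^2/s), > 0.
#' @param c_den dense-phase equilibrium concentration (any unit), >= c_dil.
#' @param c_dil dilute-phase equilibrium concentration (same unit), > 0.
#' @param kappa interface conductance (um/s), > 0. \code{Inf} means no
#'   interface resistance.
#' @return An object of class \code{two_phase_params}.
#' @examples
#' laf1_params()
#' two_phase_params(R = 1, D_den = 0.0017, D_dil = 94, c_den = 1190, c_dil = 1)
#' @export
two_phase_params <- function(R, D_den, D_dil, c_den, c_dil, kappa = Inf) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop(sprintf("'%s' must be a single numeric value", nm), call. = FALSE)
    as.numeric(x)
  }
  R <- num1(R, "R"); D_den <- num1(D_den, "D_den"); D_dil <- num1(D_dil, "D_dil")
  c_den <- num1(c_den, "c_den"); c_dil <- num1(c_dil, "c_dil")
  kappa <- num1(kappa, "kappa")
  if (R <= 0 || !is.finite(R)) stop("R must be positive and finite", call. = FALSE)
  if (D_den <= 0) stop("D_den must be positive", call. = FALSE)
  if (D_dil <= 0) stop("D_dil must be positive", call. = FALSE)
  if (c_dil <= 0) stop("c_dil must be positive", call. = FALSE)
  if (c_den < c_dil) stop("c_den must be >= c_dil", call. = FALSE)
  if (kappa <= 0) stop("kappa must be positive (Inf allowed)", call. = FALSE)
  structure(list(R = R, D_den = D_den, D_dil = D_dil,
                 c_den = c_den, c_dil = c_dil, kappa = kappa),
            class = "two_phase_params")
}

#' @export
print.two_phase_params <- function(x, ...) {
  cat("Two-phase droplet parameters\n")
  cat(sprintf("  R      = %g um\n", x$R))
  cat(sprintf("  D_den  = %g um^2/s   D_dil = %g um^2/s\n", x$D_den, x$D_dil))
  cat(sprintf("  c_den  = %g          c_dil = %g   (c_den/c_dil = %g)\n",
              x$c_den, x$c_dil, x$c_den / x$c_dil))
  if (is.finite(x$kappa)) {
    cat(sprintf("  kappa  = %g um/s\n", x$kappa))
  } else {
    cat("  kappa  = Inf (no interface resistance)\n")
  }
  invisible(x)
}

#' LAF-1 droplet worked-example parameters
#'
#' The measured parameters of a 1-um LAF-1 protein droplet used as the
#' worked example throughout the package: \code{R = 1} um,
#' \code{D_den = 0.0017} um^2/s, \code{D_dil = 94} um^2/s and a
#' dense/dilute concentration ratio of 1190. By default there is no
#' interface resistance (\code{kappa = Inf}); pass the inferred
#' conductance to study the interface-limited regime.
#'
#' @param kappa interface conductance (um/s); default \code{Inf}.
#' @return A \code{\link{two_phase_params}} object.
#' @examples
#' recovery_timescale(laf1_params())
#' @export
laf1_params <- function(kappa = Inf) {
  two_phase_params(R = 1, D_den = 0.0017, D_dil = 94,
                   c_den = 1190, c_dil = 1, kappa = kappa)
}
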