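#' Sticker-spacer force field
#'
#' Interaction parameters of the coarse-grained polymer model: a
#' finitely extensible stretchable bond between chain neighbours, a
#' saturable short-range attraction between unlike sticker types, and a
#' WCA repulsive core between like types that enforces one-to-one
#' binding. Energies are in kBT, lengths in nm.
#'
#' Defaults: \code{K = 0.15} kBT/nm^2, \code{R0 = 10} nm, \code{U0 = 14}
#' kBT, \code{r0 = 1} nm, \code{epsilon = 1} kBT, \code{sigma = 2} nm,
#' \code{rc = 1.12 * sigma}.
#'
#' @param K bond stiffness (kBT/nm^2).
#' @param R0 maximum bond extension (nm); the bond energy diverges there.
#' @param U0 heterotypic well depth (kBT).
#' @param r0 attraction range (nm).
#' @param epsilon repulsion strength (kBT).
#' @param sigma repulsion diameter (nm).
#' @param rc repulsion cutoff (nm), approximately \code{2^(1/6) * sigma}.
#' @return An object of class \code{force_field}.
#' @export
force_field <- function(K = 0.15, R0 = 10, U0 = 14, r0 = 1,
                        epsilon = 1, sigma = 2, rc = 1.12 * sigma) {
  vals <- c(K = K, R0 = R0, r0 = r0, epsilon = epsilon, sigma = sigma, rc = rc)
  if (any(vals <= 0)) stop("force-field lengths and strengths must be positive",
                           call. = FALSE)
  if (U0 < 0) stop("U0 must be non-negative", call. = FALSE)
  if (abs(rc / sigma - 2^(1 / 6)) > 0.02)
    warning("rc is usually ~2^(1/6)*sigma for a purely repulsive core")
  structure(list(K = K, R0 = R0, U0 = U0, r0 = r0,
                 epsilon = epsilon, sigma = sigma, rc = rc),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat("Sticker-spacer force field (kBT, nm)\n")
  cat(sprintf("  bond:      K = %g, R0 = %g\n", x$K, x$R0))
  cat(sprintf("  attraction: U0 = %g, r0 = %g\n", x$U0, x$r0))
  cat(sprintf("  repulsion:  epsilon = %g, sigma = %g, rc = %g\n",
              x$epsilon, x$sigma, x$rc))
  invisible(x)
}

#' Pairwise interaction energies and forces
#'
#' \code{bond_energy} is the stretchable-bond potential
#' \eqn{U_b = -\frac{1}{2} K R_0^2 \ln[1 - (r/R_0)^2]} (infinite at
#' \eqn{r \ge R_0}); \code{attract_energy} the heterotypic well
#' \eqn{U_a = -\frac{1}{2} U_0 [1 + \cos(\pi r/r_0)]} for \eqn{r < r_0};
#' \code{repulse_energy} the WCA core
#' \eqn{U_r = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#' \eqn{r \le r_c}. The \code{*_force} variants return the radial force
#' scalar \eqn{F(r) = -dU/dr} (positive = repulsive).
#'
#' @param r distances (nm), >= 0.
#' @param ff a \code{\link{force_field}}.
#' @return Numeric vector of energies (kBT) or force scalars (kBT/nm).
#' @export
bond_energy <- function(r, ff = force_field()) {
  stopifnot(all(r >= 0))
  bond_energy_cpp(as.numeric(r), unclass(ff))
}
#' @rdname bond_energy
#' @export
bond_force <- function(r, ff = force_field()) {
  stopifnot(all(r >= 0))
  bond_force_cpp(as.numeric(r), unclass(ff))
}
#' @rdname bond_energy
#' @export
attract_energy <- function(r, ff = force_field()) {
  stopifnot(all(r >= 0))
  attract_energy_cpp(as.numeric(r), unclass(ff))
}
#' @rdname bond_energy
#' @export
attract_force <- function(r, ff = force_field()) {
  stopifnot(all(r >= 0))
  attract_force_cpp(as.numeric(r), unclass(ff))
}
#' @rdname bond_energy
#' @export
repulse_energy <- function(r, ff = force_field()) {
  stopifnot(all(r > 0))
  repulse_energy_cpp(as.numeric(r), unclass(ff))
}
#' @rdname bond_energy
#' @export
repulse_force <- function(r, ff = force_field()) {
  stopifnot(all(r > 0))
  repulse_force_cpp(as.numeric(r), unclass(ff))
}

#' Thermal statistics of a single chain bond by quadrature
#'
#' Mean length of one chain bond between like-type stickers under the
#' bond plus repulsion potentials at temperature kBT, computed by
#' numerically integrating \eqn{r^2 e^{-U(r)/k_BT}}. With the default
#' parameters the equilibrium bond length is about 3.9 nm.
#'
#' @param ff a \code{\link{force_field}}.
#' @param kBT temperature (kBT units).
#' @param n quadrature points.
#' @return The thermal mean bond length (nm).
#' @export
mean_bond_length <- function(ff = force_field(), kBT = 1, n = 20000) {
  r <- seq(1e-6, ff$R0 * (1 - 1e-9), length.out = n)
  u <- bond_energy(r, ff) + repulse_energy(r, ff)
  w <- r^2 * exp(-(u - min(u)) / kBT)
  sum(r * w) / sum(w)
}
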