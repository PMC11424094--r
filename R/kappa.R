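#' Equilibrium profile across a condensate interface
#'
#' Holds the equilibrium concentration and local diffusion-coefficient
#' profiles across the interfacial region, used by the mean-field
#' conductance integral.
#'
#' @param x_grid strictly increasing positions across the interface (nm).
#' @param c_eq equilibrium concentration profile (any consistent unit),
#'   monotone between the dense and dilute levels.
#' @param D_local local diffusion coefficient profile (um^2/s).
#' @param delta optional interface width (nm), e.g. from a tanh fit.
#' @return An object of class \code{interface_profile}.
#' @export
interface_profile <- function(x_grid, c_eq, D_local, delta = NULL) {
  stopifnot(is.numeric(x_grid), is.numeric(c_eq), is.numeric(D_local),
            length(x_grid) == length(c_eq), length(x_grid) == length(D_local))
  if (any(diff(x_grid) <= 0)) stop("x_grid must be strictly increasing", call. = FALSE)
  if (any(c_eq <= 0)) stop("c_eq must be positive", call. = FALSE)
  d <- diff(c_eq)
  if (any(d > 0) && any(d < 0))
    stop("c_eq must be monotone across the interface", call. = FALSE)
  structure(list(x_grid = as.numeric(x_grid), c_eq = as.numeric(c_eq),
                 D_local = as.numeric(D_local), delta = delta),
            class = "interface_profile")
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Mean-field interface conductance from an equilibrium profile
#'
#' For transport through an interface where molecules simply diffuse with
#' a local coefficient D(x) down the equilibrium profile c_eq(x), the
#' conductance is \eqn{\kappa^{-1} = \int c_{den} / (c_{eq}(x) D(x)) dx}
#' over the interfacial window. Because the integrand is bounded by its
#' values in the two bulk phases, this mean-field conductance obeys
#' \eqn{\kappa^{-1} < \delta/D_{den} + \delta c_{den}/(c_{dil} D_{dil})}
#' and is therefore large for any narrow interface: mean-field theory
#' cannot produce a dominant interface resistance.
#'
#' @param profile an \code{\link{interface_profile}} (x in nm, D in um^2/s).
#' @param c_den dense-phase concentration (same unit as \code{c_eq}).
#' @return Interface conductance kappa (um/s).
#' @examples
#' # flat dilute-level profile of width delta reduces to kappa0
#' pr <- interface_profile(seq(0, 5, 0.01), rep(0.05, 501), rep(17, 501))
#' mean_field_kappa(pr, c_den = 7.7)
#' kappa0(c_dil = 0.05, D_dil = 17, delta = 5, c_den = 7.7)
#' @export
mean_field_kappa <- function(profile, c_den) {
  stopifnot(inherits(profile, "interface_profile"))
  if (any(profile$D_local <= 0))
    stop("D_local must be positive everywhere", call. = FALSE)
  integ <- c_den / (profile$c_eq * profile$D_local)
  inv_kappa <- trapz(profile$x_grid, integ) * 1e-3   # nm -> um
  1 / inv_kappa
}

#' Sharp-interface conductance prediction
#'
#' The mean-field conductance of an interface of width delta when the
#' profile is at the dilute level with dilute-phase diffusivity:
#' \eqn{\kappa_0 = c_{dil} D_{dil} / (\delta c_{den})}. This is the
#' no-bouncing baseline against which measured conductances are compared.
#'
#' @param c_dil,c_den dilute/dense concentrations (same unit).
#' @param D_dil dilute-phase diffusion coefficient (um^2/s).
#' @param delta interface width (nm).
#' @return kappa0 (um/s).
#' @export
kappa0 <- function(c_dil, D_dil, delta, c_den) {
  stopifnot(c_dil > 0, D_dil > 0, delta > 0, c_den > 0)
  c_dil * D_dil / (delta * 1e-3 * c_den)
}

#' Sticker-availability description of an interface
#'
#' Parameters controlling the rate at which a polymer arriving from the
#' dilute phase can form its first heterotypic sticker bond with the
#' dense phase: capture radius, interface width, polymer valence, global
#' sticker stoichiometry, the fractions of unbound A/B stickers in each
#' phase, concentrations, and the dilute diffusivity.
#'
#' @param r0 sticker capture radius (nm).
#' @param delta interface width (nm).
#' @param n monomers (stickers) per polymer.
#' @param s global stoichiometry c_A/c_B (> 0).
#' @param f_dil_A,f_dil_B,f_den_A,f_den_B unbound fractions in [0,1].
#' @param c_dil,c_den polymer concentrations (nm^-3).
#' @param D_dil dilute-phase diffusion coefficient (um^2/s).
#' @return An object of class \code{sticker_availability}.
#' @export
sticker_availability <- function(r0, delta, n, s, f_dil_A, f_dil_B,
                                 f_den_A, f_den_B, c_dil, c_den, D_dil) {
  fr <- c(f_dil_A, f_dil_B, f_den_A, f_den_B)
  if (any(fr < 0 | fr > 1)) stop("unbound fractions must lie in [0,1]", call. = FALSE)
  if (s <= 0) stop("stoichiometry s must be positive", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  stopifnot(r0 > 0, delta > 0, c_dil > 0, c_den > 0, D_dil > 0)
  structure(list(r0 = r0, delta = delta, n = n, s = s,
                 f_dil_A = f_dil_A, f_dil_B = f_dil_B,
                 f_den_A = f_den_A, f_den_B = f_den_B,
                 c_dil = c_dil, c_den = c_den, D_dil = D_dil),
            class = "sticker_availability")
}

#' Interface conductance from sticker availability
#'
#' The conductance of a sticker-spacer condensate interface is set by the
#' encounter rate of unbound sticker pairs across the interface:
#' \deqn{\kappa = 4\pi r_0 \delta D_{dil} n^2 c_{dil}
#'   (f^A_{dil} f^B_{den} + f^B_{dil} f^A_{den}) / (2 + s + s^{-1}).}
#' The companion dimensionless availability parameter is
#' \deqn{u = 4\pi r_0 \delta^2 n^2 c_{den}
#'   (f^A_{dil} f^B_{den} + f^B_{dil} f^A_{den}) / (2 + s + s^{-1}),}
#' and the identity \eqn{\kappa/\kappa_0 = u} holds exactly, so scarce
#' free stickers (small u) depress the conductance below the no-bouncing
#' baseline \code{\link{kappa0}}.
#'
#' @param sa a \code{\link{sticker_availability}} object.
#' @return \code{kappa_sticker_theory}: kappa in um/s;
#'   \code{u_parameter}: dimensionless u.
#' @export
kappa_sticker_theory <- function(sa) {
  stopifnot(inherits(sa, "sticker_availability"))
  avail <- sa$f_dil_A * sa$f_den_B + sa$f_dil_B * sa$f_den_A
  stoich <- 2 + sa$s + 1 / sa$s
  ## nm^2 * nm^-3 * um^2/s -> um/s carries a factor 1e3
  4 * pi * sa$r0 * sa$delta * sa$D_dil * sa$n^2 * sa$c_dil / stoich * avail * 1e3
}

#' @rdname kappa_sticker_theory
#' @export
u_parameter <- function(sa) {
  stopifnot(inherits(sa, "sticker_availability"))
  avail <- sa$f_dil_A * sa$f_den_B + sa$f_dil_B * sa$f_den_A
  stoich <- 2 + sa$s + 1 / sa$s
  4 * pi * sa$r0 * sa$delta^2 * sa$n^2 * sa$c_den / stoich * avail
}

#' Invert a labeled-population decay time into an interface conductance
#'
#' In a slab geometry where the dilute phase occupies a layer of
#' half-width d next to the dense phase, the slowest decay mode of the
#' labeled dilute population satisfies
#' \deqn{\kappa = (c_{dil}/c_{den}) \sqrt{D_{dil}/\tau}
#'   \tan(d / \sqrt{\tau D_{dil}}).}
#' The decay cannot be faster than pure diffusion to a perfectly
#' absorbing interface, \eqn{\tau > (2d/\pi)^2 / D_{dil}}; below that
#' bound the tangent argument reaches pi/2 and no finite conductance
#' reproduces the decay.
#'
#' Units must be consistent (e.g. um and s, or reduced simulation units).
#'
#' @param tau fitted decay time of the labeled population.
#' @param d half-width of the dilute phase.
#' @param D_dil dilute-phase diffusion coefficient.
#' @param c_dil,c_den phase concentrations (any unit; only the ratio enters).
#' @return kappa in the corresponding units.
#' @export
slab_kappa_from_decay <- function(tau, d, D_dil, c_dil, c_den) {
  stopifnot(tau > 0, d > 0, D_dil > 0, c_dil > 0, c_den > 0)
  arg <- d / sqrt(tau * D_dil)
  if (arg >= pi / 2)
    stop(paste0("diffusion-limited regime: decay time is at or below the ",
                "pure-diffusion bound (2d/pi)^2/D_dil; kappa is not ",
                "identifiable"), call. = FALSE)
  (c_dil / c_den) * sqrt(D_dil / tau) * tan(arg)
}

#' Numerical decay of a labeled dilute slab against a conducting interface
#'
#' Method-of-lines solution of the one-dimensional problem underlying
#' \code{\link{slab_kappa_from_decay}}: labeled molecules diffuse in
#' x in [0, d] with a reflecting boundary at x = d and absorption into the
#' dense phase at x = 0 at rate flux = (kappa c_den / c_dil) c(0). Serves
#' as the independent round-trip oracle for the tangent inversion.
#'
#' @param kappa imposed interface conductance.
#' @param d dilute half-width.
#' @param D_dil dilute diffusivity.
#' @param c_dil,c_den phase concentrations.
#' @param n_cells grid cells.
#' @param t_max,n_times output time grid (default: several decay times).
#' @return List with \code{times}, \code{survival} (normalised total
#'   labeled material), and \code{tau} from a log-linear tail fit.
#' @export
solve_slab_decay <- function(kappa, d, D_dil, c_dil, c_den,
                             n_cells = 400, t_max = NULL, n_times = 200) {
  stopifnot(kappa > 0, d > 0, D_dil > 0)
  K <- kappa * c_den / c_dil        # surface rate constant for labeled loss
  ## crude timescale estimate: series of interface and diffusion times
  tau0 <- d / K + (2 * d / pi)^2 / D_dil
  if (is.null(t_max)) t_max <- 8 * tau0
  h <- d / n_cells
  x <- (seq_len(n_cells) - 0.5) * h
  times <- seq(0, t_max, length.out = n_times)
  func <- function(t, y, p) {
    ## flux positive toward the interface at x = 0
    Fint <- K * y[1] / (1 + K * (h / 2) / D_dil)  # series resistance to face
    Fin <- D_dil * diff(y) / h                    # flux from cell i+1 into i
    dy <- c(Fin, 0) - c(Fint, Fin)
    list(dy / h)
  }
  sol <- deSolve::ode(y = rep(1, n_cells), times = times, func = func,
                      parms = NULL, method = "lsoda", jactype = "bandint",
                      bandup = 1, banddown = 1, rtol = 1e-9, atol = 1e-12)
  surv <- rowSums(sol[, -1, drop = FALSE]) / n_cells
  keep <- surv < 0.6 & surv > 1e-4
  if (sum(keep) < 5) keep <- surv > 1e-4 & times > 0
  fitc <- stats::coef(stats::lm(log(surv[keep]) ~ times[keep]))
  list(times = times, survival = surv, tau = -1 / as.numeric(fitc[2]))
}

#' Droplet-size crossover between interface- and diffusion-limited recovery
#'
#' The interface term of the recovery timescale grows linearly in R while
#' the two diffusive terms grow as R^2, so recovery is interface-limited
#' below, and diffusion-limited above, the radius at which they are equal:
#' \deqn{R_\times = \frac{1/(3\kappa)}{1/(\pi^2 D_{den}) +
#'   c_{den}/(3 c_{dil} D_{dil})}.}
#'
#' @param params a \code{\link{two_phase_params}} object; \code{kappa = Inf}
#'   gives \code{R_x = 0}.
#' @return Crossover radius (um).
#' @examples
#' crossover_radius(laf1_params(kappa = 7.4e-5))  # ~71 um
#' @export
crossover_radius <- function(params) {
  stopifnot(inherits(params, "two_phase_params"))
  if (!is.finite(params$kappa)) return(0)
  (1 / (3 * params$kappa)) /
    (1 / (pi^2 * params$D_den) + params$c_den / (3 * params$c_dil * params$D_dil))
}
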