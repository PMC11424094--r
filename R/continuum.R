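#' Decomposition of the condensate recovery timescale
#'
#' The time for a fully bleached droplet to recover is, to a good
#' approximation when dilute-phase diffusion is much faster than
#' dense-phase diffusion, a sum of three independent contributions:
#' dense-phase mixing \eqn{\tau_{den} = R^2/(\pi^2 D_{den})}, resupply
#' from the dilute phase
#' \eqn{\tau_{dil} = c_{den} R^2/(3 c_{dil} D_{dil})}, and transfer
#' across the interface \eqn{\tau_{int} = R/(3\kappa)}.
#'
#' @param params a \code{\link{two_phase_params}} object.
#' @return A list with components \code{tau_total}, \code{tau_den},
#'   \code{tau_dil}, \code{tau_int} (seconds). \code{tau_int} is zero
#'   when \code{kappa} is infinite.
#' @examples
#' # micron-sized LAF-1 droplet, no interface resistance: ~64 s
#' recovery_timescale(laf1_params())$tau_total
#' @export
recovery_timescale <- function(params) {
  stopifnot(inherits(params, "two_phase_params"))
  tau_den <- params$R^2 / (pi^2 * params$D_den)
  tau_dil <- params$c_den * params$R^2 / (3 * params$c_dil * params$D_dil)
  tau_int <- if (is.finite(params$kappa)) params$R / (3 * params$kappa) else 0
  list(tau_total = tau_den + tau_dil + tau_int,
       tau_den = tau_den, tau_dil = tau_dil, tau_int = tau_int)
}

#' Recovery curve container
#'
#' Holds an unbleached-fraction curve f(t), optionally with fitted
#' plateau \code{fit_A} and recovery time \code{fit_tau}.
#'
#' @param times strictly increasing times (s), starting at 0.
#' @param f unbleached fraction inside the condensate.
#' @param fit_A,fit_tau optional fit results.
#' @return An object of class \code{recovery_curve}.
#' @export
recovery_curve <- function(times, f, fit_A = NULL, fit_tau = NULL) {
  stopifnot(is.numeric(times), is.numeric(f), length(times) == length(f))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  structure(list(times = as.numeric(times), f = as.numeric(f),
                 fit_A = fit_A, fit_tau = fit_tau),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("Recovery curve: %d points, t in [%g, %g]\n",
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  f range [%.4g, %.4g]\n", min(x$f), max(x$f)))
  if (!is.null(x$fit_A)) cat(sprintf("  fit: A = %.4g, tau = %.4g s\n",
                                     x$fit_A, x$fit_tau))
  invisible(x)
}

#' Single-exponential approximation to the recovery curve
#'
#' In the regime \code{D_dil >> D_den} the full two-phase solution is
#' well approximated by \eqn{f(t) = 1 - \exp(-t/\tau)} with \eqn{\tau}
#' from \code{\link{recovery_timescale}}.
#'
#' @param params a \code{\link{two_phase_params}} object.
#' @param times non-negative times (s).
#' @return A \code{\link{recovery_curve}}.
#' @export
approx_recovery_curve <- function(params, times) {
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  tau <- recovery_timescale(params)$tau_total
  recovery_curve(times, 1 - exp(-times / tau), fit_A = 1, fit_tau = tau)
}

## Non-uniform radial finite-volume grid with the droplet surface r = R on
## a cell face and refinement on both sides of it. Outside the droplet the
## spacing grows geometrically so that large "effectively infinite" outer
## domains stay affordable.
radial_grid <- function(R, R_out, n_inner = 60, refine = 0.85, grow = 1.06,
                        max_cells = 6000) {
  if (n_inner < 30) stop("need at least 30 cells inside the droplet", call. = FALSE)
  if (R_out <= R) stop("outer_radius must exceed R", call. = FALSE)
  x <- seq(0, 1, length.out = n_inner + 1)
  faces_in <- R * ((1 - refine) * x + refine * x * (2 - x))
  h0 <- R - faces_in[n_inner]
  fo <- R
  h <- h0
  repeat {
    nxt <- fo[length(fo)] + h
    if (nxt >= R_out) break
    fo <- c(fo, nxt)
    h <- h * grow
    if (length(fo) + n_inner > max_cells)
      stop("radial grid too large; increase 'grow' or reduce outer radius",
           call. = FALSE)
  }
  fo <- c(fo, R_out)
  nf <- length(fo)
  if (nf >= 3 && (fo[nf] - fo[nf - 1]) < 0.25 * (fo[nf - 1] - fo[nf - 2]))
    fo <- fo[-(nf - 1)]
  faces <- c(faces_in, fo[-1])
  n <- length(faces) - 1L
  list(faces = faces,
       centers = (faces[-1] + faces[-(n + 1)]) / 2,
       volumes = 4 * pi / 3 * diff(faces^3),
       areas = 4 * pi * faces^2,
       iface = n_inner + 1L,   # index of the face sitting at r = R
       n_inner = n_inner, n = n)
}

#' Solve the bleached-population diffusion problem in a two-phase droplet
#'
#' Integrates the radial diffusion equation for the concentration
#' \eqn{c(r,t)} of the bleached population, with diffusivity
#' \code{D_den} inside the droplet (r < R) and \code{D_dil} outside,
#' zero gradient at the centre, and a finite-conductance flux condition
#' at the interface: the flux through r = R equals
#' \eqn{\kappa [c(R^-) - (c_{den}/c_{dil}) c(R^+)]}.
#' The discretisation is a conservative finite-volume scheme on a
#' non-uniform radial grid (the interface sits on a cell face, with the
#' jump condition folded into the face flux as a series resistance), and
#' time integration uses a stiff method-of-lines solver.
#'
#' @param params a \code{\link{two_phase_params}} object.
#' @param outer_radius radius of the outer (dilute) domain boundary (um).
#'   \code{Inf} requests an effectively infinite dilute phase, realised
#'   as an absorbing far-field boundary at
#'   \code{10 * max(R, sqrt(D_dil * t_max))}.
#' @param t_max final time (s); default six times the closed-form total
#'   recovery timescale.
#' @param times optional explicit output times (must start at 0).
#' @param n_inner number of cells inside the droplet (>= 30).
#' @param grow geometric growth factor of the outer grid spacing.
#' @param outer_bc \code{"reflecting"} (closed domain, default for finite
#'   \code{outer_radius}) or \code{"absorbing"} (far-field c = 0, default
#'   and forced for \code{outer_radius = Inf}).
#' @param init \code{"bleach"} (c = c_den inside, 0 outside: a
#'   full-droplet bleach viewed through the bleached population) or
#'   \code{"equilibrium"} (c_den inside, c_dil outside; a fixed point).
#' @param n_times number of output times when \code{times} is NULL.
#' @param rtol,atol integrator tolerances; \code{atol} defaults to
#'   \code{1e-10 * c_den}.
#' @param check_flux verify after solving that the interface flux agrees
#'   with one-sided quadratic gradient reconstructions on both sides.
#' @param check_tol maximum allowed relative flux mismatch before a
#'   grid-refinement error is raised.
#' @return An object of class \code{radial_field}: grid geometry,
#'   \code{times}, and a \code{length(times) x n_cells} matrix
#'   \code{values} of concentrations.
#' @seealso \code{\link{unbleached_fraction}}, \code{\link{field_mass}}
#' @export
solve_frap_radial <- function(params, outer_radius = Inf, t_max = NULL,
                              times = NULL, n_inner = 180, grow = 1.06,
                              outer_bc = NULL, init = c("bleach", "equilibrium"),
                              n_times = 160, rtol = 1e-8, atol = NULL,
                              check_flux = TRUE, check_tol = 1e-4) {
  stopifnot(inherits(params, "two_phase_params"))
  init <- match.arg(init)
  R <- params$R
  P <- params$c_den / params$c_dil
  if (is.null(t_max)) {
    tau <- recovery_timescale(params)$tau_total
    t_max <- 6 * tau
  }
  if (is.null(times)) {
    s <- seq(0, 1, length.out = n_times)
    times <- t_max * s^1.6           # denser output at early times
  } else {
    times <- sort(unique(as.numeric(times)))
    if (times[1] != 0) times <- c(0, times)
    t_max <- max(times)
  }
  infinite <- !is.finite(outer_radius)
  if (infinite) {
    outer_radius <- 10 * max(R, sqrt(params$D_dil * t_max))
    if (is.null(outer_bc)) outer_bc <- "absorbing"
  } else if (is.null(outer_bc)) outer_bc <- "reflecting"
  outer_bc <- match.arg(outer_bc, c("reflecting", "absorbing"))

  g <- radial_grid(R, outer_radius, n_inner = n_inner, grow = grow)
  n <- g$n
  centers <- g$centers
  faces <- g$faces
  iface <- g$iface

  ## face flux (positive outward) F_j = a_j c_{j-1} - b_j c_j for ordinary
  ## interior faces; the interface face uses one-sided quadratic stencils
  ## (two cell centres plus the face value on each side) combined with the
  ## conductance jump condition, giving a four-point flux formula
  a <- b <- numeric(n + 1L)
  for (j in 2:n) {
    if (j == iface) next
    D <- if (faces[j] < R) params$D_den else params$D_dil
    gg <- D / (centers[j] - centers[j - 1L])
    a[j] <- gg; b[j] <- gg
  }
  dcoef <- function(x1, x2, x3, at) {
    ## coefficients of the derivative at 'at' of the quadratic through
    ## (x1,y1),(x2,y2),(x3,y3)
    c((2 * at - x2 - x3) / ((x1 - x2) * (x1 - x3)),
      (2 * at - x1 - x3) / ((x2 - x1) * (x2 - x3)),
      (2 * at - x1 - x2) / ((x3 - x1) * (x3 - x2)))
  }
  al <- dcoef(centers[iface - 2L], centers[iface - 1L], R, R)  # dense side
  be <- dcoef(R, centers[iface], centers[iface + 1L], R)       # dilute side
  den2 <- (if (is.finite(params$kappa)) 1 / params$kappa else 0) +
    1 / (params$D_den * al[3]) - P / (params$D_dil * be[1])
  wif <- c(-al[1] / (al[3] * den2), -al[2] / (al[3] * den2),
           P * be[2] / (be[1] * den2), P * be[3] / (be[1] * den2))
  ifc <- (iface - 2L):(iface + 1L)   # cells entering the interface flux
  a_out <- if (outer_bc == "absorbing")
    params$D_dil / (faces[n + 1L] - centers[n]) else 0

  inside <- centers < R
  y0 <- if (init == "bleach") ifelse(inside, params$c_den, 0)
        else ifelse(inside, params$c_den, params$c_dil)

  A <- g$areas
  V <- g$volumes
  ii <- 2:n
  func <- function(t, y, parms) {
    Fin <- a[ii] * y[ii - 1L] - b[ii] * y[ii]
    Fin[iface - 1L] <- sum(wif * y[ifc])
    Fall <- c(0, Fin, a_out * y[n])
    list((A[1:n] * Fall[1:n] - A[2:(n + 1L)] * Fall[2:(n + 1L)]) / V)
  }
  if (is.null(atol)) atol <- 1e-10 * params$c_den
  sol <- deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                      method = "lsoda", jactype = "bandint", bandup = 2,
                      banddown = 2, rtol = rtol, atol = atol)
  vals <- unname(sol[, -1, drop = FALSE])
  neg <- min(vals)
  if (neg < -1e-6 * params$c_den)
    stop("solver produced significantly negative concentrations", call. = FALSE)
  vals[vals < 0] <- 0

  field <- structure(list(
    faces = faces, centers = centers, volumes = V, areas = A,
    iface = iface, times = times, values = vals, params = params,
    outer_radius = outer_radius, outer_bc = outer_bc,
    domain = if (infinite) "effectively-infinite" else "finite",
    init = init), class = "radial_field")

  field$wif <- wif
  if (check_flux) {
    mis <- interface_flux_mismatch(field)
    if (mis > check_tol)
      stop(sprintf(paste0("interface flux mismatch %.3g exceeds %.3g; ",
                          "the radial grid is too coarse - increase n_inner"),
                   mis, check_tol), call. = FALSE)
    field$flux_mismatch <- mis
  }
  field
}

## Self-consistency of the interface discretisation: reconstruct c(R-), c(R+)
## and the one-sided gradient fluxes from quadratics through the three
## nearest cell centres on each side -- a stencil independent of the one the
## scheme itself uses -- and compare the dense-side, dilute-side and
## conductance-jump fluxes with the flux the scheme applied. Checked at a
## few intermediate output times; early boundary-layer times are skipped.
interface_flux_mismatch <- function(field) {
  p <- field$params
  R <- p$R
  P <- p$c_den / p$c_dil
  i <- field$iface
  x <- field$centers
  ## sample times where the droplet content has made 20/50/80% of its
  ## total change, so the interface flux is well above integrator noise
  ins <- seq_len(i - 1L)
  m_in <- as.numeric(field$values[, ins, drop = FALSE] %*% field$volumes[ins])
  prog <- (m_in - m_in[1]) / (m_in[length(m_in)] - m_in[1] - 1e-300)
  idx <- unique(vapply(c(0.2, 0.5, 0.8),
                       function(p) which.min(abs(prog - p)), integer(1)))
  idx <- idx[idx >= 3L]
  if (!length(idx)) idx <- max(3L, length(field$times) %/% 2L)
  lag3 <- function(xs, ys, at) {
    ## value and derivative at 'at' of the quadratic through three points
    l1 <- (at - xs[2]) * (at - xs[3]) / ((xs[1] - xs[2]) * (xs[1] - xs[3]))
    l2 <- (at - xs[1]) * (at - xs[3]) / ((xs[2] - xs[1]) * (xs[2] - xs[3]))
    l3 <- (at - xs[1]) * (at - xs[2]) / ((xs[3] - xs[1]) * (xs[3] - xs[2]))
    d1 <- (2 * at - xs[2] - xs[3]) / ((xs[1] - xs[2]) * (xs[1] - xs[3]))
    d2 <- (2 * at - xs[1] - xs[3]) / ((xs[2] - xs[1]) * (xs[2] - xs[3]))
    d3 <- (2 * at - xs[1] - xs[2]) / ((xs[3] - xs[1]) * (xs[3] - xs[2]))
    c(val = sum(c(l1, l2, l3) * ys), slope = sum(c(d1, d2, d3) * ys))
  }
  worst <- 0
  for (k in idx) {
    y <- field$values[k, ]
    FF <- sum(field$wif * y[(i - 2L):(i + 1L)])
    den <- lag3(x[(i - 3L):(i - 1L)], y[(i - 3L):(i - 1L)], R)
    dil <- lag3(x[i:(i + 2L)], y[i:(i + 2L)], R)
    cands <- c(-p$D_den * den[["slope"]], -p$D_dil * dil[["slope"]])
    if (is.finite(p$kappa))
      cands <- c(cands, p$kappa * (den[["val"]] - P * dil[["val"]]))
    scale <- max(abs(FF), 1e-300)
    ## ignore times where the flux has decayed to numerical noise
    if (scale > 1e-9 * max(abs(y)) * p$D_den / R)
      worst <- max(worst, max(abs(cands - FF)) / scale)
  }
  worst
}

#' @export
print.radial_field <- function(x, ...) {
  cat(sprintf("Radial concentration field: %d cells, %d times, domain %s\n",
              length(x$centers), length(x$times), x$domain))
  cat(sprintf("  droplet R = %g um, outer radius = %g um (%s)\n",
              x$params$R, x$outer_radius, x$outer_bc))
  invisible(x)
}

#' Total bleached material in a radial field over time
#'
#' @param field a \code{radial_field}.
#' @return Numeric vector: \eqn{\int 4\pi r^2 c(r,t)\,dr} at each output
#'   time. Constant in a closed (reflecting) domain.
#' @export
field_mass <- function(field) {
  stopifnot(inherits(field, "radial_field"))
  as.numeric(field$values %*% field$volumes)
}

#' Unbleached fraction inside the droplet
#'
#' Computes \eqn{f(t) = 1 - \int_0^R 4\pi r^2 c\,dr / \int_0^R 4\pi r^2
#' c_{den}\,dr} on the solver grid, where c is the bleached-population
#' concentration.
#'
#' @param field a \code{radial_field} from \code{\link{solve_frap_radial}}.
#' @param R droplet radius (um); defaults to the radius the field was
#'   solved with (must coincide with a grid face).
#' @param c_den dense-phase concentration normalising the integral.
#' @return A \code{\link{recovery_curve}}.
#' @export
unbleached_fraction <- function(field, R = NULL, c_den = NULL) {
  stopifnot(inherits(field, "radial_field"))
  if (is.null(R)) R <- field$params$R
  if (is.null(c_den)) c_den <- field$params$c_den
  j <- which(abs(field$faces - R) <= 1e-9 * max(R, 1))
  if (length(j) != 1L)
    stop("R does not coincide with a grid face", call. = FALSE)
  ins <- seq_len(j - 1L)
  Vin <- field$volumes[ins]
  m_in <- as.numeric(field$values[, ins, drop = FALSE] %*% Vin)
  recovery_curve(field$times, 1 - m_in / (c_den * sum(Vin)))
}

#' Extract a recovery time from a curve
#'
#' Fits \eqn{f(t) = 1 - \exp(-t/\tau)} by least squares over the window
#' \code{f} in \code{window} (default 0.05 to 0.95), and also reports the
#' e-folding time, i.e. the time at which f first reaches 1 - 1/e.
#'
#' @param curve a \code{\link{recovery_curve}}.
#' @param window inclusive range of f used in the fit.
#' @return List with \code{tau} (the fitted value, the default estimate),
#'   \code{tau_efold}, and the \code{nls} fit object.
#' @export
fit_recovery_tau <- function(curve, window = c(0.05, 0.95)) {
  stopifnot(inherits(curve, "recovery_curve"))
  t <- curve$times; f <- curve$f
  keep <- f >= window[1] & f <= window[2] & t > 0
  if (sum(keep) < 5)
    stop("too few points inside the fit window", call. = FALSE)
  tau0 <- stats::approx(f, t, xout = 1 - exp(-1), ties = "ordered")$y
  if (is.na(tau0)) tau0 <- stats::median(t[keep])
  fit <- minpack.lm::nlsLM(ff ~ 1 - exp(-tt / tau),
                           data = list(tt = t[keep], ff = f[keep]),
                           start = list(tau = tau0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  tef <- stats::approx(f, t, xout = 1 - exp(-1), ties = "ordered")$y
  list(tau = as.numeric(stats::coef(fit)[["tau"]]), tau_efold = tef, fit = fit)
}

#' Fit the finite-reservoir recovery form
#'
#' In a closed simulation box the dilute phase holds a limited pool of
#' unbleached molecules, so recovery plateaus below one. The curve is
#' fitted with \eqn{f(t) = A[1 - \exp(-t/(A\tau))]}, whose initial slope
#' \eqn{1/\tau} matches the infinite-reservoir recovery rate; fixing
#' \code{A = 1} reduces to the single-exponential form.
#'
#' @param curve a \code{\link{recovery_curve}} with at least 10 points
#'   spanning about three decay times.
#' @param fix_A fit with the plateau fixed at 1.
#' @return The input curve with \code{fit_A} and \code{fit_tau} filled
#'   in, plus attributes \code{fit} (the nls object) and
#'   \code{residual_sd}.
#' @export
fit_finite_recovery <- function(curve, fix_A = FALSE) {
  stopifnot(inherits(curve, "recovery_curve"))
  t <- curve$times; f <- curve$f
  if (length(t) < 10) stop("need at least 10 time points", call. = FALSE)
  A0 <- max(f)
  if (A0 <= 0) stop("curve never rises above zero", call. = FALSE)
  tA0 <- stats::approx(f, t, xout = A0 * (1 - exp(-1)), ties = "ordered")$y
  if (is.na(tA0)) tA0 <- stats::median(t[t > 0])
  fit <- tryCatch({
    if (fix_A) {
      minpack.lm::nlsLM(ff ~ 1 - exp(-tt / tau),
                        data = list(tt = t, ff = f),
                        start = list(tau = tA0),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
    } else {
      minpack.lm::nlsLM(ff ~ A * (1 - exp(-tt / (A * tau))),
                        data = list(tt = t, ff = f),
                        start = list(A = A0, tau = tA0 / max(A0, 1e-12)),
                        lower = c(1e-6, 1e-12), upper = c(1.5, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
    }
  }, error = function(e) {
    stop(sprintf("finite-recovery fit failed: %s (residual range %.3g..%.3g)",
                 conditionMessage(e), min(f), max(f)), call. = FALSE)
  })
  cf <- stats::coef(fit)
  curve$fit_A <- if (fix_A) 1 else as.numeric(cf[["A"]])
  curve$fit_tau <- as.numeric(cf[["tau"]])
  attr(curve, "fit") <- fit
  attr(curve, "residual_sd") <- stats::sd(stats::resid(fit))
  curve
}

#' Late-time decay rate of a recovery curve
#'
#' Log-linear fit of \eqn{1 - f(t)} over the portion of the curve where
#' f lies between \code{frac[1]} and \code{frac[2]}; returns the inverse
#' decay rate. Useful for comparing against the slowest eigenmode of the
#' diffusion problem.
#'
#' @param curve a \code{\link{recovery_curve}}.
#' @param frac window of f values considered "late time".
#' @return The tail decay time (s).
#' @export
tail_decay_time <- function(curve, frac = c(0.7, 0.99)) {
  t <- curve$times; f <- curve$f
  keep <- f >= frac[1] & f <= frac[2] & (1 - f) > 0
  if (sum(keep) < 4) stop("too few points in the tail window", call. = FALSE)
  fitc <- stats::coef(stats::lm(log(1 - f[keep]) ~ t[keep]))
  -1 / as.numeric(fitc[2])
}
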