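#' Concentration unit conversions
#'
#' Polymer number densities are carried internally in nm^-3; one
#' molecule per nm^3 corresponds to 1660.5 mM (the inverse Avogadro
#' volume).
#'
#' @param x concentration values.
#' @return Converted values.
#' @export
nm3_to_mM <- function(x) x * 1e24 / 6.02214076e23 * 1e3
#' @rdname nm3_to_mM
#' @export
mM_to_nm3 <- function(x) x / (1e24 / 6.02214076e23 * 1e3)

## periodic (circular-mean) centre of mass of a set of coordinates
circular_com <- function(u, L) {
  th <- u / L * 2 * pi
  m <- atan2(mean(sin(th)), mean(cos(th)))
  (m %% (2 * pi)) / (2 * pi) * L
}

## shift a frame so 'center' maps to the box centre, rewrapped
recenter_coords <- function(xyz, box, center) {
  out <- sweep(xyz, 2, center - box / 2, "-")
  sweep(out, 2, box, function(a, L) a - L * floor(a / L))
}

#' Density profile and phase concentrations from a trajectory
#'
#' For each frame the largest cluster is found, the box is recentred on
#' its periodic centre of mass, and sticker counts are histogrammed
#' either along x (slab geometry) or radially from the centre (droplet).
#' The time-averaged profile (in polymers/nm^3: sticker density divided
#' by chain length) is summarised by a tanh interface fit
#' \deqn{c(u) = c_{dil} + \frac{c_{den} - c_{dil}}{2}
#'   [1 - \tanh(2(u - u_0)/\delta)]}
#' on the folded coordinate u (distance from the dense centre), giving
#' the interface position u0 and width delta. The reported phase
#' concentrations are plateau averages over the regions more than one
#' delta inside/outside u0 (consistent with the fitted levels to within
#' 10 percent).
#'
#' @param traj a \code{cg_trajectory}.
#' @param axis \code{"x"} for slab geometry or \code{"radial"}.
#' @param bins number of histogram bins on the folded coordinate.
#' @param recenter recentre each frame on the largest cluster.
#' @param frames frames to use (default all).
#' @param cutoff clustering distance (nm).
#' @return List with the profile data frame (\code{u}, \code{conc}),
#'   \code{c_den}, \code{c_dil} (nm^-3), \code{c_den_mM}, \code{c_dil_mM},
#'   \code{delta} (nm), \code{u0}, \code{slab_width}, \code{d} (dilute
#'   half-width, slab only), and \code{phase_separated}.
#' @export
density_profile <- function(traj, axis = c("x", "radial"), bins = 60,
                            recenter = TRUE, frames = NULL, cutoff = 1) {
  stopifnot(inherits(traj, "cg_trajectory"))
  axis <- match.arg(axis)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  box <- traj$box
  nmono <- as.integer(round(length(traj$mol) / max(traj$mol)))
  umax <- if (axis == "x") box[1] / 2 else min(box) / 2
  edges <- seq(0, umax, length.out = bins + 1)
  counts <- numeric(bins)
  frac_largest <- numeric(length(frames))
  for (k in seq_along(frames)) {
    st <- trajectory_frame(traj, frames[k])
    xyz <- st$pos
    if (recenter) {
      lab <- cluster_polymers(st, cutoff)
      frac_largest[k] <- mean(lab == 1L)
      members <- st$mol %in% which(lab == 1L)
      ctr <- vapply(1:3, function(a) circular_com(xyz[members, a], box[a]),
                    numeric(1))
      xyz <- recenter_coords(xyz, box, ctr)
    } else frac_largest[k] <- NA_real_
    u <- if (axis == "x") abs(xyz[, 1] - box[1] / 2)
         else sqrt(rowSums(sweep(xyz, 2, box / 2, "-")^2))
    h <- findInterval(u, edges, rightmost.closed = TRUE)
    h <- h[h >= 1 & h <= bins]
    counts <- counts + tabulate(h, bins)
  }
  vol <- if (axis == "x") 2 * diff(edges) * box[2] * box[3]
         else 4 * pi / 3 * diff(edges^3)
  conc <- counts / (length(frames) * vol * nmono)
  mid <- (edges[-1] + edges[-(bins + 1)]) / 2
  phase_separated <- !recenter || mean(frac_largest, na.rm = TRUE) >= 0.2
  if (recenter && !phase_separated)
    warning("largest cluster holds <20% of polymers; no dense phase identified")

  out <- list(profile = data.frame(u = mid, conc = conc),
              axis = axis, phase_separated = phase_separated,
              frac_largest = mean(frac_largest))
  ## first guess: interface where the profile crosses its mid level
  cmax <- max(conc); cmin <- min(conc)
  midlev <- (cmax + cmin) / 2
  below <- which(conc < midlev)
  u0_est <- if (length(below) && below[1] > 1) {
    i <- below[1]
    mid[i - 1] + (midlev - conc[i - 1]) / (conc[i] - conc[i - 1]) *
      (mid[i] - mid[i - 1])
  } else umax / 2
  den_reg0 <- mid < 0.7 * u0_est
  dil_reg0 <- mid > u0_est + 0.15 * (umax - u0_est)
  c_den0 <- if (any(den_reg0)) mean(conc[den_reg0]) else cmax
  c_dil0 <- if (any(dil_reg0)) mean(conc[dil_reg0]) else cmin
  bw <- diff(mid[1:2])
  fit <- tryCatch(
    minpack.lm::nlsLM(conc ~ cdil + (cden - cdil) / 2 * (1 - tanh(2 * (mid - u0) / del)),
                      data = data.frame(mid = mid, conc = conc),
                      start = list(cden = c_den0, cdil = max(c_dil0, 1e-12),
                                   u0 = u0_est, del = 2 * bw),
                      lower = c(0, 0, 0, bw / 2),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (!phase_separated) {
    out$c_den <- NA_real_
    out$c_dil <- mean(conc)
    out$delta <- NA_real_; out$u0 <- NA_real_
  } else if (is.null(fit)) {
    out$c_den <- c_den0; out$c_dil <- c_dil0
    out$delta <- NA_real_; out$u0 <- u0_est
  } else {
    cf <- stats::coef(fit)
    out$u0 <- as.numeric(cf[["u0"]])
    out$delta <- as.numeric(cf[["del"]])
    den_reg <- mid < out$u0 - out$delta
    dil_reg <- mid > out$u0 + out$delta
    ## volume-weighted plateau means = count in region / region volume
    out$c_den <- if (any(den_reg))
      sum(conc[den_reg] * vol[den_reg]) / sum(vol[den_reg])
      else as.numeric(cf[["cden"]])
    out$c_dil <- if (any(dil_reg))
      sum(conc[dil_reg] * vol[dil_reg]) / sum(vol[dil_reg])
      else as.numeric(cf[["cdil"]])
    out$fit <- fit
  }
  out$c_den_mM <- nm3_to_mM(out$c_den)
  out$c_dil_mM <- nm3_to_mM(out$c_dil)
  if (axis == "x" && !is.na(out$u0)) {
    out$slab_width <- 2 * out$u0
    out$d <- box[1] / 2 - out$u0
  }
  out
}

#' Diffusion coefficient from mean squared displacement
#'
#' Computes the time-averaged MSD of polymer centres of mass (unwrapped
#' coordinates), averages over polymers, and fits MSD = 6 D t through
#' the origin over lag times up to a quarter of the trajectory length.
#'
#' @param traj a \code{cg_trajectory}.
#' @param polymers optional polymer indices to include (e.g. the dense
#'   or dilute population).
#' @param max_lag_frac largest lag as a fraction of the duration (<= 0.25).
#' @return List with \code{D}, the \code{msd} data frame (lag, msd) and
#'   the fit \code{r_squared}.
#' @export
msd_diffusion <- function(traj, polymers = NULL, max_lag_frac = 0.25) {
  stopifnot(inherits(traj, "cg_trajectory"), max_lag_frac <= 0.25)
  nf <- n_frames(traj)
  nlag <- floor((nf - 1) * max_lag_frac)
  if (nlag < 2) stop("trajectory too short for MSD lags", call. = FALSE)
  npoly <- max(traj$mol)
  if (is.null(polymers)) polymers <- seq_len(npoly)
  ## unwrapped polymer centres of mass, frames x polymers x 3
  com <- array(0, c(nf, length(polymers), 3))
  for (a in 1:3) {
    unw <- traj$coords[, a, ] + traj$images[, a, ] * traj$box[a]
    for (p in seq_along(polymers)) {
      rows <- which(traj$mol == polymers[p])
      com[, p, a] <- colMeans(unw[rows, , drop = FALSE])
    }
  }
  lags <- seq_len(nlag)
  msd <- vapply(lags, function(l) {
    d2 <- (com[(1 + l):nf, , , drop = FALSE] -
           com[1:(nf - l), , , drop = FALSE])^2
    mean(apply(d2, c(1, 2), sum))
  }, numeric(1))
  tlag <- lags * diff(traj$times[1:2])
  D <- sum(msd * tlag) / (6 * sum(tlag^2))
  ss_res <- sum((msd - 6 * D * tlag)^2)
  ss_tot <- sum((msd - mean(msd))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(D = D, msd = data.frame(lag = tlag, msd = msd), r_squared = r2)
}

#' Fractions of unbound stickers per type and phase
#'
#' A sticker counts as bound if a sticker of the other type lies within
#' the attraction distance. Phases are assigned per polymer: members of
#' the largest cluster are dense, the rest dilute.
#'
#' @param state a \code{\link{sim_state}}.
#' @param cutoff bond distance (nm).
#' @param labels optional precomputed cluster labels.
#' @return List \code{f_den_A}, \code{f_den_B}, \code{f_dil_A},
#'   \code{f_dil_B} (NaN where a phase holds no stickers of that type),
#'   plus the per-phase sticker counts.
#' @export
unbound_fractions <- function(state, cutoff = 1, labels = NULL) {
  stopifnot(inherits(state, "sim_state"))
  if (is.null(labels)) labels <- cluster_polymers(state, cutoff)
  cp <- contact_pairs(state, cutoff, unlike_only = TRUE)
  bound <- rep(FALSE, nrow(state$pos))
  if (nrow(cp) > 0) bound[unique(c(cp[, 1], cp[, 2]))] <- TRUE
  dense <- labels[state$mol] == 1L
  res <- list()
  for (ph in c("den", "dil")) for (ty in c("A", "B")) {
    sel <- (if (ph == "den") dense else !dense) &
      state$type == (if (ty == "A") 1L else 2L)
    res[[paste0("f_", ph, "_", ty)]] <- mean(!bound[sel])
    res[[paste0("n_", ph, "_", ty)]] <- sum(sel)
  }
  res
}

#' Bundle phase measurements
#'
#' Collects the quantities measured from trajectories that feed the
#' interface-conductance theory: phase concentrations, diffusion
#' coefficients, interface width, dilute half-width, and unbound
#' fractions, with optional uncertainties.
#'
#' @param c_den,c_dil polymer concentrations (nm^-3).
#' @param D_den,D_dil diffusion coefficients (reduced or physical).
#' @param delta interface width (nm).
#' @param d dilute-phase half-width (nm).
#' @param f_dil_A,f_dil_B,f_den_A,f_den_B unbound fractions.
#' @param sem optional named list of standard errors.
#' @return An object of class \code{phase_measurement}.
#' @export
phase_measurement <- function(c_den, c_dil, D_den = NA, D_dil = NA,
                              delta = NA, d = NA, f_dil_A = NA, f_dil_B = NA,
                              f_den_A = NA, f_den_B = NA, sem = list()) {
  if (!is.na(c_den) && !is.na(c_dil) && c_den <= c_dil)
    stop("c_den must exceed c_dil", call. = FALSE)
  fr <- c(f_dil_A, f_dil_B, f_den_A, f_den_B)
  if (any(!is.na(fr) & (fr < 0 | fr > 1)))
    stop("unbound fractions must lie in [0,1]", call. = FALSE)
  structure(list(c_den = c_den, c_dil = c_dil,
                 c_den_mM = nm3_to_mM(c_den), c_dil_mM = nm3_to_mM(c_dil),
                 D_den = D_den, D_dil = D_dil, delta = delta, d = d,
                 f_dil_A = f_dil_A, f_dil_B = f_dil_B,
                 f_den_A = f_den_A, f_den_B = f_den_B, sem = sem),
            class = "phase_measurement")
}

#' @export
print.phase_measurement <- function(x, ...) {
  cat("Phase measurement\n")
  cat(sprintf("  c_den = %.4g nm^-3 (%.3g mM), c_dil = %.4g nm^-3 (%.3g mM)\n",
              x$c_den, x$c_den_mM, x$c_dil, x$c_dil_mM))
  cat(sprintf("  D_den = %.3g, D_dil = %.3g; delta = %.3g nm, d = %.3g nm\n",
              x$D_den, x$D_dil, x$delta, x$d))
  cat(sprintf("  unbound: dil A %.3g B %.3g | den A %.3g B %.3g\n",
              x$f_dil_A, x$f_dil_B, x$f_den_A, x$f_den_B))
  invisible(x)
}

#' First-half / second-half equilibration diagnostic
#'
#' Splits the frames of a trajectory in two halves and compares a
#' per-half scalar measurement; agreement within its spread indicates
#' the recorded window is equilibrated.
#'
#' @param traj a \code{cg_trajectory}.
#' @param measure function(traj, frames) returning a scalar.
#' @return List with \code{first}, \code{second} and their relative
#'   difference.
#' @export
equilibration_check <- function(traj, measure) {
  nf <- n_frames(traj)
  h1 <- measure(traj, seq_len(floor(nf / 2)))
  h2 <- measure(traj, (floor(nf / 2) + 1):nf)
  list(first = h1, second = h2,
       rel_diff = abs(h1 - h2) / max(abs(h1), abs(h2), 1e-300))
}
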