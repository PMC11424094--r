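#' Survival-labeling protocol for the interface conductance
#'
#' Implements the in-silico labeling experiment: every polymer outside
#' the largest cluster in the first frame is "labeled"; a labeled
#' polymer becomes permanently unlabeled the first time it holds an A-B
#' sticker bond to a dense-phase polymer continuously for longer than
#' \code{entry_multiple} times the isolated-pair bond lifetime (the
#' partner's phase is evaluated when the bond forms). The surviving
#' labeled fraction S(t) decays exponentially with a time constant that
#' \code{\link{slab_kappa_from_decay}} converts into kappa.
#'
#' A bond is treated as continuous across consecutive snapshots; the
#' recording interval must not exceed \code{pair_lifetime/5} so that
#' genuine breaks are not missed.
#'
#' @param traj a \code{cg_trajectory} of a phase-separated system.
#' @param pair_lifetime mean isolated-pair bond lifetime (reduced time),
#'   from \code{\link{isolated_pair_bond_lifetime}}.
#' @param entry_multiple lasting-bond threshold in lifetimes.
#' @param cutoff bond/clustering distance (nm).
#' @param min_labeled minimum labeled polymers for usable statistics.
#' @return An object of class \code{survival_record}: \code{times},
#'   \code{S}, per-polymer \code{entry_times} (NA if never entered),
#'   \code{labeled} ids and \code{decay_tau} from an exponential fit
#'   (NA when S never drops).
#' @export
survival_protocol <- function(traj, pair_lifetime, entry_multiple = 10,
                              cutoff = 1, min_labeled = 10) {
  stopifnot(inherits(traj, "cg_trajectory"), pair_lifetime > 0)
  nf <- n_frames(traj)
  if (nf < 3) stop("trajectory too short", call. = FALSE)
  rec_dt <- stats::median(diff(traj$times))
  if (rec_dt > pair_lifetime / 5)
    stop(sprintf(paste0("recording interval %.3g exceeds pair_lifetime/5 = %.3g; ",
                        "bond continuity cannot be tracked"),
                 rec_dt, pair_lifetime / 5), call. = FALSE)
  threshold <- entry_multiple * pair_lifetime

  st1 <- trajectory_frame(traj, 1)
  lab1 <- cluster_polymers(st1, cutoff)
  labeled <- which(lab1 != 1L)
  if (length(labeled) < min_labeled)
    stop(sprintf("only %d labeled polymers (<%d): statistics too poor",
                 length(labeled), min_labeled), call. = FALSE)
  is_labeled <- rep(FALSE, max(traj$mol))
  is_labeled[labeled] <- TRUE
  entry_times <- rep(NA_real_, max(traj$mol))

  ## active bond runs keyed "sticker_i:sticker_j" -> start time
  runs <- new.env(parent = emptyenv())
  S <- numeric(nf)
  S[1] <- 1
  for (k in 2:nf) {
    st <- trajectory_frame(traj, k)
    lab <- cluster_polymers(st, cutoff)
    dense_poly <- which(lab == 1L)
    cp <- contact_pairs(st, cutoff, unlike_only = TRUE)
    now <- character(0)
    if (nrow(cp) > 0) {
      pi_ <- traj$mol[cp[, 1]]
      pj_ <- traj$mol[cp[, 2]]
      ## bonds between a still-labeled polymer and a dense-phase polymer
      keep <- (is_labeled[pi_] & pj_ %in% dense_poly & pi_ != pj_) |
              (is_labeled[pj_] & pi_ %in% dense_poly & pi_ != pj_)
      if (any(keep)) now <- paste(cp[keep, 1], cp[keep, 2], sep = ":")
    }
    tnow <- traj$times[k]
    for (key in now) {
      if (is.null(runs[[key]])) runs[[key]] <- tnow   # bond formed
      else if (tnow - runs[[key]] > threshold) {
        ij <- as.integer(strsplit(key, ":")[[1]])
        for (p in unique(traj$mol[ij])) {
          if (is_labeled[p]) {
            is_labeled[p] <- FALSE
            entry_times[p] <- tnow
          }
        }
      }
    }
    stale <- setdiff(ls(runs), now)
    if (length(stale)) rm(list = stale, envir = runs)
    S[k] <- sum(is_labeled[labeled]) / length(labeled)
  }

  ## decay time from the decaying part of the curve only: the initial
  ## flat S = 1 stretch (no polymer can unlabel before the lasting-bond
  ## threshold has elapsed) carries no rate information
  decay_tau <- NA_real_
  keep <- S < 1 & S > 0.02
  if (min(S) < 0.9 && sum(keep) >= 4) {
    ft <- stats::lm(log(S[keep]) ~ traj$times[keep])
    sl <- as.numeric(stats::coef(ft)[2])
    if (is.finite(sl) && sl < 0) decay_tau <- -1 / sl
  }
  structure(list(times = traj$times, S = S, labeled = labeled,
                 entry_times = entry_times, decay_tau = decay_tau,
                 threshold = threshold),
            class = "survival_record")
}

#' @export
print.survival_record <- function(x, ...) {
  cat(sprintf("Survival record: %d labeled polymers, %d entries, S(end) = %.3f\n",
              length(x$labeled), sum(!is.na(x$entry_times)), x$S[length(x$S)]))
  if (!is.na(x$decay_tau)) cat(sprintf("  decay tau = %.4g (reduced)\n", x$decay_tau))
  invisible(x)
}

#' Interface conductance from the entry flux
#'
#' At equilibrium the flux of molecules entering the dense phase per
#' unit interface area equals kappa times the dense-phase concentration,
#' so counting entry events directly measures kappa:
#' \code{kappa = entries / (time * area * c_den)}.
#'
#' @param record a \code{survival_record} (entry events), or a numeric
#'   count of entry events.
#' @param area total interface area (nm^2): two cross-sections for a
#'   slab, the sphere surface for a droplet.
#' @param c_den dense-phase polymer concentration (nm^-3).
#' @param total_time observation window; defaults to the record's span.
#' @return kappa (nm per reduced time; divide by 1e-3 * unit time in s
#'   for um/s when a physical unit map is available).
#' @export
flux_kappa <- function(record, area, c_den, total_time = NULL) {
  stopifnot(area > 0, c_den > 0)
  if (inherits(record, "survival_record")) {
    n_entries <- sum(!is.na(record$entry_times))
    if (is.null(total_time)) total_time <- diff(range(record$times))
  } else {
    n_entries <- as.numeric(record)
    if (is.null(total_time)) stop("total_time required with a raw count",
                                  call. = FALSE)
  }
  if (n_entries == 0) stop("no entry events observed", call. = FALSE)
  (n_entries / total_time) / (area * c_den)
}

#' Polymer crossings of the dense-phase boundary
#'
#' Counts polymers entering and leaving the largest cluster between
#' consecutive frames -- a simple membership-based exchange diagnostic;
#' at equilibrium entry and exit rates balance.
#'
#' @param traj a \code{cg_trajectory}.
#' @param cutoff clustering distance (nm).
#' @return Data frame with \code{time}, \code{n_enter}, \code{n_exit}.
#' @export
phase_crossings <- function(traj, cutoff = 1) {
  nf <- n_frames(traj)
  prev <- cluster_polymers(trajectory_frame(traj, 1), cutoff) == 1L
  out <- data.frame(time = traj$times[-1], n_enter = 0L, n_exit = 0L)
  for (k in 2:nf) {
    cur <- cluster_polymers(trajectory_frame(traj, k), cutoff) == 1L
    out$n_enter[k - 1] <- sum(cur & !prev)
    out$n_exit[k - 1] <- sum(!cur & prev)
    prev <- cur
  }
  out
}

#' Droplet radius from dense/dilute mass balance
#'
#' Solves \eqn{\frac{4}{3}\pi R^3 c_{den} + (V_{box} -
#' \frac{4}{3}\pi R^3) c_{dil} = N_{total}} for the effective droplet
#' radius in a closed box.
#'
#' @param c_den,c_dil droplet-system phase concentrations (per-volume
#'   units consistent with \code{V_box}).
#' @param V_box box volume.
#' @param N_total total number of polymers.
#' @return Droplet radius in the length unit of \code{V_box^(1/3)}.
#' @examples
#' # the small-droplet system: ~36.3 nm
#' droplet_radius(mM_to_nm3(8.1), mM_to_nm3(0.073), 286^3, 2000)
#' @export
droplet_radius <- function(c_den, c_dil, V_box, N_total) {
  stopifnot(c_den > c_dil, c_dil >= 0, V_box > 0, N_total >= 0)
  excess <- N_total - V_box * c_dil
  if (excess < 0)
    stop("N_total below the all-dilute amount: no droplet exists", call. = FALSE)
  R <- (3 * excess / (4 * pi * (c_den - c_dil)))^(1 / 3)
  if (4 * pi * R^3 / 3 > V_box)
    stop("mass balance requires a droplet larger than the box", call. = FALSE)
  R
}

#' In-silico FRAP on a simulated droplet
#'
#' For every admissible bleach frame t0, all polymers belonging to the
#' droplet (largest cluster) are marked bleached, and
#' f(lag) = fraction of droplet-resident polymers at t0 + lag that are
#' unbleached. Curves are averaged over all choices of t0 after an
#' equilibration cut, mirroring how simulated FRAP curves are averaged
#' over bleach times.
#'
#' @param traj a \code{cg_trajectory} containing a droplet.
#' @param equil_frac fraction of initial frames discarded before the
#'   first bleach.
#' @param max_lag_frac largest lag as a fraction of the remaining
#'   duration.
#' @param cutoff clustering distance (nm).
#' @return An object of class \code{bleach_record}: \code{times} (lags),
#'   \code{f}, the number of t0 averaged, and
#'   \code{unbleached_fraction0} -- the mean fraction of all polymers
#'   outside the droplet at bleach time (the expected plateau in a
#'   closed box).
#' @export
insilico_frap <- function(traj, equil_frac = 0.2, max_lag_frac = 0.5,
                          cutoff = 1) {
  nf <- n_frames(traj)
  first <- max(1L, ceiling(equil_frac * nf))
  nlag <- floor((nf - first) * max_lag_frac)
  if (nlag < 2) stop("droplet trajectory too short for FRAP lags", call. = FALSE)
  members <- vector("list", nf)
  for (k in first:nf) {
    lab <- cluster_polymers(trajectory_frame(traj, k), cutoff)
    members[[k]] <- which(lab == 1L)
    if (k == first && length(members[[k]]) < 2)
      stop("no droplet identified at the first bleach frame", call. = FALSE)
  }
  npoly <- max(traj$mol)
  t0s <- first:(nf - nlag)
  fsum <- numeric(nlag + 1)
  cnt <- numeric(nlag + 1)
  out0 <- numeric(length(t0s))
  for (it in seq_along(t0s)) {
    t0 <- t0s[it]
    bleached <- members[[t0]]
    out0[it] <- 1 - length(bleached) / npoly
    for (l in 0:nlag) {
      cur <- members[[t0 + l]]
      if (length(cur) == 0) next
      fsum[l + 1] <- fsum[l + 1] + mean(!(cur %in% bleached))
      cnt[l + 1] <- cnt[l + 1] + 1
    }
  }
  lag_dt <- stats::median(diff(traj$times))
  structure(list(times = (0:nlag) * lag_dt, f = fsum / pmax(cnt, 1),
                 n_t0 = length(t0s), unbleached_fraction0 = mean(out0)),
            class = "bleach_record")
}

#' @export
print.bleach_record <- function(x, ...) {
  cat(sprintf("In-silico FRAP: %d lags, averaged over %d bleach times\n",
              length(x$times), x$n_t0))
  cat(sprintf("  f(0) = %.3g, f(end) = %.3g, initial outside fraction %.3g\n",
              x$f[1], x$f[length(x$f)], x$unbleached_fraction0))
  invisible(x)
}

#' Interface touch ("bounce") events of one polymer
#'
#' A touch is a maximal interval of consecutive frames in which any
#' sticker of the polymer lies within \code{cutoff} of a sticker of the
#' dense cluster. A touch counts as an entry when an A-B bond to a
#' dense-phase polymer persisted beyond the lasting-bond threshold
#' during the interval; earlier touches are bounces.
#'
#' @param traj a \code{cg_trajectory}.
#' @param polymer polymer index to follow.
#' @param pair_lifetime isolated-pair bond lifetime (reduced time).
#' @param entry_multiple lasting-bond threshold in lifetimes.
#' @param cutoff contact distance (nm).
#' @return Data frame with \code{start}, \code{end} (times) and
#'   \code{entered}; zero rows if the polymer never touches the cluster.
#' @export
bounce_events <- function(traj, polymer, pair_lifetime, entry_multiple = 10,
                          cutoff = 1) {
  nf <- n_frames(traj)
  threshold <- entry_multiple * pair_lifetime
  mine <- which(traj$mol == polymer)
  touching <- logical(nf)
  bond_run <- 0
  entered_at <- rep(FALSE, nf)
  run_start <- NA_real_
  for (k in seq_len(nf)) {
    st <- trajectory_frame(traj, k)
    lab <- cluster_polymers(st, cutoff)
    if (lab[polymer] == 1L && sum(lab == 1L) > 1) {
      ## polymer absorbed into the largest cluster still counts as touching
      touching[k] <- TRUE
    }
    dense_st <- which(lab[traj$mol] == 1L & traj$mol != polymer)
    if (length(dense_st) > 0) {
      dmin <- min_dist_sets(st$pos[mine, , drop = FALSE],
                            st$pos[dense_st, , drop = FALSE], st$box)
      if (dmin < cutoff) touching[k] <- TRUE
      ## A-B bond persistence to the dense phase
      bonded <- has_ab_bond(st, mine, dense_st, cutoff)
      if (bonded) {
        if (is.na(run_start)) run_start <- traj$times[k]
        if (traj$times[k] - run_start > threshold) entered_at[k] <- TRUE
      } else run_start <- NA_real_
    } else run_start <- NA_real_
  }
  r <- rle(touching)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) return(data.frame(start = numeric(0), end = numeric(0),
                                    entered = logical(0)))
  data.frame(start = traj$times[starts[keep]],
             end = traj$times[ends[keep]],
             entered = vapply(which(keep), function(i)
               any(entered_at[starts[i]:ends[i]]), logical(1)))
}

min_dist_sets <- function(a, b, box) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- sweep(b, 2, a[i, ], "-")
    d <- sweep(d, 2, box, function(v, L) v - L * round(v / L))
    best <- min(best, min(rowSums(d^2)))
  }
  sqrt(best)
}

has_ab_bond <- function(st, mine, others, cutoff) {
  for (i in mine) {
    d <- sweep(st$pos[others, , drop = FALSE], 2, st$pos[i, ], "-")
    d <- sweep(d, 2, st$box, function(v, L) v - L * round(v / L))
    hit <- which(rowSums(d^2) < cutoff^2)
    if (any(st$type[others[hit]] != st$type[i])) return(TRUE)
  }
  FALSE
}
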