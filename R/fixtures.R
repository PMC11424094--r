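#' Deterministic synthetic fixtures
#'
#' Generates small synthetic inputs whose target properties are known by
#' construction, so every analysis operation can be tested without long
#' simulations. Kinds:
#' \describe{
#'   \item{brownian-traj}{independent Brownian walkers with exact
#'     diffusion coefficient \code{D}.}
#'   \item{recovery-curve}{a finite-reservoir recovery curve with chosen
#'     plateau \code{A} and time \code{tau}, plus optional noise.}
#'   \item{slab-config}{a single-frame slab configuration with
#'     prescribed dense/dilute concentrations.}
#'   \item{droplet-config}{a spherical droplet configuration with
#'     prescribed concentrations.}
#'   \item{scripted-exchange-traj}{a trajectory with hand-scheduled
#'     touch/entry events against a static dense cluster.}
#' }
#'
#' @param spec list with \code{kind}, \code{seed} and kind-specific
#'   fields (see the individual \code{fixture_*} functions).
#' @return The generated object.
#' @export
generate_fixture <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$kind))
  seed <- if (is.null(spec$seed)) 1L else spec$seed
  switch(spec$kind,
    "brownian-traj" = fixture_brownian_traj(
      n = spec$n, D = spec$D, dt = spec$dt, n_frames = spec$n_frames,
      box = spec$box, seed = seed),
    "recovery-curve" = fixture_recovery_curve(
      A = spec$A, tau = spec$tau, times = spec$times,
      noise_sd = if (is.null(spec$noise_sd)) 0 else spec$noise_sd,
      seed = seed),
    "slab-config" = fixture_slab_config(
      c_den = spec$c_den, c_dil = spec$c_dil, box = spec$box,
      sequence = if (is.null(spec$sequence)) "A" else spec$sequence,
      seed = seed),
    "droplet-config" = fixture_droplet_config(
      c_den = spec$c_den, c_dil = spec$c_dil, box = spec$box,
      sequence = if (is.null(spec$sequence)) "A" else spec$sequence,
      seed = seed),
    "scripted-exchange-traj" = fixture_scripted_exchange(
      n_dense = spec$n_dense, schedule = spec$schedule,
      n_frames = spec$n_frames, dt = spec$dt, box = spec$box, seed = seed),
    stop(sprintf("unknown fixture kind '%s'", spec$kind), call. = FALSE))
}

#' @rdname generate_fixture
#' @param n number of walkers.
#' @param D diffusion coefficient (length^2 per time).
#' @param dt frame interval.
#' @param n_frames number of frames.
#' @param box box lengths.
#' @param seed RNG seed.
#' @export
fixture_brownian_traj <- function(n, D, dt, n_frames, box, seed = 1) {
  box <- as.numeric(box)
  with_seed(seed, {
    steps <- array(stats::rnorm(n * 3 * n_frames, 0, sqrt(2 * D * dt)),
                   c(n, 3, n_frames))
    start <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                   stats::runif(n, 0, box[3]))
    steps[, , 1] <- 0
    unw <- aperm(apply(steps, c(1, 2), cumsum), c(2, 3, 1)) +
      array(rep(start, n_frames), c(n, 3, n_frames))
    img <- array(0L, c(n, 3, n_frames))
    wrapped <- unw
    for (a in 1:3) {
      sh <- floor(unw[, a, ] / box[a])
      img[, a, ] <- as.integer(sh)
      wrapped[, a, ] <- unw[, a, ] - sh * box[a]
    }
    cg_trajectory(times = dt * seq_len(n_frames), coords = wrapped,
                  type = rep(1L, n), mol = seq_len(n), box = box,
                  images = img)
  })
}

#' @rdname generate_fixture
#' @param A plateau of the finite-reservoir recovery form.
#' @param tau recovery time.
#' @param times sample times.
#' @param noise_sd additive Gaussian noise.
#' @export
fixture_recovery_curve <- function(A, tau, times, noise_sd = 0, seed = 1) {
  f <- A * (1 - exp(-times / (A * tau)))
  if (noise_sd > 0)
    f <- f + with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  recovery_curve(times, pmax(f, 0))
}

## place chains of 'sequence' as compact confined random walks; 'inside'
## maps a point to TRUE (dense region) or FALSE
place_chains <- function(n_chain, sequence, box, sample_start, confine,
                         step = 1.5) {
  nmono <- nchar(sequence)
  out <- matrix(0, n_chain * nmono, 3)
  for (p in seq_len(n_chain)) {
    at <- sample_start()
    for (k in seq_len(nmono)) {
      out[(p - 1) * nmono + k, ] <- at
      repeat {
        s <- stats::rnorm(3)
        cand <- at + s / sqrt(sum(s^2)) * step
        if (confine(cand)) { at <- cand; break }
      }
    }
  }
  out
}

#' @rdname generate_fixture
#' @param c_den,c_dil target polymer concentrations (nm^-3).
#' @param sequence chain sequence (default a single sticker, giving the
#'   sharpest profiles).
#' @export
fixture_slab_config <- function(c_den, c_dil, box, sequence = "A", seed = 1) {
  stopifnot(c_den > c_dil, c_dil >= 0)
  box <- as.numeric(box)
  V <- prod(box)
  w <- 0.3 * box[1]                      # slab width
  n_den <- round(c_den * w * box[2] * box[3])
  n_dil <- round(c_dil * (V - w * box[2] * box[3]))
  if (n_den < 1) stop("infeasible slab fixture: no dense chains", call. = FALSE)
  lo <- (box[1] - w) / 2; hi <- (box[1] + w) / 2
  sequence <- expand_sequence(sequence)
  nmono <- nchar(sequence)
  ## starting x stratified across each region so the realised density
  ## matches the target to rounding accuracy, not sqrt(N) sampling noise
  with_seed(seed, {
    iden <- 0L
    pos_den <- place_chains(n_den, sequence, box,
      sample_start = function() {
        iden <<- iden + 1L
        c(lo + (iden - 0.5) / n_den * w,
          stats::runif(1, 0, box[2]), stats::runif(1, 0, box[3]))
      },
      confine = function(p) p[1] > lo && p[1] < hi)
    idil <- 0L
    pos_dil <- if (n_dil > 0) place_chains(n_dil, sequence, box,
      sample_start = function() {
        idil <<- idil + 1L
        x <- (idil - 0.5) / n_dil * (box[1] - w)
        x <- if (x < lo) x else x + w
        c(x, stats::runif(1, 0, box[2]), stats::runif(1, 0, box[3]))
      },
      confine = function(p) {
        x <- p[1] - box[1] * floor(p[1] / box[1])
        x < lo | x > hi
      }) else matrix(0, 0, 3)
    pos <- rbind(pos_den, pos_dil)
    pos <- sweep(pos, 2, box, function(a, L) a - L * floor(a / L))
    nch <- n_den + n_dil
    typ <- rep(as.integer(chartr("AB", "12", strsplit(sequence, "")[[1]])), nch)
    sim_state(pos, typ, rep(seq_len(nch), each = nmono), box)
  })
}

#' @rdname generate_fixture
#' @export
fixture_droplet_config <- function(c_den, c_dil, box, sequence = "A",
                                   seed = 1) {
  stopifnot(c_den > c_dil, c_dil >= 0)
  box <- as.numeric(box)
  V <- prod(box)
  Vd <- 0.15 * V
  Rd <- (3 * Vd / (4 * pi))^(1 / 3)
  if (2 * Rd > min(box)) stop("droplet does not fit the box", call. = FALSE)
  n_den <- round(c_den * Vd)
  n_dil <- round(c_dil * (V - Vd))
  ctr <- box / 2
  sequence <- expand_sequence(sequence)
  nmono <- nchar(sequence)
  with_seed(seed, {
    rad_sample <- function(rmax, rmin = 0) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      r <- ((rmax^3 - rmin^3) * stats::runif(1) + rmin^3)^(1 / 3)
      ctr + u * r
    }
    pos_den <- place_chains(n_den, sequence, box,
      sample_start = function() rad_sample(Rd),
      confine = function(p) sum((p - ctr)^2) < Rd^2)
    pos_dil <- if (n_dil > 0) place_chains(n_dil, sequence, box,
      sample_start = function() {
        repeat {
          p <- stats::runif(3) * box
          if (sum((p - ctr)^2) > (Rd + 1)^2) return(p)
        }
      },
      confine = function(p) {
        q <- p - box * floor(p / box)
        sum((q - ctr)^2) > Rd^2
      }) else matrix(0, 0, 3)
    pos <- rbind(pos_den, pos_dil)
    pos <- sweep(pos, 2, box, function(a, L) a - L * floor(a / L))
    nch <- n_den + n_dil
    typ <- rep(as.integer(chartr("AB", "12", strsplit(sequence, "")[[1]])), nch)
    sim_state(pos, typ, rep(seq_len(nch), each = nmono), box)
  })
}

#' @rdname generate_fixture
#' @param n_dense polymers forming the static dense cluster.
#' @param schedule data frame with one row per scripted dilute polymer:
#'   \code{touch_start}, \code{touch_end} (frame indices of a contact
#'   interval; NA for no contact) and \code{enters} (logical: the
#'   contact persists to the end of the trajectory, so a lasting bond
#'   forms during it).
#' @export
fixture_scripted_exchange <- function(n_dense, schedule, n_frames, dt = 1,
                                      box = c(120, 40, 40), seed = 1) {
  stopifnot(n_dense >= 2, is.data.frame(schedule), n_frames >= 2)
  box <- as.numeric(box)
  n_dil <- nrow(schedule)
  nmono <- 2L                             # AB dimers keep bookkeeping simple
  n <- (n_dense + n_dil) * nmono
  ctr <- box / 2
  ## static dense cluster: a line of B-A dimers; the 0.8 nm gap between
  ## one dimer's A and the next dimer's B keeps the line connected under
  ## the 1 nm clustering rule
  dense_pos <- matrix(0, n_dense * nmono, 3)
  for (p in seq_len(n_dense)) {
    base <- ctr + c((p - 1) * 1.6 - (n_dense - 1) * 0.8, 0, 0)
    dense_pos[(p - 1) * 2 + 1, ] <- base
    dense_pos[(p - 1) * 2 + 2, ] <- base + c(0.8, 0, 0)
  }
  ## parked positions for dilute polymers, away from the cluster and from
  ## each other (3 nm spacing > the 1 nm contact rule)
  park <- matrix(0, n_dil * nmono, 3)
  for (q in seq_len(n_dil)) {
    base <- c(3 + (q - 1) * 3, 5, 5)
    if (base[1] > box[1] - 3)
      stop("too many scripted polymers for the box", call. = FALSE)
    park[(q - 1) * 2 + 1, ] <- base
    park[(q - 1) * 2 + 2, ] <- base + c(0.8, 0, 0)
  }
  ## contact sites: 0.5 nm from the A sticker of successive dense dimers,
  ## slightly staggered so many polymers can touch simultaneously
  site_of <- function(q) {
    host <- ((q - 1) %% n_dense) + 1
    dense_pos[(host - 1) * 2 + 2, ] + c(0, 0, 0.5 + 0.04 * ((q - 1) %/% n_dense))
  }
  coords <- array(0, c(n, 3, n_frames))
  for (k in seq_len(n_frames)) {
    fr <- rbind(dense_pos, park)
    for (q in seq_len(n_dil)) {
      ts <- schedule$touch_start[q]; te <- schedule$touch_end[q]
      if (!is.na(ts) && k >= ts && k <= te) {
        i1 <- n_dense * 2 + (q - 1) * 2 + 1
        fr[i1, ] <- site_of(q)
        fr[i1 + 1, ] <- fr[i1, ] + c(0, 3, 0)
      }
    }
    coords[, , k] <- fr
  }
  typ <- rep(c(2L, 1L), n_dense + n_dil)   # B-A dimers: first sticker B
  mol <- rep(seq_len(n_dense + n_dil), each = nmono)
  cg_trajectory(times = dt * seq_len(n_frames), coords = coords,
                type = typ, mol = mol, box = box)
}
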