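#' Specification of a polymer system
#'
#' Describes a set of identical linear sticker-spacer polymers in a
#' periodic box. The sequence is a string over \{A, B\}; \code{"A6B6"}
#' style run-length shorthand is accepted and expanded.
#'
#' @param sequence sticker sequence, e.g. \code{"AAAAAABBBBBB"} or
#'   \code{"A6B6"}.
#' @param n_polymers number of chains.
#' @param box three box lengths (nm).
#' @param geometry \code{"slab"} (chains initialised in a central slab
#'   along x, the phase-separated starting point) or \code{"cubic"}
#'   (uniform, or a central sphere for droplet initialisation via
#'   \code{\link{build_system}}).
#' @return An object of class \code{polymer_spec}.
#' @examples
#' polymer_spec("A6B6", 100, c(100, 35, 35))
#' @export
polymer_spec <- function(sequence, n_polymers, box,
                         geometry = c("slab", "cubic")) {
  geometry <- match.arg(geometry)
  sequence <- expand_sequence(sequence)
  if (nchar(sequence) == 0) stop("sequence must be non-empty", call. = FALSE)
  if (!grepl("^[AB]+$", sequence))
    stop("sequence must use only A and B", call. = FALSE)
  if (n_polymers < 1) stop("n_polymers must be >= 1", call. = FALSE)
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths",
                                              call. = FALSE)
  structure(list(sequence = sequence, n_polymers = as.integer(n_polymers),
                 box = box, geometry = geometry),
            class = "polymer_spec")
}

## "A6B6" -> "AAAAAABBBBBB"; already-expanded strings pass through
expand_sequence <- function(s) {
  if (length(s) != 1L || !is.character(s) || grepl("[^AB0-9]", s))
    stop("sequence must use only A and B (optionally with repeat counts)",
         call. = FALSE)
  if (!grepl("[0-9]", s)) return(s)
  m <- gregexpr("[AB][0-9]*", s)[[1]]
  parts <- regmatches(s, gregexpr("[AB][0-9]*", s))[[1]]
  paste(vapply(parts, function(p) {
    ch <- substr(p, 1, 1)
    k <- if (nchar(p) > 1) as.integer(substr(p, 2, nchar(p))) else 1L
    paste(rep(ch, k), collapse = "")
  }, character(1)), collapse = "")
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat(sprintf("%d polymers of sequence %s (%d stickers each)\n",
              x$n_polymers, x$sequence, nchar(x$sequence)))
  cat(sprintf("  box %g x %g x %g nm, %s initialisation\n",
              x$box[1], x$box[2], x$box[3], x$geometry))
  invisible(x)
}

## evaluate expr with a temporarily seeded R RNG, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation state constructor
#'
#' @param pos n x 3 sticker positions (nm), wrapped into the box.
#' @param type integer sticker types (1 = A, 2 = B).
#' @param mol integer molecule index per sticker (1-based, contiguous).
#' @param box three box lengths (nm).
#' @param vel n x 3 velocities; zeros if omitted.
#' @param images n x 3 integer periodic image counts.
#' @param time simulation time (reduced units).
#' @return An object of class \code{sim_state}.
#' @export
sim_state <- function(pos, type, mol, box, vel = NULL, images = NULL,
                      time = 0) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  stopifnot(ncol(pos) == 3, length(type) == n, length(mol) == n,
            length(box) == 3)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  if (is.null(images)) images <- matrix(0L, n, 3)
  storage.mode(images) <- "integer"
  structure(list(pos = pos, vel = as.matrix(vel), images = images,
                 type = as.integer(type), mol = as.integer(mol),
                 box = as.numeric(box), time = time),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("Simulation state: %d stickers, %d polymers, t = %g\n",
              nrow(x$pos), max(x$mol), x$time))
  cat(sprintf("  box %g x %g x %g nm; %d A, %d B stickers\n",
              x$box[1], x$box[2], x$box[3], sum(x$type == 1L), sum(x$type == 2L)))
  invisible(x)
}

#' Build an initial polymer configuration
#'
#' Places each chain as a random walk with steps near the thermal bond
#' length (about 3.9 nm at default parameters), wraps into the periodic
#' box, and relaxes overlaps with a displacement-capped steepest-descent
#' push on the repulsive and bond terms. Deterministic given the seed.
#'
#' @param spec a \code{\link{polymer_spec}}.
#' @param ff a \code{\link{force_field}}.
#' @param seed integer RNG seed.
#' @param kBT temperature used to draw initial velocities.
#' @param region \code{"auto"} uses the spec geometry (slab: central slab
#'   along x sized for a dense phase; cubic: whole box); \code{"uniform"},
#'   \code{"slab"} or \code{"sphere"} override. For slab/sphere the dense
#'   region is sized from \code{dense_frac}.
#' @param dense_frac fraction of the box volume used for the initial
#'   dense region (slab or sphere initialisation).
#' @param minimize_steps overlap-relaxation iterations.
#' @return A \code{\link{sim_state}}.
#' @export
build_system <- function(spec, ff = force_field(), seed = 1, kBT = 1,
                         region = "auto", dense_frac = 0.2,
                         minimize_steps = 200) {
  stopifnot(inherits(spec, "polymer_spec"))
  nmono <- nchar(spec$sequence)
  n <- spec$n_polymers * nmono
  box <- spec$box
  if (region == "auto") region <- switch(spec$geometry, slab = "slab",
                                         cubic = "uniform")
  b <- mean_bond_length(ff, kBT = kBT)
  if (b >= min(box))
    stop("box too small for the bond length; packing failure", call. = FALSE)
  typ <- rep(as.integer(chartr("AB", "12", strsplit(spec$sequence, "")[[1]])),
             spec$n_polymers)
  mol <- rep(seq_len(spec$n_polymers), each = nmono)
  pos <- with_seed(seed, {
    starts <- switch(region,
      uniform = cbind(stats::runif(spec$n_polymers, 0, box[1]),
                      stats::runif(spec$n_polymers, 0, box[2]),
                      stats::runif(spec$n_polymers, 0, box[3])),
      slab = {
        w <- box[1] * dense_frac
        cbind(stats::runif(spec$n_polymers, (box[1] - w) / 2, (box[1] + w) / 2),
              stats::runif(spec$n_polymers, 0, box[2]),
              stats::runif(spec$n_polymers, 0, box[3]))
      },
      sphere = {
        rad <- (3 * prod(box) * dense_frac / (4 * pi))^(1 / 3)
        u <- matrix(stats::rnorm(3 * spec$n_polymers), ncol = 3)
        u <- u / sqrt(rowSums(u^2)) * rad * stats::runif(spec$n_polymers)^(1 / 3)
        sweep(u, 2, box / 2, "+")
      },
      stop("unknown region", call. = FALSE))
    out <- matrix(0, n, 3)
    for (p in seq_len(spec$n_polymers)) {
      at <- starts[p, ]
      for (k in seq_len(nmono)) {
        out[(p - 1) * nmono + k, ] <- at
        step <- stats::rnorm(3)
        at <- at + step / sqrt(sum(step^2)) * b
      }
    }
    out <- sweep(out, 2, box, function(a, L) a - L * floor(a / L))
    out
  })
  img <- matrix(0L, n, 3)
  rel <- minimize_cpp(pos, img, typ, mol, box, unclass(ff),
                      as.integer(minimize_steps), 0.05)
  vel <- with_seed(seed + 1L, matrix(stats::rnorm(n * 3, 0, sqrt(kBT)), n, 3))
  st <- sim_state(rel$pos, typ, mol, box, vel = vel, images = matrix(0L, n, 3))
  d <- bond_lengths(st)
  if (any(d >= ff$R0))
    stop("packing failure: a bond exceeds R0 after relaxation", call. = FALSE)
  st
}

#' Chain bond lengths of a state
#'
#' @param state a \code{\link{sim_state}}.
#' @return Minimum-image lengths (nm) of all consecutive same-chain bonds.
#' @export
bond_lengths <- function(state) {
  n <- nrow(state$pos)
  i <- which(state$mol[-n] == state$mol[-1])
  d <- state$pos[i + 1L, , drop = FALSE] - state$pos[i, , drop = FALSE]
  d <- sweep(d, 2, state$box, function(a, L) a - L * round(a / L))
  sqrt(rowSums(d^2))
}

#' Run Langevin dynamics
#'
#' Integrates underdamped Langevin dynamics with the BAOAB splitting.
#' With \code{gamma = 0} and \code{kBT = 0} this reduces to velocity
#' Verlet and conserves energy; with interactions switched off each
#' sticker diffuses with \code{D = kBT/gamma}. Reduced units: length nm,
#' energy kBT, friction gamma per sticker; unit time is
#' \code{gamma nm^2 / kBT}.
#'
#' @param state a \code{\link{sim_state}}.
#' @param ff a \code{\link{force_field}}.
#' @param n_steps number of timesteps.
#' @param dt timestep (reduced time); default 1e-3.
#' @param kBT temperature.
#' @param gamma friction per sticker.
#' @param mass sticker mass (reduced).
#' @param seed integer seed for the thermostat noise.
#' @param record_every store a snapshot every this many steps.
#' @return A \code{cg_trajectory}: snapshot times, wrapped positions and
#'   periodic image counts (\code{n x 3 x n_frames} arrays), topology,
#'   per-frame potential/kinetic energies, and the final
#'   \code{\link{sim_state}} in \code{$final_state}.
#' @export
run_langevin <- function(state, ff = force_field(), n_steps, dt = 1e-3,
                         kBT = 1, gamma = 1, mass = 1, seed = 1,
                         record_every = 100) {
  stopifnot(inherits(state, "sim_state"), n_steps >= record_every)
  res <- run_langevin_cpp(state$pos, state$vel, state$images, state$type,
                          state$mol, state$box, unclass(ff),
                          as.integer(n_steps), dt, kBT, gamma, mass,
                          as.numeric(seed), as.integer(record_every),
                          state$time)
  traj <- structure(list(
    times = res$times,
    coords = res$pos, images = res$img,
    type = state$type, mol = state$mol, box = state$box,
    pe = res$pe, ke = res$ke,
    dt = dt, record_every = as.integer(record_every),
    ff = ff), class = "cg_trajectory")
  traj$final_state <- sim_state(res$final_pos, state$type, state$mol,
                                state$box, vel = res$final_vel,
                                images = res$final_img,
                                time = res$final_time)
  traj
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d stickers, %d polymers\n",
              length(x$times), dim(x$coords)[1], max(x$mol)))
  cat(sprintf("  t in [%g, %g] (reduced), box %g x %g x %g nm\n",
              min(x$times), max(x$times), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Extract one frame of a trajectory as a state
#'
#' @param traj a \code{cg_trajectory}.
#' @param frame frame index.
#' @return A \code{\link{sim_state}} (velocities zero except for the
#'   final frame, which is available as \code{traj$final_state}).
#' @export
trajectory_frame <- function(traj, frame) {
  stopifnot(inherits(traj, "cg_trajectory"),
            frame >= 1, frame <= length(traj$times))
  sim_state(traj$coords[, , frame], traj$type, traj$mol, traj$box,
            images = traj$images[, , frame], time = traj$times[frame])
}

#' Mean bond lifetime of an isolated sticker pair
#'
#' Simulates a single A and a single B sticker in a small periodic box
#' and measures the mean duration of contiguous intervals with
#' separation below the attraction range r0 (the bond criterion used
#' throughout). With \code{U0 = 0} this is the free-diffusion escape
#' time from the contact shell; it grows approximately exponentially in
#' U0.
#'
#' @param ff a \code{\link{force_field}}.
#' @param box_length cubic box side (nm).
#' @param dt timestep.
#' @param kBT,gamma,mass Langevin parameters.
#' @param seed RNG seed.
#' @param n_events number of completed bond intervals to collect (>= 100
#'   recommended).
#' @param max_steps hard cap on integration steps.
#' @return List with \code{mean} lifetime (reduced time), \code{sem},
#'   \code{n_events} and the raw \code{lifetimes}.
#' @export
isolated_pair_bond_lifetime <- function(ff = force_field(), box_length = 8,
                                        dt = 1e-3, kBT = 1, gamma = 1,
                                        mass = 1, seed = 1, n_events = 200,
                                        max_steps = 5e7) {
  res <- pair_lifetime_cpp(unclass(ff), box_length, dt, kBT, gamma, mass,
                           as.numeric(seed), as.integer(n_events), max_steps)
  lt <- res$lifetimes
  list(mean = mean(lt), sem = stats::sd(lt) / sqrt(length(lt)),
       n_events = res$n_events, lifetimes = lt)
}
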