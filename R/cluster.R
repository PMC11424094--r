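#' Trajectory container
#'
#' Assembles a coarse-grained trajectory from snapshot arrays. Mostly
#' used by fixture generators and file readers;
#' \code{\link{run_langevin}} builds its result directly.
#'
#' @param times strictly increasing snapshot times (reduced units).
#' @param coords \code{n x 3 x n_frames} array of wrapped positions (nm).
#' @param type,mol per-sticker type (1 = A, 2 = B) and molecule index.
#' @param box three box lengths (nm).
#' @param images optional \code{n x 3 x n_frames} integer array of
#'   periodic image counts (zeros if omitted).
#' @return An object of class \code{cg_trajectory}.
#' @export
cg_trajectory <- function(times, coords, type, mol, box, images = NULL) {
  coords <- as.array(coords)
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3,
            dim(coords)[3] == length(times))
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (is.null(images)) images <- array(0L, dim(coords))
  storage.mode(images) <- "integer"
  structure(list(times = as.numeric(times), coords = coords, images = images,
                 type = as.integer(type), mol = as.integer(mol),
                 box = as.numeric(box)),
            class = "cg_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a \code{cg_trajectory}.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$times)

#' One-frame trajectory from a state
#' @param state a \code{\link{sim_state}}.
#' @return A \code{cg_trajectory} with a single frame.
#' @export
state_trajectory <- function(state) {
  n <- nrow(state$pos)
  cg_trajectory(times = max(state$time, 1e-12),
                coords = array(state$pos, c(n, 3, 1)),
                type = state$type, mol = state$mol, box = state$box,
                images = array(state$images, c(n, 3, 1)))
}

#' Group polymers into connected clusters
#'
#' Two stickers are connected if they belong to the same polymer or if
#' they are within the attraction distance (default r0 = 1 nm, minimum
#' image); polymers sharing connected stickers form one cluster. Labels
#' are ordered by decreasing cluster size, so label 1 identifies the
#' largest cluster -- used throughout as the dense phase.
#'
#' @param state a \code{\link{sim_state}}.
#' @param cutoff connection distance (nm).
#' @return Integer vector of cluster labels, one per polymer.
#' @export
cluster_polymers <- function(state, cutoff = 1) {
  stopifnot(inherits(state, "sim_state"), cutoff > 0)
  cluster_polymers_cpp(state$pos, state$type, state$mol, state$box, cutoff)
}

#' Sticker contact pairs
#'
#' All sticker pairs within \code{cutoff} (minimum image), optionally
#' restricted to unlike types -- the criterion for an A-B bond.
#'
#' @param state a \code{\link{sim_state}}.
#' @param cutoff contact distance (nm).
#' @param unlike_only keep only A-B pairs.
#' @return Two-column integer matrix of sticker indices.
#' @export
contact_pairs <- function(state, cutoff = 1, unlike_only = TRUE) {
  stopifnot(inherits(state, "sim_state"))
  contact_pairs_cpp(state$pos, state$type, state$mol, state$box,
                    cutoff, unlike_only)
}
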