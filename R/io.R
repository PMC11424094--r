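#' Write and read trajectories as extended XYZ text
#'
#' One block per frame: atom count, a comment line carrying
#' \code{time=... box=...}, then \code{element x y z mol} records
#' (element A or B). Readable by standard visualisation tools; the
#' extra molecule column round-trips the topology.
#'
#' @param traj a \code{cg_trajectory}.
#' @param path output file.
#' @return \code{write_xyz}: the path, invisibly. \code{read_xyz}: a
#'   \code{cg_trajectory} (image counts are not stored in XYZ and read
#'   back as zero).
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "cg_trajectory"))
  n <- dim(traj$coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  el <- c("A", "B")[traj$type]
  for (k in seq_len(n_frames(traj))) {
    writeLines(as.character(n), con)
    writeLines(sprintf("time=%.10g box=%.10g,%.10g,%.10g", traj$times[k],
                       traj$box[1], traj$box[2], traj$box[3]), con)
    writeLines(sprintf("%s %.8f %.8f %.8f %d", el,
                       traj$coords[, 1, k], traj$coords[, 2, k],
                       traj$coords[, 3, k], traj$mol), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed XYZ file: too short", call. = FALSE)
  pos <- 1L
  frames <- list(); times <- numeric(0); box <- NULL
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- suppressWarnings(as.integer(lines[pos]))
    if (is.na(n)) stop(sprintf("parse error at line %d: expected atom count",
                               pos), call. = FALSE)
    cm <- lines[pos + 1L]
    tm <- as.numeric(sub(".*time=([-0-9.eE+]+).*", "\\1", cm))
    bx <- as.numeric(strsplit(sub(".*box=([-0-9.eE+,]+).*", "\\1", cm), ",")[[1]])
    if (length(bx) != 3 || any(is.na(bx)))
      stop(sprintf("parse error at line %d: bad box spec", pos + 1L),
           call. = FALSE)
    rows <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    bad <- which(lengths(parts) < 4)
    if (length(bad))
      stop(sprintf("parse error at line %d: expected 'el x y z [mol]'",
                   pos + 1L + bad[1]), call. = FALSE)
    el <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    ml <- if (all(lengths(parts) >= 5))
      vapply(parts, function(p) as.integer(p[5]), integer(1))
      else seq_len(n)
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, tm)
    box <- bx
    if (length(frames) == 1L) { type1 <- match(el, c("A", "B")); mol1 <- ml }
    pos <- pos + 2L + n
  }
  coords <- array(unlist(frames), c(nrow(frames[[1]]), 3, length(frames)))
  cg_trajectory(times, coords, type1, mol1, box)
}

#' Write and read LAMMPS-style dump text
#'
#' Standard \code{ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS pp pp pp
#' / ATOMS id type mol x y z} blocks, atoms sorted by id. Timesteps are
#' the snapshot times divided by \code{dt} (rounded).
#'
#' @param traj a \code{cg_trajectory}.
#' @param path output file.
#' @param dt time per timestep used to convert snapshot times.
#' @return \code{write_lammps_dump}: the path, invisibly;
#'   \code{read_lammps_dump}: a \code{cg_trajectory}.
#' @export
write_lammps_dump <- function(traj, path, dt = 1) {
  stopifnot(inherits(traj, "cg_trajectory"))
  n <- dim(traj$coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(c("ITEM: TIMESTEP", as.character(round(traj$times[k] / dt)),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0 %.10g", traj$box[1]),
                 sprintf("0 %.10g", traj$box[2]),
                 sprintf("0 %.10g", traj$box[3]),
                 "ITEM: ATOMS id type mol x y z"), con)
    writeLines(sprintf("%d %d %d %.8f %.8f %.8f", seq_len(n), traj$type,
                       traj$mol, traj$coords[, 1, k], traj$coords[, 2, k],
                       traj$coords[, 3, k]), con)
  }
  invisible(path)
}

#' @rdname write_lammps_dump
#' @export
read_lammps_dump <- function(path, dt = 1) {
  lines <- readLines(path)
  idx <- which(lines == "ITEM: TIMESTEP")
  if (!length(idx)) stop("parse error: no ITEM: TIMESTEP found", call. = FALSE)
  frames <- list(); times <- numeric(0)
  for (s in idx) {
    step <- as.numeric(lines[s + 1L])
    n <- as.integer(lines[s + 3L])
    box <- vapply(lines[(s + 5L):(s + 7L)],
                  function(l) diff(as.numeric(strsplit(trimws(l), "\\s+")[[1]])),
                  numeric(1), USE.NAMES = FALSE)
    hdr <- s + 8L
    rows <- strsplit(trimws(lines[(hdr + 1L):(hdr + n)]), "\\s+")
    bad <- which(lengths(rows) != 6)
    if (length(bad))
      stop(sprintf("parse error at line %d: expected 6 columns",
                   hdr + bad[1]), call. = FALSE)
    m <- t(vapply(rows, as.numeric, numeric(6)))
    m <- m[order(m[, 1]), , drop = FALSE]
    frames[[length(frames) + 1L]] <- m
    times <- c(times, step * dt)
  }
  m1 <- frames[[1]]
  coords <- array(unlist(lapply(frames, function(m) m[, 4:6])),
                  c(nrow(m1), 3, length(frames)))
  cg_trajectory(times, coords, as.integer(m1[, 2]), as.integer(m1[, 3]), box)
}

#' Write and read recovery curves as CSV with metadata header
#'
#' Header lines of the form \code{# key: value} (units, seed, config
#' hash, ...) precede a \code{time,f} table.
#'
#' @param curve a \code{\link{recovery_curve}} (or any list with
#'   \code{times} and \code{f}).
#' @param path output file.
#' @param meta named list written into the header.
#' @return \code{write_curve_csv}: the path, invisibly;
#'   \code{read_curve_csv}: a \code{recovery_curve} with a \code{meta}
#'   attribute.
#' @export
write_curve_csv <- function(curve, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
  writeLines("time,f", con)
  writeLines(sprintf("%.12g,%.12g", curve$times, curve$f), con)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    k <- sub(":.*$", "", kv)
    meta[[trimws(k)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("time", "f") %in% names(df)))
    stop("parse error: curve CSV needs 'time' and 'f' columns", call. = FALSE)
  cv <- recovery_curve(df$time, df$f)
  attr(cv, "meta") <- meta
  cv
}

## recognised configuration sections and keys
config_schema <- list(
  params = c("R", "D_den", "D_dil", "c_den", "c_dil", "kappa"),
  polymer = c("sequence", "n_polymers", "box", "geometry"),
  forcefield = c("K", "R0", "U0", "r0", "epsilon", "sigma", "rc"),
  run = c("n_steps", "dt", "kBT", "gamma", "mass", "record_every", "seed"),
  frap = c("outer_radius", "t_max", "n_inner", "n_times"),
  fixture = c("kind", "n", "D", "dt", "n_frames", "box", "A", "tau",
              "noise_sd", "times", "c_den", "c_dil", "sequence", "n_dense",
              "schedule", "seed"),
  output = c("out", "format"))

#' Read, validate, and write run configurations
#'
#' Configurations are nested lists with sections named after the
#' parameter bundles they fill (\code{params}, \code{polymer},
#' \code{forcefield}, \code{run}, \code{frap}, \code{fixture},
#' \code{output}). Unknown sections or keys are rejected. YAML or JSON
#' is chosen by file extension; configs round-trip losslessly.
#'
#' @param path file ending in .yaml, .yml or .json.
#' @param config a configuration list.
#' @return \code{read_config}: the validated list; \code{write_config}:
#'   the path, invisibly.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("config must be .yaml/.yml/.json", call. = FALSE))
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(config, path),
    json = jsonlite::write_json(config, path, auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
    stop("config must be .yaml/.yml/.json", call. = FALSE))
  invisible(path)
}

validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list", call. = FALSE)
  bad <- setdiff(names(cfg), names(config_schema))
  if (length(bad))
    stop(sprintf("unknown config section(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in [%s]: %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Hash of a configuration
#'
#' MD5 of the canonical (recursively name-sorted) JSON serialisation;
#' changes if and only if some parameter changes.
#'
#' @param config a configuration list.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(canon(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Write a measurement or record as JSON with provenance
#'
#' @param x a list-like object (e.g. \code{\link{phase_measurement}},
#'   survival or bleach records).
#' @param path output .json path.
#' @param provenance optional list (config, seed, package version) added
#'   under \code{$provenance}; the package version is always included.
#' @return The path, invisibly.
#' @export
write_measurement_json <- function(x, path, provenance = list()) {
  provenance$package <- as.character(utils::packageVersion("condex"))
  out <- c(unclass(x), list(provenance = provenance))
  out <- lapply(out, function(v) if (inherits(v, "nls")) NULL else v)
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
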