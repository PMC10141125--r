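#' Write coordinates or a trajectory in XYZ format
#'
#' Standard multi-frame XYZ: per frame an atom count, a comment line holding
#' the frame time, then `El x y z` rows.  Polymer beads are written as `C`
#' with the ring index appended in a trailing column; wall beads (if
#' included) as `W`.
#'
#' @param x A `polymer_trajectory`, a `polymer_system`, or an N x 3 matrix.
#' @param path Output file.
#' @param wall Optionally a [build_pore_system()] object whose wall beads are
#'   appended to every frame.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, wall = NULL) {
  frames <- if (inherits(x, "polymer_trajectory")) {
    lapply(seq_along(x$times), function(f) list(t = x$times[f],
                                                xyz = x$coords[f, , ]))
  } else if (inherits(x, "polymer_system")) {
    list(list(t = 0, xyz = x$coords))
  } else {
    list(list(t = 0, xyz = as.matrix(x)))
  }
  ring <- if (inherits(x, "polymer_trajectory")) x$topology$ring_of_bead
          else if (inherits(x, "polymer_system")) x$topology$ring_of_bead
          else rep(1L, nrow(frames[[1]]$xyz))
  wxyz <- if (!is.null(wall)) wall$wall else NULL
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$xyz) + if (is.null(wxyz)) 0L else nrow(wxyz)
    writeLines(as.character(n), con)
    writeLines(sprintf("t= %.6f", fr$t), con)
    writeLines(sprintf("C %.6f %.6f %.6f %d", fr$xyz[, 1], fr$xyz[, 2],
                       fr$xyz[, 3], ring), con)
    if (!is.null(wxyz))
      writeLines(sprintf("W %.6f %.6f %.6f 0", wxyz[, 1], wxyz[, 2],
                         wxyz[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' @param path XYZ file written by [write_xyz()] (or any XYZ whose comment
#'   line carries `t= <time>`; missing times become the frame index).
#' @return List with `times`, `coords` array `[frames, atoms, 3]`,
#'   `element` (first frame's element column), and `ring` (trailing integer
#'   column when present).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  times <- numeric(0)
  frames <- list()
  element <- NULL
  ring <- NULL
  while (pos <= length(lines)) {
    n <- as.integer(lines[pos])
    cm <- lines[pos + 1L]
    tm <- suppressWarnings(as.numeric(sub("^t=\\s*", "", cm)))
    times <- c(times, if (is.na(tm)) length(frames) + 1 else tm)
    rows <- strsplit(trimws(lines[pos + 1L + seq_len(n)]), "\\s+")
    mat <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (is.null(element)) {
      element <- vapply(rows, `[`, character(1), 1)
      if (all(lengths(rows) >= 5))
        ring <- as.integer(vapply(rows, `[`, character(1), 5))
    }
    frames[[length(frames) + 1L]] <- mat
    pos <- pos + 2L + n
  }
  coords <- array(0, dim = c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  list(times = times, coords = coords, element = element, ring = ring)
}

#' Write a LAMMPS data file (atoms + bonds)
#'
#' Writes the polymer and wall as a LAMMPS `data` file with `atom_style
#' molecular`: atom type 1 = polymer bead, type 2 = wall bead; molecule id =
#' ring index (0 for wall); FENE bonds as bond type 1.
#'
#' @param polymer A `polymer_system`.
#' @param pore A [build_pore_system()] object (or `NULL` for no wall).
#' @param path Output file.
#' @param x_pad Padding of the open x extents around the contents.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(polymer, pore, path, x_pad = 50) {
  co <- polymer$coords
  topo <- polymer$topology
  wall <- if (is.null(pore)) matrix(numeric(0), ncol = 3) else pore$wall
  nat <- nrow(co) + nrow(wall)
  box_y <- if (is.null(pore)) c(-50, 50) else c(-pore$box[1] / 2, pore$box[1] / 2)
  box_z <- if (is.null(pore)) c(-50, 50) else c(-pore$box[2] / 2, pore$box[2] / 2)
  xs <- c(co[, 1], wall[, 1])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("LAMMPS data file: bead-spring polymer + frozen FCC pore wall",
               "",
               sprintf("%d atoms", nat),
               sprintf("%d bonds", nrow(topo$bonds)),
               "2 atom types", "1 bond types", "",
               sprintf("%.6f %.6f xlo xhi", min(xs) - x_pad, max(xs) + x_pad),
               sprintf("%.6f %.6f ylo yhi", box_y[1], box_y[2]),
               sprintf("%.6f %.6f zlo zhi", box_z[1], box_z[2]),
               "", "Atoms # molecular", ""), con)
  id <- seq_len(nrow(co))
  writeLines(sprintf("%d %d 1 %.6f %.6f %.6f", id, topo$ring_of_bead,
                     co[, 1], co[, 2], co[, 3]), con)
  if (nrow(wall))
    writeLines(sprintf("%d 0 2 %.6f %.6f %.6f", nrow(co) + seq_len(nrow(wall)),
                       wall[, 1], wall[, 2], wall[, 3]), con)
  writeLines(c("", "Bonds", ""), con)
  writeLines(sprintf("%d 1 %d %d", seq_len(nrow(topo$bonds)),
                     topo$bonds[, 1], topo$bonds[, 2]), con)
  invisible(path)
}

#' Write a trajectory as a LAMMPS-style dump file
#'
#' Text dump with `ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS / ATOMS id
#' mol x y z` sections per frame; timesteps are frame times divided by the
#' integration step.
#'
#' @param traj A `polymer_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lammps_dump <- function(traj, path) {
  dt <- traj$params$dt
  ring <- traj$topology$ring_of_bead
  n <- traj$topology$n_beads
  box <- if (!is.null(traj$pore$box)) traj$pore$box else c(100, 100)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$times)) {
    xyz <- traj$coords[f, , ]
    writeLines(c("ITEM: TIMESTEP",
                 sprintf("%d", round(traj$times[f] / dt)),
                 "ITEM: NUMBER OF ATOMS", sprintf("%d", n),
                 "ITEM: BOX BOUNDS ff pp pp",
                 "-1e6 1e6",
                 sprintf("%.6f %.6f", -box[1] / 2, box[1] / 2),
                 sprintf("%.6f %.6f", -box[2] / 2, box[2] / 2),
                 "ITEM: ATOMS id mol x y z"), con)
    writeLines(sprintf("%d %d %.6f %.6f %.6f", seq_len(n), ring,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a LAMMPS-style dump file written by [write_lammps_dump()]
#'
#' @param path Dump file.
#' @param dt Time step used to convert timesteps back to \eqn{\tau}.
#' @return List with `times`, `coords` `[frames, atoms, 3]`, `mol` (molecule
#'   ids of the first frame).
#' @export
read_lammps_dump <- function(path, dt = 0.0025) {
  lines <- readLines(path)
  ts_idx <- which(lines == "ITEM: TIMESTEP")
  stopifnot(length(ts_idx) >= 1)
  times <- as.numeric(lines[ts_idx + 1L]) * dt
  n <- as.integer(lines[ts_idx[1] + 3L])
  coords <- array(0, dim = c(length(ts_idx), n, 3))
  mol <- NULL
  for (f in seq_along(ts_idx)) {
    at0 <- ts_idx[f] + 9L  # first atom row
    rows <- strsplit(trimws(lines[at0 + seq_len(n) - 1L]), "\\s+")
    m <- t(vapply(rows, function(r) as.numeric(r), numeric(5)))
    m <- m[order(m[, 1]), , drop = FALSE]
    if (f == 1) mol <- as.integer(m[, 2])
    coords[f, , ] <- m[, 3:5]
  }
  list(times = times, coords = coords, mol = mol)
}
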