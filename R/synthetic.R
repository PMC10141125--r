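#' Prescribe a crossing schedule for a synthetic trajectory
#'
#' Builds an internally consistent per-bead piecewise-linear axial schedule
#' from high-level prescriptions: a first-crossing time for every bead,
#' optional recrossing episodes, and a constant drift speed.  Bead `i`
#' follows \eqn{x_i(t) = v (t - \tau_i)} (so it crosses the entrance plane
#' \eqn{x_p = 0} exactly at \eqn{\tau_i}), plus, during a recrossing episode
#' `(bead, t0, t1, amplitude)`, a triangular dip of the given amplitude
#' centred on the episode that temporarily pulls the bead back below the
#' plane.
#'
#' @param first_crossings Numeric vector of prescribed first-crossing times
#'   \eqn{\tau_i}, one per bead (must be positive so every bead starts cis).
#' @param speed Drift speed in \eqn{\sigma/\tau}.
#' @param recross Optional data frame with columns `bead`, `t0`, `t1`,
#'   `amplitude` describing recrossing episodes; episodes must start after
#'   the bead's first crossing.
#' @param ring_of_bead Optional ring membership (defaults to a single ring).
#' @return Object of class `crossing_schedule`.
#' @export
crossing_schedule <- function(first_crossings, speed = 0.1, recross = NULL,
                              ring_of_bead = NULL) {
  stopifnot(all(first_crossings > 0), speed > 0)
  n <- length(first_crossings)
  if (is.null(ring_of_bead)) ring_of_bead <- rep(1L, n)
  stopifnot(length(ring_of_bead) == n)
  if (!is.null(recross)) {
    stopifnot(all(c("bead", "t0", "t1", "amplitude") %in% names(recross)))
    bad <- which(recross$t0 <= first_crossings[recross$bead] |
                   recross$t1 <= recross$t0)
    if (length(bad))
      stop(sprintf("inconsistent recrossing episode(s): %s",
                   paste(bad, collapse = ", ")))
  }
  structure(list(first_crossings = first_crossings, speed = speed,
                 recross = recross, ring_of_bead = ring_of_bead, n = n),
            class = "crossing_schedule")
}

# axial position of bead i at times tt under a schedule
.schedule_x <- function(schedule, i, tt) {
  x <- schedule$speed * (tt - schedule$first_crossings[i])
  rc <- schedule$recross
  if (!is.null(rc)) {
    for (k in which(rc$bead == i)) {
      t0 <- rc$t0[k]; t1 <- rc$t1[k]; a <- rc$amplitude[k]
      mid <- (t0 + t1) / 2
      tri <- pmax(0, 1 - abs(tt - mid) / ((t1 - t0) / 2))
      x <- x - a * tri
    }
  }
  x
}

#' Realise a crossing schedule as a trajectory
#'
#' Samples the schedule's piecewise-linear axial paths at a uniform frame
#' interval and assembles a `polymer_trajectory`, optionally adding
#' Ornstein-Uhlenbeck positional noise to the transverse (y, z) coordinates
#' (the axial paths stay exact so that the prescribed crossing structure is
#' realised to machine precision).  Ground-truth annotations (the exact
#' first-crossing times and, when a pore is supplied, the exact multi-ring
#' co-occupancy intervals implied by the continuous paths) are attached as
#' `truth`.
#'
#' Keep episode endpoints and crossing times on the frame grid if analysis
#' results are to be recovered exactly: the analysers interpolate linearly
#' between frames, which is exact for piecewise-linear paths with
#' breakpoints on the grid.
#'
#' @param schedule A [crossing_schedule()].
#' @param pore A [build_pore_system()] object (geometry for the trajectory
#'   metadata and ground-truth events).
#' @param t_end Final frame time (default: past the last event).
#' @param frame_dt Frame interval in \eqn{\tau}.
#' @param noise OU noise amplitude (stationary s.d.) in \eqn{\sigma} applied
#'   to y and z.
#' @param noise_tau OU correlation time in \eqn{\tau}.
#' @param seed Integer seed for the noise.
#' @return A `polymer_trajectory` with `status = "synthetic"` and a `truth`
#'   list (`tau_i`, `events`).
#' @export
make_trajectory <- function(schedule, pore, t_end = NULL, frame_dt = 0.5,
                            noise = 0, noise_tau = 1, seed = 1) {
  n <- schedule$n
  if (is.null(t_end)) {
    t_last <- max(schedule$first_crossings,
                  if (!is.null(schedule$recross)) schedule$recross$t1 else 0)
    # run until the slowest bead is well past the pore exit
    t_end <- t_last + (pore$pore_length + 2) / schedule$speed
  }
  tt <- seq(0, t_end, by = frame_dt)
  nf <- length(tt)
  coords <- array(0, dim = c(nf, n, 3))
  for (i in seq_len(n)) coords[, i, 1] <- .schedule_x(schedule, i, tt)
  if (noise > 0) {
    a <- exp(-frame_dt / noise_tau)
    b <- noise * sqrt(1 - a^2)
    .with_seed(seed, {
      for (i in seq_len(n)) {
        for (d in 2:3) {
          z <- numeric(nf)
          z[1] <- rnorm(1, sd = noise)
          for (f in 2:nf) z[f] <- a * z[f - 1] + b * rnorm(1)
          coords[, i, d] <- z
        }
      }
    })
  }
  topo <- structure(list(n_beads = n,
                         bonds = matrix(integer(0), ncol = 2),
                         ring_of_bead = schedule$ring_of_bead,
                         n_rings = length(unique(schedule$ring_of_bead)),
                         beads_per_ring = NA_integer_,
                         catenation = matrix(integer(0), ncol = 2)),
                    class = "polymer_topology")
  truth <- list(tau_i = schedule$first_crossings,
                events = .schedule_events(schedule, pore, t_end))
  trajectory(times = tt, coords = coords, topology = topo, pore = pore,
             seed = seed, status = "synthetic", truth = truth)
}

# exact multi-ring pore co-occupancy intervals of the continuous schedule,
# computed on a fine grid of the schedule breakpoints
.schedule_events <- function(schedule, pore, t_end, res = 1e-3) {
  if (length(unique(schedule$ring_of_bead)) < 2) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0)))
  }
  # breakpoints: crossing times of the pore boundaries for each bead segment
  # (linear pieces); a dense grid at resolution `res` is a simple exact-enough
  # oracle for fixtures with events far longer than `res`
  tt <- seq(0, t_end, by = res)
  inp <- vapply(seq_len(schedule$n), function(i) {
    x <- .schedule_x(schedule, i, tt)
    x >= pore$x_p & x <= pore$x_p + pore$pore_length
  }, logical(length(tt)))
  multi <- vapply(seq_along(tt), function(f) {
    length(unique(schedule$ring_of_bead[inp[f, ]])) >= 2
  }, logical(1))
  .runs_to_intervals(multi, tt)
}

#' Coplanar bead fixtures at prescribed tilt angles
#'
#' Generates frames whose in-pore beads lie (up to optional Gaussian noise)
#' on planes tilted by prescribed angles: frame `k`'s plane normal makes the
#' angle `theta_sequence[k]` (degrees) with \eqn{\hat z}, with the plane
#' containing the pore axis direction.  Used to validate the SVD plane-fit
#' orientation estimator and the entropy summary.
#'
#' @param theta_sequence Angles in degrees, in [0, 90].
#' @param n_beads Beads per frame (all inside the pore).
#' @param noise Gaussian positional noise s.d. in \eqn{\sigma}.
#' @param pore A [build_pore_system()] object.
#' @param radius In-plane disc radius of the bead cloud.
#' @param seed Integer seed.
#' @return Array `[frames, beads, 3]` of coordinates.
#' @export
make_orientation_fixture <- function(theta_sequence, n_beads = 12, noise = 0,
                                     pore = NULL, radius = 1, seed = 1) {
  stopifnot(all(theta_sequence >= 0 & theta_sequence <= 90), n_beads >= 3)
  if (is.null(pore))
    pore <- list(x_p = 0, pore_length = 4)
  centre <- c(pore$x_p + pore$pore_length / 2, 0, 0)
  nf <- length(theta_sequence)
  coords <- array(0, dim = c(nf, n_beads, 3))
  ang <- 2 * pi * (seq_len(n_beads) - 1) / n_beads
  rr <- radius * sqrt(seq_len(n_beads) / n_beads)  # spread over the disc
  .with_seed(seed, {
    for (f in seq_len(nf)) {
      th <- theta_sequence[f] * pi / 180
      # normal n = (0, sin th, cos th); in-plane basis: x-axis and
      # u = (0, cos th, -sin th)
      u <- c(0, cos(th), -sin(th))
      pts <- outer(rr * cos(ang), c(1, 0, 0)) + outer(rr * sin(ang), u)
      pts <- sweep(pts, 2, centre, "+")
      if (noise > 0)
        pts <- pts + matrix(rnorm(3 * n_beads, sd = noise), ncol = 3)
      coords[f, , ] <- pts
    }
  })
  coords
}
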