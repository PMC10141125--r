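#' Draw Maxwell-Boltzmann initial velocities
#'
#' @param n Number of beads.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return An `n x 3` matrix of velocities in \eqn{\sigma/\tau}.
#' @export
init_velocities <- function(n, params = sim_params(), seed = 1) {
  .with_seed(seed,
             matrix(rnorm(3 * n, sd = sqrt(params$kT / params$mass)), ncol = 3))
}

#' Deterministic force field evaluation
#'
#' Evaluates the conservative forces (FENE bonds, WCA pair repulsion among
#' polymer beads and against the frozen wall, and optionally the in-pore
#' driving force) on a configuration, without friction or noise.  Useful for
#' checks such as Newton's-third-law momentum balance.
#'
#' @param coords N x 3 bead coordinates.
#' @param topology A `polymer_topology` (its `bonds` are used).
#' @param pore Optional [build_pore_system()] object; `NULL` means no wall and
#'   no periodic boundaries.
#' @param params A [sim_params()] object.
#' @param drive Apply the driving force `f_ext` along +x to in-pore beads?
#' @return N x 3 matrix of forces in \eqn{\epsilon\sigma^{-1}}.
#' @export
polymer_forces <- function(coords, topology, pore = NULL,
                           params = sim_params(), drive = FALSE) {
  wall <- if (is.null(pore)) matrix(numeric(0), ncol = 3) else pore$wall
  .forces_cpp(as.matrix(coords), topology$bonds, wall,
              .engine_params(params, pore), drive)
}

# low-level engine call; returns the raw C++ result with frames reshaped
.run_engine <- function(coords, velocities, topology, pore, params, nsteps,
                        sample_every, fixed_bead = 0L, drive = TRUE,
                        stop_on_exit = TRUE, t0 = 0, seed = 1) {
  wall <- if (is.null(pore)) matrix(numeric(0), ncol = 3) else pore$wall
  res <- .run_langevin_cpp(as.matrix(coords), as.matrix(velocities),
                           topology$bonds, wall,
                           .engine_params(params, pore),
                           as.integer(nsteps), as.integer(sample_every),
                           as.integer(fixed_bead), drive, stop_on_exit,
                           t0, seed)
  n <- nrow(as.matrix(coords))
  nf <- length(res$times)
  # frames stored bead-major per frame: (x1,y1,z1,x2,...) -> array [F, N, 3]
  res$frames <- aperm(array(res$frames, dim = c(3, n, nf)), c(3, 2, 1))
  res
}

#' Equilibrate a polymer at the pore entrance
#'
#' Holds one bead fixed at the pore entrance and integrates the undriven
#' Langevin dynamics until the radius-of-gyration series is stationary.
#' Stationarity is declared when a Mann-Kendall trend test (Kendall rank
#' correlation of Rg against time) is non-significant at level `alpha` over
#' the most recent `window_tau` of the run.  Because Rg decorrelates over
#' tens of \eqn{\tau}, the tested series is thinned to one sample per
#' `thin_tau` so the trend test is not fooled by short-range autocorrelation.
#' The test is applied at checkpoints every `check_every` tau; the driving
#' force is off throughout.
#'
#' @param polymer A `polymer_system` from [build_polycatenane()].
#' @param pore A [build_pore_system()] object.
#' @param params A [sim_params()] object.
#' @param fixed_bead Index of the bead held immobile (default 1, the bead
#'   placed at the pore entrance by the builders).
#' @param seed Integer seed (velocities and thermostat noise).
#' @param max_tau Maximum equilibration time in \eqn{\tau}.
#' @param check_every Checkpoint interval in \eqn{\tau}.
#' @param sample_tau Rg sampling interval in \eqn{\tau}.
#' @param window_tau Span of the most recent Rg samples entering the trend
#'   test, in \eqn{\tau}.
#' @param thin_tau Spacing of the thinned samples entering the test.
#' @param alpha Significance level of the trend test.
#' @param min_checks Checkpoints to run before the first test is allowed.
#' @param on_fail `"error"` (default) or `"warn"` when `max_tau` is reached
#'   without passing; the Rg series is attached to the condition either way.
#' @return List with `coords`, `velocities` (state at the end), `rg` (data
#'   frame `time`, `rg`), `converged`, and `tau` (equilibration time used).
#' @export
equilibrate <- function(polymer, pore, params = sim_params(), fixed_bead = 1L,
                        seed = 1, max_tau = 3000, check_every = 250,
                        sample_tau = 2, window_tau = 600, thin_tau = 20,
                        alpha = 0.05, min_checks = 3,
                        on_fail = c("error", "warn")) {
  on_fail <- match.arg(on_fail)
  topo <- polymer$topology
  coords <- minimize_energy(polymer$coords, topo, pore, params,
                            fixed_bead = fixed_bead)
  vel <- init_velocities(topo$n_beads, params, seed)
  vel[fixed_bead, ] <- 0
  steps_chunk <- round(check_every / params$dt)
  sample_every <- max(1L, round(sample_tau / params$dt))
  n_chunks <- ceiling(max_tau / check_every)
  rg_t <- rg_v <- numeric(0)
  converged <- FALSE
  t_now <- 0
  for (chunk in seq_len(n_chunks)) {
    res <- .run_engine(coords, vel, topo, pore, params, steps_chunk,
                       sample_every, fixed_bead = fixed_bead, drive = FALSE,
                       stop_on_exit = FALSE, t0 = t_now,
                       seed = seed + 7919 * chunk)
    if (res$status == 2)
      stop("FENE bond overstretched during equilibration")
    coords <- res$positions
    vel <- res$velocities
    rg_new <- apply(res$frames, 1, .rg)
    # later chunks re-record their initial frame (= previous end): drop it
    keep <- if (chunk == 1) seq_along(res$times) else -1L
    rg_t <- c(rg_t, res$times[keep])
    rg_v <- c(rg_v, rg_new[keep])
    t_now <- t_now + check_every
    if (chunk >= min_checks && t_now >= window_tau) {
      sel <- rg_t >= t_now - window_tau
      thin <- max(1L, round(thin_tau / sample_tau))
      w <- rg_v[sel][seq(1, sum(sel), by = thin)]
      p <- suppressWarnings(
        cor.test(seq_along(w), w, method = "kendall", exact = FALSE)$p.value)
      if (is.finite(p) && p > alpha) {
        converged <- TRUE
        break
      }
    }
  }
  rg <- data.frame(time = rg_t, rg = rg_v)
  if (!converged) {
    msg <- sprintf("equilibration did not reach stationarity within %g tau", max_tau)
    cond <- structure(class = c("porelink_equilibration_failure",
                                if (on_fail == "error") "error" else "warning",
                                "condition"),
                      list(message = msg, call = sys.call(), rg = rg))
    if (on_fail == "error") stop(cond) else warning(cond)
  }
  list(coords = coords, velocities = vel, rg = rg, converged = converged,
       tau = t_now)
}

#' Relax a configuration by capped steepest descent
#'
#' Removes residual overlaps of a freshly built configuration (e.g. between
#' the polymer and the pore wall) before thermal dynamics, by moving each
#' bead along its conservative force with a per-bead displacement cap.  A
#' standard energy-minimisation preamble; it does not sample any ensemble.
#'
#' @param coords N x 3 coordinates.
#' @param topology A `polymer_topology`.
#' @param pore A [build_pore_system()] object or `NULL`.
#' @param params A [sim_params()] object.
#' @param fixed_bead Bead index held immobile (0 for none).
#' @param max_disp Per-bead displacement cap per iteration in \eqn{\sigma}.
#' @param lr Displacement per unit force in \eqn{\sigma^2/\epsilon}.
#' @param iters Maximum iterations.
#' @param f_tol Stop once the largest per-bead force magnitude drops below
#'   this value (\eqn{\epsilon\sigma^{-1}}).
#' @return Relaxed N x 3 coordinate matrix.
#' @export
minimize_energy <- function(coords, topology, pore = NULL,
                            params = sim_params(), fixed_bead = 0L,
                            max_disp = 0.05, lr = 1e-4, iters = 500,
                            f_tol = 20) {
  coords <- as.matrix(coords)
  for (it in seq_len(iters)) {
    f <- polymer_forces(coords, topology, pore, params, drive = FALSE)
    if (fixed_bead > 0) f[fixed_bead, ] <- 0
    fmag <- sqrt(rowSums(f^2))
    if (max(fmag) < f_tol) break
    step <- pmin(fmag * lr, max_disp) / pmax(fmag, 1e-12)
    coords <- coords + f * step
  }
  coords
}

# radius of gyration of one frame (N x 3)
.rg <- function(xyz) {
  c0 <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, c0)^2)))
}

#' Run a driven translocation simulation
#'
#' Integrates the driven Langevin dynamics from an (equilibrated) initial
#' state until every bead's axial coordinate has passed the pore exit plane,
#' or until `max_tau` is reached (in which case the trajectory is flagged
#' incomplete).  The driving force `f_ext` acts along +x on every bead inside
#' the pore.
#'
#' @param coords,velocities Initial state (N x 3 each); typically from
#'   [equilibrate()].
#' @param topology A `polymer_topology`.
#' @param pore A [build_pore_system()] object.
#' @param params A [sim_params()] object.
#' @param seed Integer seed for the thermostat noise.
#' @param max_tau Step cap in \eqn{\tau}.
#' @param sample_tau Frame sampling interval in \eqn{\tau} (default 0.5, fine
#'   enough to resolve single-bead crossings).
#' @return A `polymer_trajectory` object; see [trajectory()].
#' @export
run_translocation <- function(coords, velocities, topology, pore,
                              params = sim_params(), seed = 1,
                              max_tau = 12000, sample_tau = 0.5) {
  nsteps <- round(max_tau / params$dt)
  sample_every <- max(1L, round(sample_tau / params$dt))
  res <- .run_engine(coords, velocities, topology, pore, params, nsteps,
                     sample_every, fixed_bead = 0L, drive = TRUE,
                     stop_on_exit = TRUE, t0 = 0, seed = seed)
  if (res$status == 2)
    stop(sprintf("FENE bond %d overstretched during production (replica aborted)",
                 res$bad_bond))
  trajectory(times = res$times, coords = res$frames, topology = topology,
             pore = pore, params = params, seed = seed,
             status = if (res$status == 1) "completed" else "incomplete",
             tkin = res$tkin)
}

#' Trajectory container
#'
#' Time-ordered frames of bead positions with the metadata needed by the
#' analysis stages.  Frame times are strictly increasing with constant
#' spacing.
#'
#' @param times Frame times in \eqn{\tau}.
#' @param coords Array `[frames, beads, 3]` of positions.
#' @param topology A `polymer_topology`.
#' @param pore The pore the trajectory was generated in (geometry metadata).
#' @param params A [sim_params()] object.
#' @param seed Replica seed.
#' @param status `"completed"`, `"incomplete"`, or `"synthetic"`.
#' @param tkin Optional per-frame kinetic temperature series.
#' @param truth Optional ground-truth annotations (synthetic trajectories).
#' @return An object of class `polymer_trajectory`.
#' @export
trajectory <- function(times, coords, topology, pore, params = sim_params(),
                       seed = NA_integer_, status = "completed", tkin = NULL,
                       truth = NULL) {
  stopifnot(length(times) == dim(coords)[1],
            dim(coords)[2] == topology$n_beads, dim(coords)[3] == 3)
  if (length(times) > 1) {
    dtimes <- diff(times)
    stopifnot(all(dtimes > 0))
    if (max(abs(dtimes - dtimes[1])) > 1e-6 * dtimes[1])
      warning("frame spacing is not constant")
  }
  structure(list(times = times, coords = coords, topology = topology,
                 pore = pore, params = params, seed = seed, status = status,
                 tkin = tkin, truth = truth),
            class = "polymer_trajectory")
}

#' @export
print.polymer_trajectory <- function(x, ...) {
  cat(sprintf("polymer trajectory: %d frames x %d beads, t = [%g, %g] tau (%s)\n",
              length(x$times), x$topology$n_beads, min(x$times), max(x$times),
              x$status))
  invisible(x)
}

#' Axial (translocation-axis) coordinates of a trajectory
#'
#' @param traj A `polymer_trajectory`.
#' @return Matrix `[frames, beads]` of x coordinates.
#' @export
axial_coords <- function(traj) {
  matrix(traj$coords[, , 1], nrow = dim(traj$coords)[1])
}

#' Per-frame kinetic temperature of a run
#'
#' Instantaneous kinetic temperature \eqn{m\langle v^2\rangle/3} recorded at
#' each sampled frame of an engine run, in units of \eqn{\epsilon/k_B}.
#'
#' @param traj A `polymer_trajectory` produced by [run_translocation()] (or
#'   any trajectory carrying a `tkin` series).
#' @return Numeric vector, or `NULL` when not recorded.
#' @export
kinetic_temperature <- function(traj) traj$tkin
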