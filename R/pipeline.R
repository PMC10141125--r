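#' Configuration of a pore-radius replica sweep
#'
#' @param radii Carving radii in \eqn{\sigma}.  Default: the study grid
#'   1.1-2.0 in steps of 0.1 plus 2.5.
#' @param polymer `"catenane"` (4 rings x 40 beads) or `"ring"` (160 beads).
#' @param replicas Seeded replicas per radius.  The headline ensembles use
#'   140; the desk default is 10.
#' @param params A [sim_params()] object (driving force, thermostat, ...).
#' @param seed_base Base seed; each replica's seed is derived from it
#'   deterministically, so a sweep is exactly reproducible.
#' @param equil Named list of overrides for [equilibrate()].
#' @param run Named list of overrides for [run_translocation()].
#' @param debounce Knot-event merge window in \eqn{\tau}.
#' @param keep_trajectories Retain full trajectories in the result (memory
#'   heavy; default drops them after analysis).
#' @return Object of class `sweep_config`.
#' @export
sweep_config <- function(radii = c(seq(1.1, 2.0, by = 0.1), 2.5),
                         polymer = c("catenane", "ring"), replicas = 10,
                         params = sim_params(), seed_base = 1,
                         equil = list(), run = list(), debounce = 2,
                         keep_trajectories = FALSE) {
  polymer <- match.arg(polymer)
  structure(list(radii = radii, polymer = polymer, replicas = replicas,
                 params = params, seed_base = seed_base, equil = equil,
                 run = run, debounce = debounce,
                 keep_trajectories = keep_trajectories),
            class = "sweep_config")
}

# deterministic replica seed below 2^31 (numeric arithmetic: no int overflow)
.replica_seed <- function(seed_base, radius_idx, replica) {
  (as.numeric(seed_base) * 100003 + radius_idx * 10007 + replica * 101) %%
    2147483647
}

#' Build, equilibrate, drive and analyse one replica
#'
#' Runs the full per-replica pipeline: construct the polymer with a seeded
#' jitter, equilibrate it at the pore entrance (one bead fixed, drive off),
#' release the bead and drive the chain through the pore, then compute both
#' translocation profiles, the knot-passage events, insertion orientations
#' and pore-occupancy statistics.
#'
#' @param pore A [build_pore_system()] object.
#' @param polymer `"catenane"` or `"ring"`.
#' @param params A [sim_params()] object.
#' @param seed Integer replica seed (controls jitter, velocities, noise).
#' @param equil,run Named lists of overrides for [equilibrate()] and
#'   [run_translocation()].
#' @param debounce Knot-event merge window in \eqn{\tau}.
#' @param keep_trajectory Retain the trajectory in the result.
#' @return List with `status` (`"completed"`, `"incomplete"`, or `"failed"`),
#'   `total_time`, `profiles`, `events`, `orientation`, `occupancy`,
#'   `rg` (equilibration series), `seed`, and optionally `trajectory`.
#' @export
run_replica <- function(pore, polymer = c("catenane", "ring"),
                        params = sim_params(), seed = 1, equil = list(),
                        run = list(), debounce = 2, keep_trajectory = FALSE) {
  polymer <- match.arg(polymer)
  poly <- if (polymer == "catenane")
    build_polycatenane(4, 40, box = pore$box, seed = seed)
  else
    build_ring_polymer(160, box = pore$box, seed = seed)

  eq <- tryCatch(
    do.call(equilibrate, c(list(polymer = poly, pore = pore, params = params,
                                seed = seed + 1L, on_fail = "error"), equil)),
    error = function(e) e)
  if (inherits(eq, "error"))
    return(list(status = "failed", stage = "equilibration",
                message = conditionMessage(eq), seed = seed,
                rg = eq$rg))

  traj <- tryCatch(
    do.call(run_translocation,
            c(list(coords = eq$coords, velocities = eq$velocities,
                   topology = poly$topology, pore = pore, params = params,
                   seed = seed + 2L), run)),
    error = function(e) e)
  if (inherits(traj, "error"))
    return(list(status = "failed", stage = "production",
                message = conditionMessage(traj), seed = seed, rg = eq$rg))

  if (traj$status != "completed")
    return(list(status = "incomplete", seed = seed, rg = eq$rg,
                trajectory = if (keep_trajectory) traj else NULL))

  profs <- translocation_profiles(traj)
  events <- detect_knot_events(traj, debounce = debounce)
  orient <- insertion_orientation(traj, events)
  occ <- pore_occupancy_stats(traj, events)
  list(status = "completed", total_time = profs$total_time,
       profiles = profs, events = events, orientation = orient,
       occupancy = occ[c("mean_overall", "mean_knot", "mean_noknot")],
       rg = eq$rg, seed = seed,
       trajectory = if (keep_trajectory) traj else NULL)
}

#' Run a pore-radius sweep of seeded replicas
#'
#' Loops over the configured radii and replicas, building the pore once per
#' radius and running [run_replica()] with deterministic per-replica seeds.
#' Per-replica failures are logged and excluded from the aggregates; a
#' condition with fewer than half its replicas completed is flagged.
#'
#' @param config A [sweep_config()].
#' @param verbose Print one progress line per replica.
#' @return Object of class `sweep_result`: list with `summary` (one row per
#'   radius: completion counts, mean total translocation time with 95% CI,
#'   mean knot-passage duration and fraction, pore occupancy means, and the
#'   Shannon entropy of the pooled insertion angles), `replicas` (nested
#'   per-radius lists of [run_replica()] results) and `config`.
#' @export
run_sweep <- function(config, verbose = FALSE) {
  rows <- NULL
  all_reps <- list()
  for (ri in seq_along(config$radii)) {
    r <- config$radii[ri]
    pore <- build_pore_system(r)
    reps <- vector("list", config$replicas)
    for (k in seq_len(config$replicas)) {
      seed <- .replica_seed(config$seed_base, ri, k)
      reps[[k]] <- run_replica(pore, config$polymer, config$params,
                               seed = seed, equil = config$equil,
                               run = config$run, debounce = config$debounce,
                               keep_trajectory = config$keep_trajectories)
      if (verbose)
        cat(sprintf("r=%.2f replica %d/%d: %s\n", r, k, config$replicas,
                    reps[[k]]$status))
    }
    all_reps[[as.character(r)]] <- reps
    rows <- rbind(rows, .condition_summary(r, config$polymer, reps))
  }
  structure(list(summary = rows, replicas = all_reps, config = config),
            class = "sweep_result")
}

# aggregate one radius' replicas into a summary row; replicas are the
# independent unit (CIs from per-replica values, never pooled frames)
.condition_summary <- function(r, polymer, reps) {
  done <- Filter(function(x) identical(x$status, "completed"), reps)
  n <- length(done)
  tot <- vapply(done, `[[`, numeric(1), "total_time")
  dtau_rep <- vapply(done, function(x)
    if (nrow(x$events)) mean(x$events$dtau) else NA_real_, numeric(1))
  dx_rep <- vapply(done, function(x)
    if (nrow(x$events)) mean(x$events$dx) else NA_real_, numeric(1))
  beads_all <- vapply(done, function(x) x$occupancy$mean_overall, numeric(1))
  beads_knot <- vapply(done, function(x) x$occupancy$mean_knot, numeric(1))
  beads_nok <- vapply(done, function(x) x$occupancy$mean_noknot, numeric(1))
  thetas <- unlist(lapply(done, function(x) x$orientation$theta))
  ci_tot <- .mean_ci(tot)
  ci_dtau <- .mean_ci(dtau_rep[!is.na(dtau_rep)])
  data.frame(radius = r, polymer = polymer, n_attempted = length(reps),
             n_completed = n,
             flagged = n < length(reps) / 2,
             mean_total = ci_tot[1], total_lo = ci_tot[2], total_hi = ci_tot[3],
             mean_dtau = ci_dtau[1], dtau_lo = ci_dtau[2], dtau_hi = ci_dtau[3],
             mean_dx = mean(dx_rep, na.rm = TRUE),
             mean_beads = mean(beads_all),
             mean_beads_knot = mean(beads_knot, na.rm = TRUE),
             mean_beads_noknot = mean(beads_nok, na.rm = TRUE),
             entropy_S = if (length(thetas) >= 1) shannon_entropy(thetas)$S
                         else NA_real_,
             n_theta = length(thetas))
}

# mean and 95% CI from independent replicate values; t quantiles below 30
# replicates, normal beyond
.mean_ci <- function(v, level = 0.95) {
  n <- length(v)
  if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
  m <- mean(v)
  if (n == 1) return(c(m, NA_real_, NA_real_))
  se <- sd(v) / sqrt(n)
  q <- if (n < 30) qt(1 - (1 - level) / 2, df = n - 1)
       else qnorm(1 - (1 - level) / 2)
  c(m, m - q * se, m + q * se)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep: %s, %d radii x %d replicas (seed base %d)\n",
              x$config$polymer, length(x$config$radii), x$config$replicas,
              x$config$seed_base))
  print(x$summary[, c("radius", "n_completed", "n_attempted", "mean_total",
                      "mean_dtau", "mean_beads", "entropy_S")], row.names = FALSE)
  invisible(x)
}

#' Average translocation profile across replicas
#'
#' Mean time at each translocation fraction \eqn{k/N} across completed
#' replicas, with a 95% confidence interval from the per-replica values (t
#' quantiles below 30 replicas).  The per-bead fraction grid makes replica
#' profiles directly commensurable, so averaging is at fixed fraction.
#'
#' @param profiles List of `translocation_profile`s (same fraction grid).
#' @return Data frame with `x`, `tau_mean`, `tau_lo`, `tau_hi`,
#'   `n_replicas`.  With a single profile the CI columns are `NA` and the
#'   result carries attribute `flagged = TRUE`.
#' @export
average_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  xg <- profiles[[1]]$x
  taus <- vapply(profiles, function(p) {
    stopifnot(identical(p$x, xg))
    p$tau
  }, numeric(length(xg)))
  taus <- matrix(taus, nrow = length(xg))
  ci <- t(apply(taus, 1, .mean_ci))
  out <- data.frame(x = xg, tau_mean = ci[, 1], tau_lo = ci[, 2],
                    tau_hi = ci[, 3], n_replicas = length(profiles))
  attr(out, "flagged") <- length(profiles) < 2
  out
}

#' Translocation-time jump between two pore radii
#'
#' Difference and ratio of the ensemble-mean total translocation times
#' between two radii, and the corresponding difference of the mean
#' knot-passage durations, with error propagated from the per-condition 95%
#' confidence intervals (standard errors added in quadrature).  The jump is
#' reported as `mean(r_low) - mean(r_high)`: a positive value is the
#' slowdown at the smaller pore.
#'
#' @param sweep A `sweep_result` (or its `summary` data frame).
#' @param r_low,r_high The two radii (must both be in the sweep).
#' @return List with `jump_total`, `jump_ci` (95% CI), `ratio`, `jump_dtau`,
#'   `jump_dtau_ci`, and the two condition rows.
#' @export
jump_statistics <- function(sweep, r_low = 1.4, r_high = 1.5) {
  s <- if (inherits(sweep, "sweep_result")) sweep$summary else sweep
  i1 <- which(abs(s$radius - r_low) < 1e-9)
  i2 <- which(abs(s$radius - r_high) < 1e-9)
  if (length(i1) != 1 || length(i2) != 1)
    stop("both radii must be present in the sweep summary")
  se <- function(i, lo, hi, n) {
    if (is.na(s[[lo]][i])) return(NA_real_)
    q <- if (s$n_completed[i] < 30) qt(0.975, df = s$n_completed[i] - 1)
         else qnorm(0.975)
    (s[[hi]][i] - s[[lo]][i]) / (2 * q)
  }
  d_tot <- s$mean_total[i1] - s$mean_total[i2]
  se_tot <- sqrt(se(i1, "total_lo", "total_hi")^2 +
                   se(i2, "total_lo", "total_hi")^2)
  d_dt <- s$mean_dtau[i1] - s$mean_dtau[i2]
  se_dt <- sqrt(se(i1, "dtau_lo", "dtau_hi")^2 +
                  se(i2, "dtau_lo", "dtau_hi")^2)
  list(jump_total = d_tot,
       jump_ci = d_tot + c(-1, 1) * qnorm(0.975) * se_tot,
       ratio = s$mean_total[i1] / s$mean_total[i2],
       jump_dtau = d_dt,
       jump_dtau_ci = d_dt + c(-1, 1) * qnorm(0.975) * se_dt,
       conditions = s[c(i1, i2), ])
}
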