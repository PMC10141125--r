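#' Entrance-plane crossing events of every bead
#'
#' Scans the axial coordinate of each bead for crossings of the pore entrance
#' plane `x_p`, in either direction, with sub-frame timing by linear
#' interpolation between the two bracketing frames (removes
#' sampling-interval bias from waiting times).
#'
#' @param traj A `polymer_trajectory`.
#' @param x_p Entrance-plane axial coordinate (defaults to the trajectory's
#'   pore).
#' @return Data frame with columns `bead`, `time`, `dir` (+1 cis-to-trans,
#'   -1 back), sorted by time.
#' @export
crossing_events <- function(traj, x_p = traj$pore$x_p) {
  x <- axial_coords(traj)
  tt <- traj$times
  above <- x > x_p
  nf <- nrow(x)
  if (nf < 2) return(data.frame(bead = integer(0), time = numeric(0),
                                dir = integer(0)))
  chg <- above[-1, , drop = FALSE] != above[-nf, , drop = FALSE]
  idx <- which(chg, arr.ind = TRUE)
  if (nrow(idx) == 0) return(data.frame(bead = integer(0), time = numeric(0),
                                        dir = integer(0)))
  f <- idx[, 1]; b <- idx[, 2]
  x0 <- x[cbind(f, b)]; x1 <- x[cbind(f + 1, b)]
  frac <- (x_p - x0) / (x1 - x0)
  tc <- tt[f] + frac * (tt[f + 1] - tt[f])
  dir <- ifelse(x1 > x0, 1L, -1L)
  out <- data.frame(bead = b, time = tc, dir = dir)
  out[order(out$time), , drop = FALSE]
}

#' First-passage times of all beads through the pore entrance
#'
#' \eqn{\tau_i} is the earliest time at which bead \eqn{i}'s axial coordinate
#' first exceeds the entrance plane `x_p` (the irreversible-definition clock,
#' insensitive to later recrossings).
#'
#' @param traj A `polymer_trajectory` whose beads start on the cis side.
#' @param x_p Entrance-plane coordinate.
#' @param strict If `TRUE` (default), a bead that never crosses is an error
#'   (inconsistent for a completed replica); otherwise its time is `NA`.
#' @return Numeric vector of length N of first-passage times in \eqn{\tau}.
#' @export
first_passage_times <- function(traj, x_p = traj$pore$x_p, strict = TRUE) {
  n <- traj$topology$n_beads
  ev <- crossing_events(traj, x_p)
  up <- ev[ev$dir > 0, , drop = FALSE]
  tau <- rep(NA_real_, n)
  first <- up[!duplicated(up$bead), , drop = FALSE]
  tau[first$bead] <- first$time
  # a bead already past x_p in frame 1 counts as crossed at the start
  x1 <- axial_coords(traj)[1, ]
  tau[is.na(tau) & x1 > x_p] <- traj$times[1]
  if (strict && anyNA(tau))
    stop(sprintf("%d bead(s) never crossed the entrance plane", sum(is.na(tau))))
  tau
}

#' Irreversible translocation profile from first-passage times
#'
#' The irreversible translocation fraction is
#' \eqn{x^{irrev}(\tau) = N^{-1}\sum_i H(\tau - \tau_i)}, a nondecreasing
#' step function of time.  Reported as the time at each fraction
#' \eqn{k/N}, which is the k-th order statistic of the first-passage times.
#'
#' @param tau_i Per-bead first-passage times (no `NA`s).
#' @param t0 Time assigned to fraction 0 (trajectory start).
#' @return Object of class `translocation_profile`: data frame with columns
#'   `x` (fractions `0:N / N`), `tau` (time at that fraction), and `w`
#'   (waiting time, the forward gap `tau[k+1] - tau[k]`; `NA` in the last
#'   row), with `definition = "irreversible"` as an attribute.
#' @export
irreversible_profile <- function(tau_i, t0 = 0) {
  stopifnot(!anyNA(tau_i))
  n <- length(tau_i)
  tau <- c(t0, sort(tau_i))
  out <- data.frame(x = (0:n) / n, tau = tau, w = c(diff(tau), NA))
  attr(out, "definition") <- "irreversible"
  class(out) <- c("translocation_profile", class(out))
  out
}

#' Reversible translocation profile from the instantaneous bead census
#'
#' The reversible translocation fraction is the instantaneous census
#' \eqn{x^{rev}(\tau) = N^{-1}\sum_i H(x_i(\tau) - x_p)}, which fluctuates as
#' beads recross the entrance plane.  The time reported at fraction
#' \eqn{k/N} is the *last* time the census permanently attains that level
#' (the final upward transition from \eqn{(k-1)/N}); the time at fraction 1
#' is therefore the final entrance crossing, which the package reports as
#' the total translocation time.  It equals the irreversible total exactly
#' when the final crossing is a first passage (the typical driven case).  The
#' waiting time at level \eqn{k/N} is the total dwell time the census spends
#' at that level, so the waiting times partition the total time.
#'
#' The raw fluctuating census is returned in the `census` attribute
#' (data frame `time`, `x`, piecewise constant between crossings).
#'
#' @param traj A `polymer_trajectory`.
#' @param x_p Entrance-plane coordinate.
#' @return A `translocation_profile` (columns `x`, `tau`, `w`) with
#'   `definition = "reversible"` and attribute `census`.
#' @export
reversible_profile <- function(traj, x_p = traj$pore$x_p) {
  n <- traj$topology$n_beads
  ev <- crossing_events(traj, x_p)
  x1 <- axial_coords(traj)[1, ]
  c0 <- sum(x1 > x_p)
  t0 <- traj$times[1]
  tend <- max(traj$times)
  cen <- c0 + c(0, cumsum(ev$dir))
  ctime <- c(t0, ev$time)
  if (cen[length(cen)] != n)
    warning("final census is not the full chain; trajectory may be incomplete")
  # last upward transition to each level k
  tau_level <- rep(NA_real_, n)  # tau_level[k]: last attainment of level k
  for (e in seq_along(ev$time))
    if (ev$dir[e] > 0) tau_level[cen[e + 1]] <- ev$time[e]
  t_complete <- if (all(is.na(tau_level))) t0 else max(tau_level, na.rm = TRUE)
  # dwell time at each census level within [t0, t_complete]: these partition
  # the total translocation time exactly
  dwell <- numeric(n + 1)  # dwell[k+1]: total time census == k
  seg_t <- pmin(c(ctime, tend), t_complete)
  for (s in seq_along(cen)) {
    len <- seg_t[s + 1] - seg_t[s]
    if (len > 0) dwell[cen[s] + 1] <- dwell[cen[s] + 1] + len
  }
  tau <- c(t0, tau_level)
  # levels never attained upward (started above x_p) get the start time
  tau[is.na(tau)] <- t0
  out <- data.frame(x = (0:n) / n, tau = tau, w = dwell)
  attr(out, "definition") <- "reversible"
  attr(out, "census") <- data.frame(time = ctime, x = cen / n)
  class(out) <- c("translocation_profile", class(out))
  out
}

#' Translocation profiles under both definitions
#'
#' Convenience wrapper computing the irreversible and reversible profiles of
#' one trajectory on the shared fraction grid \eqn{k/N}.
#'
#' @param traj A `polymer_trajectory`.
#' @param x_p Entrance-plane coordinate.
#' @return List with elements `irreversible`, `reversible` (each a
#'   `translocation_profile`) and `total_time` (shared total translocation
#'   time, the time at fraction 1 of the reversible profile).
#' @export
translocation_profiles <- function(traj, x_p = traj$pore$x_p) {
  tau_i <- first_passage_times(traj, x_p)
  irrev <- irreversible_profile(tau_i, t0 = traj$times[1])
  rev <- reversible_profile(traj, x_p)
  list(irreversible = irrev, reversible = rev,
       total_time = rev$tau[nrow(rev)])
}

#' Waiting-time series of a translocation profile
#'
#' For the irreversible definition the waiting time at fraction \eqn{k/N} is
#' the gap between consecutive sorted first-passage times; for the
#' reversible definition it is the total dwell time of the census at that
#' level.  Both are computed by the profile constructors; this accessor
#' returns them as a data frame for plotting/smoothing.
#'
#' @param profile A `translocation_profile`.
#' @return Data frame with columns `x` and `w` (waiting time per fraction
#'   bin, trailing `NA` rows dropped).
#' @export
waiting_time <- function(profile) {
  out <- data.frame(x = profile$x, w = profile$w)
  out[!is.na(out$w), , drop = FALSE]
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local-polynomial (Savitzky-Golay) smoothing, as used for
#' presenting waiting-time profiles.  Thin wrapper over
#' [signal::sgolayfilt()]; endpoints are handled by the filter's asymmetric
#' endpoint fits.  Smoothing is a presentation aid: peak-location statistics
#' are computed on unsmoothed series unless a smoothed series is passed
#' explicitly.
#'
#' @param series Numeric vector.
#' @param window Odd window length (default 9 samples).
#' @param order Polynomial order (default 3; must be `< window`).
#' @return Smoothed numeric vector of the same length.
#' @export
sg_smooth <- function(series, window = 9, order = 3) {
  stopifnot(window %% 2 == 1, order < window)
  if (window > length(series))
    stop("smoothing window longer than the series")
  signal::sgolayfilt(series, p = order, n = window)
}
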