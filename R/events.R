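#' Census of beads inside the pore
#'
#' A bead is inside the pore when its axial coordinate lies within
#' \eqn{[x_p, x_p + L]} (pore length `L`).
#'
#' @param frame N x 3 coordinate matrix of one frame.
#' @param pore A [build_pore_system()] object.
#' @return List with `count` and `beads` (indices of in-pore beads).
#' @export
beads_in_pore <- function(frame, pore) {
  idx <- which(in_pore(frame[, 1], pore))
  list(count = length(idx), beads = idx)
}

#' Detect knot (Hopf-link) passage events
#'
#' A knot passage is a maximal time interval during which the set of beads
#' inside the pore spans at least two distinct rings of the polycatenane
#' (the Hopf-link junction transiting the channel).  Intervals separated by
#' gaps shorter than `debounce` tau are merged, since single-bead flicker at
#' the pore mouth otherwise fragments events.  Each event is annotated with
#' its duration and with the translocation fraction (reversible definition,
#' instantaneous census) at its boundaries.
#'
#' A completed poly[4]catenane replica is expected to yield exactly
#' `n_rings - 1` events; a replica whose debounced event count differs is
#' flagged (`attr(ev, "flagged")`).
#'
#' @param traj A `polymer_trajectory`.
#' @param pore A [build_pore_system()] object (defaults to the trajectory's).
#' @param debounce Merge window in \eqn{\tau} (default 2).
#' @return Data frame of class `knot_events` with columns `t_start`, `t_end`,
#'   `dtau`, `x_start`, `x_end`, `dx`, `rings` (comma-separated ring ids).
#'   Attribute `flagged` is `TRUE` when the event count differs from
#'   `n_rings - 1`.
#' @export
detect_knot_events <- function(traj, pore = traj$pore, debounce = 2) {
  topo <- traj$topology
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      dtau = numeric(0), x_start = numeric(0),
                      x_end = numeric(0), dx = numeric(0),
                      rings = character(0))
  if (topo$n_rings < 2) {
    attr(empty, "flagged") <- FALSE
    class(empty) <- c("knot_events", class(empty))
    return(empty)
  }
  x <- axial_coords(traj)
  inp <- in_pore(x, pore)
  nf <- nrow(inp)
  ring <- topo$ring_of_bead
  multi <- logical(nf)
  nring_frame <- integer(nf)
  for (f in seq_len(nf)) {
    r <- unique(ring[inp[f, ]])
    nring_frame[f] <- length(r)
    multi[f] <- length(r) >= 2
  }
  iv <- .runs_to_intervals(multi, traj$times)
  iv <- .merge_intervals(iv, debounce)
  if (nrow(iv) == 0) {
    attr(empty, "flagged") <- TRUE
    class(empty) <- c("knot_events", class(empty))
    return(empty)
  }
  # reversible census fraction at the event boundaries
  frac <- rowMeans(x > pore$x_p)
  fstart <- findInterval(iv$t_start, traj$times)
  fend <- findInterval(iv$t_end, traj$times)
  rings <- vapply(seq_len(nrow(iv)), function(k) {
    fs <- which(traj$times >= iv$t_start[k] & traj$times <= iv$t_end[k])
    paste(sort(unique(ring[as.logical(colSums(inp[fs, , drop = FALSE]))])),
          collapse = ",")
  }, character(1))
  ev <- data.frame(t_start = iv$t_start, t_end = iv$t_end,
                   dtau = iv$t_end - iv$t_start,
                   x_start = frac[fstart], x_end = frac[fend],
                   dx = frac[fend] - frac[fstart], rings = rings)
  attr(ev, "flagged") <- nrow(ev) != (topo$n_rings - 1)
  class(ev) <- c("knot_events", class(ev))
  ev
}

# maximal TRUE runs of a logical vector -> intervals in time
.runs_to_intervals <- function(flag, times) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- which(r$values)
  data.frame(t_start = times[starts[k]], t_end = times[ends[k]])
}

# merge intervals separated by gaps shorter than `gap`
.merge_intervals <- function(iv, gap) {
  if (nrow(iv) <= 1) return(iv)
  out <- iv[1, , drop = FALSE]
  for (k in 2:nrow(iv)) {
    if (iv$t_start[k] - out$t_end[nrow(out)] < gap) {
      out$t_end[nrow(out)] <- iv$t_end[k]
    } else {
      out <- rbind(out, iv[k, , drop = FALSE])
    }
  }
  out
}

#' Orientation of the in-pore bead cloud
#'
#' Fits the best plane (least squares, via singular value decomposition) to
#' the in-pore bead positions of one frame and returns the angle
#' \eqn{\theta} between the plane normal \eqn{\hat n} (the direction of
#' least variance) and the fixed \eqn{\hat z} direction, which is
#' perpendicular to the pore translocation axis x.  \eqn{\theta} is folded
#' into [0, 90] degrees by taking the supplement (a normal and its negation
#' are the same plane); the additional symmetry fold about 45 degrees (for
#' the pore's crystal cross-section symmetry, \eqn{\theta \to 90 - \theta})
#' is returned alongside as `theta_folded`.
#'
#' @param frame N x 3 coordinates of one frame (or an already-subset bead
#'   cloud with `beads = NULL`).
#' @param pore A [build_pore_system()] object.
#' @param beads Optional bead indices to restrict to (e.g. one ring);
#'   in-pore filtering is applied after the restriction.
#' @return List of class `orientation_sample`: `theta` (degrees, [0, 90]),
#'   `theta_folded` ([0, 45]), `normal` (unit vector), `n_pore_beads`.
#'   Returns `NULL` (with a message) when fewer than 3 non-collinear beads
#'   are inside the pore.
#' @export
ring_orientation <- function(frame, pore, beads = NULL) {
  if (!is.null(beads)) frame <- frame[beads, , drop = FALSE]
  idx <- which(in_pore(frame[, 1], pore))
  if (length(idx) < 3) return(NULL)
  pts <- frame[idx, , drop = FALSE]
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr)
  if (sv$d[2] < 1e-10) return(NULL)  # collinear: plane undefined
  n_hat <- sv$v[, 3]
  cosz <- abs(n_hat[3])  # fold by supplement: normal sign is arbitrary
  theta <- acos(pmin(1, cosz)) * 180 / pi
  structure(list(theta = theta,
                 theta_folded = if (theta > 45) 90 - theta else theta,
                 normal = n_hat, n_pore_beads = length(idx)),
            class = "orientation_sample")
}

#' Ring orientation at the moment of knot insertion
#'
#' For each knot-passage event, evaluates the orientation of the ring
#' *already resident* in the pore at the event start: the resident ring is
#' the one with the most in-pore beads at the last frame before the event
#' begins (ties are skipped and logged).  The orientation sample is taken at
#' the event-start frame using only that ring's in-pore beads.
#'
#' @param traj A `polymer_trajectory`.
#' @param events A `knot_events` data frame from [detect_knot_events()].
#' @param pore A [build_pore_system()] object.
#' @return Data frame with one row per usable event: `t_start`, `ring`,
#'   `theta`, `theta_folded`, `n_pore_beads`.  Events without a resolvable
#'   resident ring or with too few beads are dropped (count in attribute
#'   `n_skipped`).
#' @export
insertion_orientation <- function(traj, events, pore = traj$pore) {
  out <- NULL
  skipped <- 0L
  ring <- traj$topology$ring_of_bead
  x <- axial_coords(traj)
  inp <- in_pore(x, pore)
  for (k in seq_len(nrow(events))) {
    fstart <- findInterval(events$t_start[k], traj$times)
    fprev <- max(1L, fstart - 1L)
    resident <- ring[inp[fprev, ]]
    if (length(resident) == 0) { skipped <- skipped + 1L; next }
    tab <- sort(table(resident), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) { skipped <- skipped + 1L; next }
    rid <- as.integer(names(tab)[1])
    os <- ring_orientation(traj$coords[fstart, , ], pore,
                           beads = which(ring == rid))
    if (is.null(os)) { skipped <- skipped + 1L; next }
    out <- rbind(out, data.frame(t_start = events$t_start[k], ring = rid,
                                 theta = os$theta,
                                 theta_folded = os$theta_folded,
                                 n_pore_beads = os$n_pore_beads))
  }
  if (is.null(out))
    out <- data.frame(t_start = numeric(0), ring = integer(0),
                      theta = numeric(0), theta_folded = numeric(0),
                      n_pore_beads = integer(0))
  attr(out, "n_skipped") <- skipped
  out
}

#' Shannon entropy of a binned orientation distribution
#'
#' Bins the angle samples, normalises the bin counts to probabilities
#' \eqn{p_x = \rho_x / \sum_x \rho_x}, and computes
#' \eqn{S = -\sum_x p_x \ln p_x} in nats, with the convention
#' \eqn{0 \ln 0 = 0}.  For a uniform distribution over N occupied bins
#' \eqn{S = \ln N}, the maximum.
#'
#' @param samples Numeric angle samples (degrees).
#' @param bin_edges Histogram bin edges; default 5-degree bins on [0, 90]
#'   (18 bins, so \eqn{\max S = \ln 18}).
#' @return Object of class `entropy_summary`: list with `bin_edges`,
#'   `counts`, `p`, `S` (nats), `S_max` (`log(nbins)`), `n`.
#' @export
shannon_entropy <- function(samples, bin_edges = seq(0, 90, by = 5)) {
  stopifnot(length(samples) >= 1)
  if (any(samples < min(bin_edges) | samples > max(bin_edges)))
    stop("samples outside the bin range")
  counts <- tabulate(findInterval(samples, bin_edges, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = length(bin_edges) - 1)
  p <- counts / sum(counts)
  nz <- p > 0
  S <- -sum(p[nz] * log(p[nz]))
  structure(list(bin_edges = bin_edges, counts = counts, p = p, S = S,
                 S_max = log(length(bin_edges) - 1), n = length(samples)),
            class = "entropy_summary")
}

#' @export
print.entropy_summary <- function(x, ...) {
  cat(sprintf("Shannon entropy S = %.4f nats (max ln %d = %.4f) from %d samples\n",
              x$S, length(x$bin_edges) - 1, x$S_max, x$n))
  invisible(x)
}

#' Beads-in-pore statistics split by knot occupancy
#'
#' Mean number of beads inside the pore over the whole translocation, and
#' separately during and outside knot-passage events.
#'
#' @param traj A `polymer_trajectory`.
#' @param events A `knot_events` data frame.
#' @param pore A [build_pore_system()] object.
#' @return List with `mean_overall`, `mean_knot`, `mean_noknot`, and the
#'   per-frame counts (`counts`, `in_event` flags).
#' @export
pore_occupancy_stats <- function(traj, events, pore = traj$pore) {
  x <- axial_coords(traj)
  counts <- rowSums(in_pore(x, pore))
  in_ev <- rep(FALSE, length(traj$times))
  for (k in seq_len(nrow(events)))
    in_ev <- in_ev | (traj$times >= events$t_start[k] &
                        traj$times <= events$t_end[k])
  list(mean_overall = mean(counts),
       mean_knot = if (any(in_ev)) mean(counts[in_ev]) else NA_real_,
       mean_noknot = if (any(!in_ev)) mean(counts[!in_ev]) else NA_real_,
       counts = counts, in_event = in_ev)
}
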