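#' Gauss linking number of two closed polylines
#'
#' Exact linking number of two closed polygonal curves, computed by summing
#' the analytic Gauss-integral contribution (signed solid angle) of every
#' segment pair.  For non-intersecting closed curves the sum is an integer up
#' to floating-point error; the rounded value is returned with the raw sum as
#' an attribute.  Sign convention: right-handed, so a Hopf link built by
#' [build_polycatenane()] has alternating-sign adjacent pairs of magnitude 1.
#'
#' @param ring_a,ring_b Matrices (n x 3) of vertices; the polyline closes
#'   last-to-first implicitly.
#' @param tol Minimum allowed distance between segments of the two curves; a
#'   pair closer than this is treated as an intersection and is an error
#'   (topology ill-defined).
#' @return Integer linking number, with attribute `"raw"` (the unrounded Gauss
#'   sum).
#' @examples
#' t <- seq(0, 2 * pi, length.out = 41)[-41]
#' a <- cbind(cos(t), sin(t), 0)
#' b <- cbind(1 + cos(t), 0, sin(t))  # canonical Hopf partner
#' linking_number(a, b)
#' @export
linking_number <- function(ring_a, ring_b, tol = 1e-6) {
  ring_a <- as.matrix(ring_a); ring_b <- as.matrix(ring_b)
  stopifnot(ncol(ring_a) == 3, ncol(ring_b) == 3)
  raw <- .linking_number_cpp(ring_a, ring_b, tol)
  lk <- round(raw)
  if (abs(raw - lk) > 0.05)
    warning(sprintf("Gauss sum %.4f is far from an integer; curves may be degenerate", raw))
  structure(as.integer(lk), raw = raw)
}

# regular polygon of n beads, radius R, centred at `centre`, in the plane
# with normal "z" (x-y plane) or "y" (x-z plane); first bead at phase t0
.ring_circle <- function(n, R, centre, normal = c("z", "y"), t0 = 0) {
  normal <- match.arg(normal)
  t <- t0 + 2 * pi * (seq_len(n) - 1) / n
  if (normal == "z")
    cbind(centre[1] + R * cos(t), centre[2] + R * sin(t), centre[3])
  else
    cbind(centre[1] + R * cos(t), centre[2], centre[3] + R * sin(t))
}

# stadium-shaped closed loop of n beads in the z = 0 plane: a thin hairpin
# elongated along -x whose apex (bead 1) sits on the pore axis at x = apex_x.
# Bead 1's neighbours run back along the two strands at y = +-width/2, so the
# loop threads a pore whose axis passes through the apex.
.ring_stadium <- function(n, bond_length, apex_x, width = 1.6) {
  P <- n * bond_length
  hw <- width / 2
  Lst <- (P - pi * width) / 2
  if (Lst <= 0) stop("ring too short for a stadium shape")
  s <- (seq_len(n) - 1) * bond_length
  # path from the apex (apex_x, 0): quarter cap up, strand -x at +hw, tail
  # semicircle, strand +x at -hw, quarter cap back to the apex
  q1 <- pi * hw / 2; s2 <- q1 + Lst; s3 <- s2 + pi * hw; s4 <- s3 + Lst
  xy <- t(vapply(s, function(si) {
    if (si < q1) {
      a <- si / hw
      c(apex_x - hw + hw * cos(a), hw * sin(a))
    } else if (si < s2) {
      c(apex_x - hw - (si - q1), hw)
    } else if (si < s3) {
      a <- (si - s2) / hw
      c(apex_x - hw - Lst - hw * sin(a), hw * cos(a))
    } else if (si < s4) {
      c(apex_x - hw - Lst + (si - s3), -hw)
    } else {
      a <- (si - s4) / hw
      c(apex_x - hw + hw * sin(a), -hw * cos(a))
    }
  }, numeric(2)))
  cbind(xy[, 1], xy[, 2], 0)
}

#' Build an interlocked poly[n]catenane (or a simple ring polymer)
#'
#' Constructs the bead/bond topology and initial coordinates of a
#' polycatenane of `n_rings` mechanically interlocked rings of
#' `beads_per_ring` beads each.  The first ring is a thin hairpin (stadium)
#' loop elongated along the open -x direction whose apex bead sits on the
#' pore axis at `x_entry`: held fixed during equilibration, it keeps the
#' chain threaded through the pore so that the driving force engages at
#' release.  The remaining rings are planar circles on the cis side in
#' alternating orthogonal planes (normals along y and z, both planes
#' containing the pore axis), positioned so that every consecutive pair
#' forms a Hopf link while non-adjacent rings stay clear of one another.
#'
#' With `n_rings = 1` the result is a simple (unknotted, uncatenated) ring
#' polymer with the same hairpin initial shape.
#'
#' Construction is verified: adjacent rings must have Gauss linking number
#' +/-1 and all other pairs 0, and no two beads may be closer than
#' `min_dist`.  If jitter causes a violation, placement is retried with fresh
#' jitter a few times before failing.
#'
#' @param n_rings Number of rings (>= 1).
#' @param beads_per_ring Beads per ring (>= 8).
#' @param bond_length Rest bond spacing along each ring, in \eqn{\sigma}.
#' @param x_entry Axial position of the first bead, the hairpin apex
#'   (default 4.5, just past the exit plane of a pore occupying x in
#'   `[0, 4]`).  Holding this bead fixed during equilibration keeps the
#'   hairpin threaded through the full pore, so at release the driving
#'   force acts on the ~10 in-pore beads at once and exceeds the
#'   confinement barrier of the narrow channels; a shallowly threaded chain
#'   is otherwise expelled before translocation can start.
#' @param jitter Uniform positional jitter amplitude in \eqn{\sigma} applied
#'   to every bead (gives each replica a distinct starting point; the main
#'   randomisation comes from thermal equilibration).
#' @param box Transverse periodic extents, used only to decide between circle
#'   and stadium initial shapes for large single rings.
#' @param seed Integer seed for the jitter (recorded in the result).
#' @param min_dist Minimum allowed bead-bead distance after placement.
#' @return An object of class `polymer_system`: list with `coords` (N x 3),
#'   `topology` (class `polymer_topology`: `n_beads`, `bonds` (2-column
#'   matrix), `ring_of_bead`, `n_rings`, `beads_per_ring`, `catenation`
#'   adjacency pairs), and `seed`.
#' @examples
#' cat4 <- build_polycatenane(4, 40)
#' ring <- build_polycatenane(1, 160)
#' @export
build_polycatenane <- function(n_rings = 4, beads_per_ring = 40,
                               bond_length = 1.0, x_entry = 4.5,
                               jitter = 0.02, box = c(20, 20), seed = 1,
                               min_dist = 0.9) {
  stopifnot(n_rings >= 1, beads_per_ring >= 8, bond_length > 0)
  R <- beads_per_ring * bond_length / (2 * pi)
  n_beads <- n_rings * beads_per_ring

  # ring 1 is a thin hairpin (stadium) threading the pore, apex bead held at
  # x_entry on the axis; rings 2..n are circles on the cis side, alternating
  # orthogonal planes, placed so that consecutive pairs are Hopf links and
  # non-adjacent rings stay clear of each other
  width <- 1.6
  base_coords <- function() {
    coords <- .ring_stadium(beads_per_ring, bond_length, x_entry, width)
    if (n_rings > 1) {
      Lst <- (beads_per_ring * bond_length - pi * width) / 2
      x_tail <- x_entry - Lst - width
      cx <- x_tail - 0.25 * R      # ring 2: crossing point 0.75 R inside the tail
      for (k in 2:n_rings) {
        normal <- if (k %% 2 == 0) "y" else "z"
        # half-step phase so no bead sits exactly at the plane crossing
        coords <- rbind(coords,
                        .ring_circle(beads_per_ring, R, c(cx, 0, 0), normal,
                                     t0 = pi / beads_per_ring))
        gap <- if (k == 2) 1.2 else 1.5  # ring 3 must also clear the stadium
        cx <- cx - gap * R
      }
    }
    coords
  }

  for (attempt in 1:5) {
    coords <- base_coords()
    if (jitter > 0) {
      j <- .with_seed(seed + 1000L * (attempt - 1L),
                      matrix(runif(3 * n_beads, -jitter, jitter), ncol = 3))
      coords <- coords + j
    }
    dmin <- .min_pair_dist(coords, exclude_bonded = FALSE)
    if (dmin >= min_dist) break
    if (attempt == 5)
      stop(sprintf("bead overlap after placement (min distance %.3f < %.3f)",
                   dmin, min_dist))
  }

  ring_of_bead <- rep(seq_len(n_rings), each = beads_per_ring)
  bonds <- do.call(rbind, lapply(seq_len(n_rings), function(k) {
    i0 <- (k - 1) * beads_per_ring
    cbind(i0 + seq_len(beads_per_ring),
          i0 + c(seq_len(beads_per_ring - 1) + 1, 1))
  }))
  catenation <- if (n_rings > 1)
    cbind(seq_len(n_rings - 1), seq_len(n_rings - 1) + 1)
  else matrix(integer(0), ncol = 2)

  topo <- structure(list(n_beads = n_beads, bonds = bonds,
                         ring_of_bead = ring_of_bead, n_rings = n_rings,
                         beads_per_ring = beads_per_ring,
                         catenation = catenation),
                    class = "polymer_topology")
  obj <- structure(list(coords = coords, topology = topo, seed = seed),
                   class = "polymer_system")
  .check_catenation(obj)
  obj
}

#' Convenience constructor for the 160-bead reference ring polymer
#'
#' @param n_beads Number of beads in the single ring.
#' @param ... Passed to [build_polycatenane()].
#' @return A `polymer_system`, see [build_polycatenane()].
#' @export
build_ring_polymer <- function(n_beads = 160, ...) {
  build_polycatenane(n_rings = 1, beads_per_ring = n_beads, ...)
}

# smallest pairwise distance (bonded pairs included unless excluded)
.min_pair_dist <- function(coords, exclude_bonded = FALSE, bonds = NULL) {
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  if (exclude_bonded && !is.null(bonds)) d[bonds] <- Inf
  min(d)
}

# verify that pairwise linking numbers reproduce the requested linear chain
.check_catenation <- function(polymer, tol = 1e-6) {
  topo <- polymer$topology
  if (topo$n_rings < 2) return(invisible(TRUE))
  adj <- catenation_adjacency(polymer$coords, topo, tol = tol)
  want <- matrix(0L, topo$n_rings, topo$n_rings)
  for (r in seq_len(nrow(topo$catenation))) {
    want[topo$catenation[r, 1], topo$catenation[r, 2]] <- 1L
    want[topo$catenation[r, 2], topo$catenation[r, 1]] <- 1L
  }
  if (!all(abs(adj$linked) == want))
    stop("constructed catenation does not match the requested linear chain")
  invisible(TRUE)
}

#' Recover the catenation adjacency from coordinates
#'
#' Computes the Gauss linking number of every ring pair and reports which
#' pairs are mechanically interlocked (|Lk| >= 1).
#'
#' @param coords N x 3 bead coordinates.
#' @param topology A `polymer_topology` (see [build_polycatenane()]).
#' @param tol Passed to [linking_number()].
#' @return List with `lk` (signed linking-number matrix) and `linked`
#'   (integer adjacency matrix with 0 diagonal).
#' @export
catenation_adjacency <- function(coords, topology, tol = 1e-6) {
  nr <- topology$n_rings
  lk <- matrix(0, nr, nr)
  for (a in seq_len(nr - 1)) {
    for (b in (a + 1):nr) {
      ra <- coords[topology$ring_of_bead == a, , drop = FALSE]
      rb <- coords[topology$ring_of_bead == b, , drop = FALSE]
      v <- linking_number(ra, rb, tol = tol)
      lk[a, b] <- v
      lk[b, a] <- v
    }
  }
  list(lk = lk, linked = abs(lk) >= 1)
}

#' @export
print.polymer_system <- function(x, ...) {
  t <- x$topology
  kind <- if (t$n_rings == 1) "ring polymer" else sprintf("poly[%d]catenane", t$n_rings)
  cat(sprintf("%s: %d rings x %d beads (%d beads, %d bonds)\n",
              kind, t$n_rings, t$beads_per_ring, t$n_beads, nrow(t$bonds)))
  invisible(x)
}
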