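#' Build an FCC crystal slab with a cylindrical pore
#'
#' Fills a slab of extent `slab[1] x slab[2]` (transverse, periodic) by
#' `slab[3]` (along the pore axis, open) with an FCC lattice of frozen wall
#' beads and carves a cylindrical pore of radius `r` through it.  The pore
#' axis is the x axis; the entrance plane sits at `x_p = 0` and the pore
#' occupies \eqn{x \in [0, L]} with `L = slab[3]`.  Carving removes every
#' lattice site whose *centre* lies within radial distance `r` of the axis, so
#' the WCA-accessible radius is smaller than the nominal `r`; all radii
#' reported by this package refer to the carving radius.
#'
#' The conventional cubic cell edge is `lattice_spacing * sqrt(2)` (so
#' `lattice_spacing` is the nearest-neighbour distance).  The default
#' `lattice_spacing = sqrt(2)` (cell edge 2\eqn{\sigma}) is exactly
#' commensurate with the default slab, keeps the wall impenetrable under the
#' WCA pair potential (largest gap 1.41\eqn{\sigma}, far below twice the WCA
#' range), and places a lattice shell at radial distance
#' \eqn{\sqrt{2}\sigma} from the axis, so the carved channel widens abruptly
#' when the carving radius crosses that shell.  The cell is adjusted
#' independently along each direction to be commensurate with the periodic
#' transverse extents and with the slab thickness; if the adjustment exceeds
#' `tol` a warning reports the strained spacing.
#'
#' @param r Carving radius in \eqn{\sigma}; `r = 0` disables carving.  Must be
#'   smaller than half the transverse extent, otherwise the slab would be
#'   disconnected across the periodic boundary.
#' @param slab Extents `c(Ly, Lz, Lx)` in \eqn{\sigma}: two transverse
#'   (periodic) extents, then the pore length along x.  Default
#'   `c(20, 20, 4)`.
#' @param lattice_spacing Nearest-neighbour wall-bead distance in
#'   \eqn{\sigma}.
#' @param tol Relative commensurability tolerance before warning.
#' @return An object of class `pore_system`: list with `wall` (matrix of wall
#'   bead x,y,z), `r`, `axis`, `x_p`, `pore_length`, `box` (periodic y,z
#'   extents), `slab`, `lattice_spacing`, and `n_full` (bead count of the
#'   uncarved slab).
#' @examples
#' pore <- build_pore_system(1.5)
#' pore
#' @export
build_pore_system <- function(r, slab = c(20, 20, 4),
                              lattice_spacing = sqrt(2), tol = 1e-9) {
  stopifnot(length(slab) == 3, all(slab > 0), lattice_spacing > 0, r >= 0)
  Ly <- slab[1]; Lz <- slab[2]; Lx <- slab[3]
  if (r >= min(Ly, Lz) / 2)
    stop("pore radius reaches the periodic boundary: slab would be disconnected")
  a <- lattice_spacing * sqrt(2)  # conventional cubic cell edge
  ny <- max(1L, round(Ly / a)); ay <- Ly / ny
  nz <- max(1L, round(Lz / a)); az <- Lz / nz
  nx <- max(1L, round(Lx / a)); ax <- Lx / nx
  strain <- max(abs(c(ay, az, ax) / a - 1))
  if (strain > tol)
    warning(sprintf(
      "lattice adjusted for commensurability: cell edges (%.4f, %.4f, %.4f) vs nominal %.4f",
      ax, ay, az, a))

  basis <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  ix <- 0:nx                 # x open: include both faces
  iy <- 0:(ny - 1L)          # y, z periodic
  iz <- 0:(nz - 1L)
  g <- expand.grid(ix = ix, iy = iy, iz = iz)
  pts <- do.call(rbind, lapply(seq_len(nrow(basis)), function(b) {
    cbind(x = (g$ix + basis[b, 1]) * ax,
          y = (g$iy + basis[b, 2]) * ay - Ly / 2,
          z = (g$iz + basis[b, 3]) * az - Lz / 2)
  }))
  # drop sites beyond the open x faces (basis offsets on the top layer)
  pts <- pts[pts[, 1] <= Lx + 1e-9, , drop = FALSE]
  n_full <- nrow(pts)
  rad <- sqrt(pts[, 2]^2 + pts[, 3]^2)
  wall <- pts[rad >= r, , drop = FALSE]

  structure(list(wall = wall, r = r, axis = c(1, 0, 0), x_p = 0,
                 pore_length = Lx, box = c(Ly, Lz), slab = slab,
                 lattice_spacing = lattice_spacing, n_full = n_full),
            class = "pore_system")
}

#' @export
print.pore_system <- function(x, ...) {
  cat(sprintf(
    "FCC pore slab: %g x %g sigma transverse (periodic), length %g sigma along x\n",
    x$slab[1], x$slab[2], x$pore_length))
  cat(sprintf("  carving radius r = %g sigma, wall beads %d (of %d uncarved)\n",
              x$r, nrow(x$wall), x$n_full))
  invisible(x)
}

#' Which beads are inside the pore
#'
#' A bead is inside the pore when its axial coordinate lies in
#' \eqn{[x_p, x_p + L]} where `L` is the pore length.
#'
#' @param x Axial (x) coordinates of beads, a numeric vector, or an `F x N`
#'   matrix of axial coordinates over frames.
#' @param pore A [build_pore_system()] object (or any list with `x_p` and
#'   `pore_length`).
#' @return Logical vector/matrix of the same shape as `x`.
#' @export
in_pore <- function(x, pore) {
  x >= pore$x_p & x <= pore$x_p + pore$pore_length
}
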