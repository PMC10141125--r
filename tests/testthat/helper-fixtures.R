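# Shared fixtures built in code (no data files).

# analysis-only pore: geometry metadata without wall beads
stub_pore <- function(r = 1.5, x_p = 0, pore_length = 4) {
  structure(list(wall = matrix(numeric(0), ncol = 3), r = r,
                 axis = c(1, 0, 0), x_p = x_p, pore_length = pore_length,
                 box = c(20, 20), slab = c(20, 20, pore_length),
                 lattice_spacing = sqrt(2), n_full = 0L),
            class = "pore_system")
}

# minimal topology for hand-built trajectories
stub_topology <- function(n, ring_of_bead = rep(1L, n)) {
  structure(list(n_beads = n, bonds = matrix(integer(0), ncol = 2),
                 ring_of_bead = ring_of_bead,
                 n_rings = length(unique(ring_of_bead)),
                 beads_per_ring = NA_integer_,
                 catenation = matrix(integer(0), ncol = 2)),
            class = "polymer_topology")
}

# trajectory from an explicit axial-coordinate matrix [frames x beads]
traj_from_x <- function(x, times = seq_len(nrow(x)) - 1,
                        ring_of_bead = rep(1L, ncol(x)), pore = stub_pore()) {
  x <- as.matrix(x)
  co <- array(0, dim = c(nrow(x), ncol(x), 3))
  co[, , 1] <- x
  trajectory(times = times, coords = co,
             topology = stub_topology(ncol(x), ring_of_bead), pore = pore,
             status = "synthetic")
}

# regular n-gon of radius R, plane normal "z" or "y", centred at `centre`
circle_pts <- function(n, R = 1, centre = c(0, 0, 0), normal = "z") {
  t <- 2 * pi * (seq_len(n) - 1) / n
  if (normal == "z")
    cbind(centre[1] + R * cos(t), centre[2] + R * sin(t), centre[3])
  else
    cbind(centre[1] + R * cos(t), centre[2], centre[3] + R * sin(t))
}

# brute-force reversible census at frame times (naive oracle)
naive_census <- function(traj, x_p = traj$pore$x_p) {
  x <- axial_coords(traj)
  rowMeans(x > x_p)
}

# tiny engine system: one or two free beads, no bonds
free_beads_topology <- function(n) stub_topology(n)
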