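test_that("pore carving removes exactly the beads inside the radius", {
  pore <- suppressWarnings(build_pore_system(1.1))
  rad <- sqrt(pore$wall[, 2]^2 + pore$wall[, 3]^2)
  expect_true(all(rad >= 1.1))
  expect_true(all(pore$wall[, 1] >= pore$x_p - 1e-9))
  expect_true(all(pore$wall[, 1] <= pore$x_p + pore$pore_length + 1e-9))
})

test_that("uncarved slab matches a brute-force FCC enumeration", {
  pore <- build_pore_system(0)
  expect_equal(nrow(pore$wall), pore$n_full)
  # independent enumeration: all FCC sites (cubic grid a = 2 plus the three
  # face-centre offsets) inside the slab, periodic y/z half-open, x closed
  a <- 2
  base <- as.matrix(expand.grid(x = seq(-2, 6, by = 1),
                                y = seq(-12, 12, by = 1),
                                z = seq(-12, 12, by = 1)))
  basis <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0)) * a
  sites <- do.call(rbind, lapply(1:4, function(b)
    sweep(base * a, 2, basis[b, ], "+")))
  keep <- sites[, 1] >= -1e-9 & sites[, 1] <= 4 + 1e-9 &
    sites[, 2] >= -10 - 1e-9 & sites[, 2] < 10 - 1e-9 &
    sites[, 3] >= -10 - 1e-9 & sites[, 3] < 10 - 1e-9
  expect_equal(pore$n_full, sum(keep))
})

test_that("carving is monotone in the radius and deterministic", {
  p1 <- build_pore_system(1.1)
  p2 <- build_pore_system(2.5)
  expect_lt(nrow(p2$wall), nrow(p1$wall))
  expect_identical(build_pore_system(1.1)$wall, p1$wall)
})

test_that("too-large radius is rejected", {
  expect_error(build_pore_system(10), "disconnected")
})

test_that("incommensurate lattice spacing adjusts with a warning", {
  expect_warning(build_pore_system(1.1, lattice_spacing = 1.0),
                 "commensurability")
})

test_that("canonical Hopf link and unlinked circles give +/-1 and 0", {
  a <- circle_pts(40, 1, c(0, 0, 0), "z")
  b <- circle_pts(40, 1, c(1, 0, 0), "y")
  expect_equal(abs(as.integer(linking_number(a, b))), 1L)
  b2 <- circle_pts(40, 1, c(3, 0, 0), "z")
  expect_identical(as.integer(linking_number(a, b2)), 0L)
})

test_that("linking number is symmetric and refinement-stable", {
  a <- circle_pts(40, 1, c(0, 0, 0), "z")
  b <- circle_pts(40, 1, c(1, 0, 0), "y")
  expect_identical(as.integer(linking_number(a, b)),
                   as.integer(linking_number(b, a)))
  a2 <- circle_pts(1000, 1, c(0, 0, 0), "z")
  b2 <- circle_pts(1000, 1, c(1, 0, 0), "y")
  expect_identical(as.integer(linking_number(a, b)),
                   as.integer(linking_number(a2, b2)))
  # raw Gauss sums agree closely between discretisations
  expect_lt(abs(attr(linking_number(a, b), "raw") -
                  attr(linking_number(a2, b2), "raw")), 1e-6)
})

test_that("intersecting curves are rejected", {
  a <- circle_pts(24, 1, c(0, 0, 0), "z")
  b <- a  # identical curves intersect everywhere
  expect_error(linking_number(a, b), "intersect")
})

test_that("polycatenane topology: 4 x 40 rings, Hopf chain adjacency", {
  cat4 <- build_polycatenane(4, 40, seed = 3)
  topo <- cat4$topology
  expect_equal(topo$n_beads, 160)
  expect_equal(nrow(topo$bonds), 160)  # one closure bond per ring
  # each ring is a closed cycle: every bead has exactly 2 bond ends
  deg <- tabulate(c(topo$bonds), nbins = 160)
  expect_true(all(deg == 2))
  adj <- catenation_adjacency(cat4$coords, topo)
  expect_equal(abs(adj$lk[cbind(1:3, 2:4)]), rep(1, 3))
  off <- abs(adj$lk[cbind(c(1, 1, 2), c(3, 4, 4))])
  expect_equal(off, rep(0, 3))
})

test_that("single ring has 160 beads, 160 bonds, no catenation", {
  ring <- build_ring_polymer(160, seed = 2)
  expect_equal(ring$topology$n_rings, 1)
  expect_equal(ring$topology$n_beads, 160)
  expect_equal(nrow(ring$topology$bonds), 160)
  expect_equal(nrow(ring$topology$catenation), 0)
  # all bonds near the nominal length
  b <- ring$topology$bonds
  bl <- sqrt(rowSums((ring$coords[b[, 1], ] - ring$coords[b[, 2], ])^2))
  expect_true(all(bl > 0.8 & bl < 1.2))
})

test_that("construction is deterministic in the seed and respects min distance", {
  c1 <- build_polycatenane(4, 40, seed = 9)
  c2 <- build_polycatenane(4, 40, seed = 9)
  expect_identical(c1$coords, c2$coords)
  d <- as.matrix(dist(c1$coords)); diag(d) <- Inf
  expect_gte(min(d), 0.9)
})
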