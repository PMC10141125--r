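test_that("bead census in the pore matches a naive per-bead check", {
  pore <- stub_pore()
  frame <- cbind(c(-3, 0.5, 1, 3.9, 4.2, 2, 0.1), rnorm(7, sd = 0.3),
                 rnorm(7, sd = 0.3))
  bp <- beads_in_pore(frame, pore)
  naive <- which(frame[, 1] >= 0 & frame[, 1] <= 4)
  expect_equal(bp$beads, naive)
  expect_equal(bp$count, length(naive))
  # empty pore
  all_out <- cbind(rep(-2, 5), 0, 0)
  expect_equal(beads_in_pore(all_out, pore)$count, 0)
})

test_that("single-ring polymers yield zero knot events", {
  x <- matrix(cumsum(rep(0.5, 30)), ncol = 1)[, rep(1, 4)] - 5
  tr <- traj_from_x(x)  # one ring
  ev <- detect_knot_events(tr)
  expect_equal(nrow(ev), 0)
  expect_false(attr(ev, "flagged"))
})

test_that("scripted two-ring co-occupancy becomes one event of known length", {
  # ring 1 bead parked inside the pore; ring 2 bead inside during [10, 25]
  times <- seq(0, 40, by = 0.5)
  x1 <- rep(2, length(times))
  x2 <- ifelse(times >= 10 & times <= 25, 2, -5)
  x3 <- -8 + 0.01 * times  # stays cis
  tr <- traj_from_x(cbind(x1, x2, x3), times = times,
                    ring_of_bead = c(1L, 2L, 2L))
  ev <- detect_knot_events(tr, debounce = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_start, 10)
  expect_equal(ev$t_end, 25)
  expect_equal(ev$dtau, 15)
  expect_equal(ev$rings, "1,2")
})

test_that("flickering co-occupancy merges across sub-debounce gaps", {
  times <- seq(0, 30, by = 0.5)
  x1 <- rep(2, length(times))
  inside <- (times >= 5 & times <= 10) | (times >= 11 & times <= 16) |
    (times >= 25 & times <= 28)
  x2 <- ifelse(inside, 2, -5)
  tr <- traj_from_x(cbind(x1, x2), times = times, ring_of_bead = c(1L, 2L))
  ev <- detect_knot_events(tr, debounce = 2)
  # brute-force oracle: intervals [5,10], [11,16] merge (gap 1 < 2);
  # [25,28] stays separate (gap 9)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$t_start, c(5, 25))
  expect_equal(ev$t_end, c(16, 28))
  # with a tiny debounce nothing merges
  ev0 <- detect_knot_events(tr, debounce = 0.1)
  expect_equal(nrow(ev0), 3)
})

test_that("plane-fit orientation is exact on coplanar fixtures", {
  pore <- stub_pore()
  # beads on z = const: normal parallel to z, theta = 0
  f0 <- make_orientation_fixture(0, n_beads = 10)[1, , ]
  os <- ring_orientation(f0, pore)
  expect_equal(os$theta, 0, tolerance = 1e-7)
  # beads in the x-z plane: normal parallel to y, theta = 90
  f90 <- make_orientation_fixture(90, n_beads = 10)[1, , ]
  expect_equal(ring_orientation(f90, pore)$theta, 90, tolerance = 1e-7)
  # the 45-degree fold maps theta and 90 - theta onto the same value
  f30 <- make_orientation_fixture(30, n_beads = 10)[1, , ]
  f60 <- make_orientation_fixture(60, n_beads = 10)[1, , ]
  expect_equal(ring_orientation(f30, pore)$theta, 30, tolerance = 1e-7)
  expect_equal(ring_orientation(f60, pore)$theta, 60, tolerance = 1e-7)
  expect_equal(ring_orientation(f30, pore)$theta_folded,
               ring_orientation(f60, pore)$theta_folded, tolerance = 1e-7)
})

test_that("orientation degrades gracefully: too few or collinear beads", {
  pore <- stub_pore()
  expect_null(ring_orientation(cbind(2, 0.1, 0.1), pore))
  line <- cbind(seq(0.5, 3.5, length.out = 6), 0, 0)
  expect_null(ring_orientation(line, pore))
})

test_that("noisy coplanar beads stay within 2 degrees of the true tilt", {
  # perturbation oracle at noise amplitude 0.01 sigma
  pore <- stub_pore()
  set.seed(5)
  for (th in c(10, 45, 80)) {
    f <- make_orientation_fixture(th, n_beads = 12, noise = 0.01, seed = th)
    expect_lt(abs(ring_orientation(f[1, , ], pore)$theta - th), 2)
  }
})

test_that("theta is invariant under reflection through the pore axis plane", {
  pore <- stub_pore()
  f <- make_orientation_fixture(37, n_beads = 12)[1, , ]
  refl <- f
  refl[, 2] <- -refl[, 2]  # reflect y
  expect_equal(ring_orientation(f, pore)$theta,
               ring_orientation(refl, pore)$theta, tolerance = 1e-9)
})

test_that("insertion orientation samples the resident ring at event start", {
  # ring 1 coplanar (z = const => theta 0) resident in the pore; ring 2
  # enters at t = 10
  times <- seq(0, 20, by = 0.5)
  nf <- length(times)
  n1 <- 8
  disc <- make_orientation_fixture(0, n_beads = n1)[1, , ]
  co <- array(0, dim = c(nf, n1 + 1, 3))
  for (f in seq_len(nf)) co[f, 1:n1, ] <- disc
  co[, n1 + 1, 1] <- ifelse(times >= 10, 2, -5)
  tr <- trajectory(times, co,
                   stub_topology(n1 + 1, c(rep(1L, n1), 2L)),
                   pore = stub_pore(), status = "synthetic")
  ev <- detect_knot_events(tr)
  expect_equal(nrow(ev), 1)
  ins <- insertion_orientation(tr, ev)
  expect_equal(nrow(ins), 1)
  expect_equal(ins$ring, 1L)
  expect_equal(ins$theta, 0, tolerance = 1e-7)
  expect_equal(ins$t_start, ev$t_start)
})

test_that("Shannon entropy: uniform, degenerate and two-bin closed forms", {
  edges <- seq(0, 90, by = 5)
  uniform <- rep(seq(2.5, 87.5, by = 5), times = 7)  # same count in all 18 bins
  expect_equal(shannon_entropy(uniform, edges)$S, log(18))
  expect_equal(shannon_entropy(uniform, edges)$S_max, log(18))
  degenerate <- rep(12, 50)
  expect_equal(shannon_entropy(degenerate, edges)$S, 0)
  two <- c(1, 89)
  expect_equal(shannon_entropy(two, edges)$S, log(2))
})

test_that("entropy is permutation-invariant and maximal only for uniform", {
  edges <- seq(0, 90, by = 15)  # 6 bins
  s1 <- shannon_entropy(c(rep(5, 4), rep(40, 2), rep(80, 1)), edges)
  s2 <- shannon_entropy(c(rep(80, 4), rep(5, 2), rep(40, 1)), edges)
  expect_equal(s1$S, s2$S)
  expect_lt(s1$S, log(6))
  su <- shannon_entropy(c(7, 22, 37, 52, 67, 82), edges)
  expect_equal(su$S, log(6))
})

test_that("pore occupancy is higher during knot events on scripted data", {
  times <- seq(0, 40, by = 0.5)
  nf <- length(times)
  # ring 1: 3 beads always in pore; ring 2: 4 beads inside during [10, 20]
  co <- array(0, dim = c(nf, 7, 3))
  co[, 1:3, 1] <- 2
  co[, 4:7, 1] <- -5
  co[times >= 10 & times <= 20, 4:7, 1] <- 2
  tr <- trajectory(times, co, stub_topology(7, c(1L, 1L, 1L, 2L, 2L, 2L, 2L)),
                   pore = stub_pore(), status = "synthetic")
  ev <- detect_knot_events(tr)
  st <- pore_occupancy_stats(tr, ev)
  expect_gt(st$mean_knot, st$mean_noknot)
  expect_equal(st$mean_knot, 7)
  expect_equal(st$mean_noknot, 3)
})
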