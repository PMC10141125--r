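test_that("FENE restoring force matches the closed form", {
  # independent closed-form oracle: k r / (1 - (r/R0)^2), k = 30, R0 = 1.5
  oracle <- function(r) 30 * r / (1 - (r / 1.5)^2)
  expect_equal(fene_force(1.0), 54.0)
  expect_equal(fene_force(1.0), oracle(1.0))
  rs <- c(0.2, 0.5, 0.97, 1.2, 1.4)
  expect_equal(fene_force(rs), oracle(rs))
  # divergence towards R0: force at 1.49 is more than 10x the force at 1.0
  expect_gt(fene_force(1.49), 10 * fene_force(1.0))
  # linear near the origin: magnitude vanishes
  expect_lt(fene_force(1e-8), 1e-6)
  expect_error(fene_force(1.5), "R0")
  expect_error(fene_force(0), "positive")
})

test_that("WCA energy is epsilon at sigma, zero at and beyond the cutoff", {
  expect_equal(wca_energy(1), 1)
  expect_equal(wca_energy(2^(1 / 6)), 0)
  expect_equal(wca_energy(2), 0)
  # continuity at the cutoff
  eps <- 1e-8
  expect_lt(abs(wca_energy(2^(1 / 6) - eps)), 1e-6)
  # repulsive below sigma
  expect_gt(wca_energy(0.8), wca_energy(1))
})

test_that("engine pair forces obey Newton's third law (momentum balance)", {
  # free catenane, no wall, no drive: deterministic forces sum to zero
  cat4 <- build_polycatenane(4, 40, seed = 5)
  f <- polymer_forces(cat4$coords, cat4$topology, pore = NULL, drive = FALSE)
  expect_lt(max(abs(colSums(f))), 1e-9)
})

test_that("engine forces match a brute-force R evaluation on a small ring", {
  ring <- build_polycatenane(1, 12, seed = 4)
  co <- ring$coords
  p <- sim_params()
  f <- polymer_forces(co, ring$topology, pore = NULL, params = p)
  # naive O(N^2) oracle: FENE on bonds + WCA on all pairs
  n <- nrow(co)
  fr <- matrix(0, n, 3)
  for (b in seq_len(nrow(ring$topology$bonds))) {
    i <- ring$topology$bonds[b, 1]; j <- ring$topology$bonds[b, 2]
    d <- co[i, ] - co[j, ]; r <- sqrt(sum(d^2))
    fm <- -p$k_fene / (1 - (r / p$R0)^2)
    fr[i, ] <- fr[i, ] + fm * d
    fr[j, ] <- fr[j, ] - fm * d
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- co[i, ] - co[j, ]; r2 <- sum(d^2)
    if (r2 < 2^(1 / 3)) {
      sr6 <- 1 / r2^3
      fp <- 24 * (2 * sr6^2 - sr6) / r2
      fr[i, ] <- fr[i, ] + fp * d
      fr[j, ] <- fr[j, ] - fp * d
    }
  }
  expect_equal(f, fr, tolerance = 1e-12)
})

test_that("driving force acts only on in-pore beads", {
  # one bead inside the pore, one outside, T = 0: only the inside bead
  # feels +x; one velocity-Verlet step accelerates it alone
  topo <- free_beads_topology(2)
  co <- rbind(c(2, 0, 0), c(-2, 0, 0))
  pore <- build_pore_system(1.5)
  f <- polymer_forces(co, topo, pore, drive = TRUE)
  expect_equal(f[1, ], c(1, 0, 0))
  expect_equal(f[2, ], c(0, 0, 0))
  p0 <- sim_params(kT = 0, gamma = 0)
  res <- porelink:::.run_engine(co, matrix(0, 2, 3), topo, pore, p0,
                                nsteps = 10, sample_every = 10,
                                drive = TRUE, stop_on_exit = FALSE, seed = 1)
  expect_gt(res$positions[1, 1], 2)
  expect_equal(res$positions[2, ], c(-2, 0, 0))
})

test_that("overdamped quiescent limit: no forces, no motion", {
  topo <- free_beads_topology(1)
  co <- matrix(c(-5, 0, 0), 1, 3)
  p0 <- sim_params(kT = 0, gamma = 100)
  res <- porelink:::.run_engine(co, matrix(0, 1, 3), topo, NULL, p0,
                                nsteps = 1000, sample_every = 100,
                                drive = FALSE, stop_on_exit = FALSE, seed = 1)
  expect_equal(res$positions, co, tolerance = 1e-12)
})

test_that("engine runs are bit-reproducible for a fixed seed", {
  ring <- build_polycatenane(1, 20, seed = 8)
  p <- sim_params()
  v <- init_velocities(20, p, 3)
  r1 <- porelink:::.run_engine(ring$coords, v, ring$topology, NULL, p,
                               nsteps = 2000, sample_every = 100,
                               drive = FALSE, stop_on_exit = FALSE, seed = 99)
  r2 <- porelink:::.run_engine(ring$coords, v, ring$topology, NULL, p,
                               nsteps = 2000, sample_every = 100,
                               drive = FALSE, stop_on_exit = FALSE, seed = 99)
  expect_identical(r1$frames, r2$frames)
  r3 <- porelink:::.run_engine(ring$coords, v, ring$topology, NULL, p,
                               nsteps = 2000, sample_every = 100,
                               drive = FALSE, stop_on_exit = FALSE, seed = 100)
  expect_false(identical(r3$frames, r2$frames))
})

test_that("a fixed bead never moves during equilibration", {
  ring <- build_polycatenane(1, 16, seed = 6)
  pore <- build_pore_system(2.5)
  p <- sim_params()
  res <- porelink:::.run_engine(ring$coords, init_velocities(16, p, 1),
                                ring$topology, pore, p, nsteps = 4000,
                                sample_every = 200, fixed_bead = 1L,
                                drive = FALSE, stop_on_exit = FALSE, seed = 5)
  expect_equal(res$positions[1, ], ring$coords[1, ], tolerance = 1e-12)
  moved <- sqrt(sum((res$positions[5, ] - ring$coords[5, ])^2))
  expect_gt(moved, 0.01)
})

test_that("FENE bonds stay below R0 and pair distances above 0.8 sigma", {
  ring <- build_polycatenane(1, 24, seed = 7)
  p <- sim_params()
  res <- porelink:::.run_engine(ring$coords, init_velocities(24, p, 2),
                                ring$topology, NULL, p, nsteps = 20000,
                                sample_every = 500, drive = FALSE,
                                stop_on_exit = FALSE, seed = 13)
  b <- ring$topology$bonds
  for (f in seq_along(res$times)) {
    co <- res$frames[f, , ]
    bl <- sqrt(rowSums((co[b[, 1], ] - co[b[, 2], ])^2))
    expect_true(all(bl < 1.5))
    d <- as.matrix(dist(co)); diag(d) <- Inf
    expect_gte(min(d), 0.8)
  }
})

test_that("kinetic temperature satisfies equipartition on a force-free run", {
  ring <- build_polycatenane(1, 40, seed = 10)
  p <- sim_params()
  res <- porelink:::.run_engine(ring$coords, init_velocities(40, p, 4),
                                ring$topology, NULL, p, nsteps = 100000,
                                sample_every = 400, drive = FALSE,
                                stop_on_exit = FALSE, seed = 21)
  tk <- res$tkin[-(1:25)]  # discard the equilibration transient
  se <- sd(tk) / sqrt(length(tk))
  expect_lt(abs(mean(tk) - 1), max(3 * se, 0.02))
})
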