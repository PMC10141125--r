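test_that("first crossing only: recrossings do not reset the clock", {
  # 1 bead: crosses x_p = 0 at t = 3, dips back at t = 4, recrosses at 5
  x <- matrix(c(-3, -2, -1, 1, -1, 1, 2, 3, 4, 5), ncol = 1)
  tr <- traj_from_x(x)
  ev <- crossing_events(tr)
  expect_equal(ev$dir, c(1L, -1L, 1L))
  tau <- first_passage_times(tr)
  expect_equal(tau, 2.5)  # interpolated between frames at t = 2 (-1) and 3 (+1)
})

test_that("monotone path has a unique interpolated crossing", {
  x <- matrix(seq(-2, 2, by = 0.5), ncol = 1)
  tr <- traj_from_x(x)
  tau <- first_passage_times(tr)
  expect_equal(tau, 4)  # x = 0 exactly at frame 5, time 4
  expect_equal(nrow(crossing_events(tr)), 1)
})

test_that("beads that never cross raise an error unless strict = FALSE", {
  x <- cbind(seq(-2, 2, length.out = 5), seq(-9, -5, length.out = 5))
  tr <- traj_from_x(x)
  expect_error(first_passage_times(tr), "never crossed")
  tau <- first_passage_times(tr, strict = FALSE)
  expect_true(is.na(tau[2]) && !is.na(tau[1]))
})

test_that("irreversible profile is the order statistics of first passages", {
  prof <- irreversible_profile(c(1, 2, 3, 4))
  expect_equal(prof$x, c(0, .25, .5, .75, 1))
  expect_equal(prof$tau, c(0, 1, 2, 3, 4))
  # x_irrev(2.5) = 0.5: two of four beads crossed
  expect_equal(max(prof$x[prof$tau <= 2.5]), 0.5)
  # nondecreasing step function reaching 1 at max tau_i
  expect_true(all(diff(prof$tau) >= 0))
  expect_equal(prof$tau[prof$x == 1], 4)
  # ties jump by multiples of 1/N
  pt <- irreversible_profile(c(2, 2, 2, 5))
  expect_equal(pt$tau, c(0, 2, 2, 2, 5))
})

test_that("reversible census equals the brute-force per-frame oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 6
    x <- matrix(cumsum(rnorm(40 * n, mean = 0.08, sd = 0.6)), ncol = n) - 2
    x[nrow(x), ] <- abs(x[nrow(x), ]) + 1  # end fully translocated
    tr <- traj_from_x(x)
    prof <- reversible_profile(tr)
    cen <- attr(prof, "census")
    # the event-based census evaluated at frame times equals the naive census
    at_frames <- vapply(tr$times, function(t)
      cen$x[max(which(cen$time <= t))], numeric(1))
    expect_equal(at_frames, naive_census(tr), tolerance = 1e-12)
  }
})

test_that("oscillating bead: census fluctuates while first-passage holds", {
  x <- matrix(c(-1, 1, -1, 1, 2, 3), ncol = 1)
  tr <- traj_from_x(x)
  prof_r <- reversible_profile(tr)
  cen <- attr(prof_r, "census")
  expect_equal(cen$x, c(0, 1, 0, 1))
  tau_i <- first_passage_times(tr)
  expect_equal(tau_i, 0.5)
  # last permanent attainment is the third crossing, not the first
  expect_equal(prof_r$tau[prof_r$x == 1], 2.5)
})

test_that("tau_irrev <= tau_rev at every fraction; totals agree", {
  set.seed(7)
  for (rep in 1:8) {
    n <- 8
    x <- matrix(cumsum(rnorm(60 * n, mean = 0.1, sd = 0.7)), ncol = n) - 3
    x[nrow(x), ] <- abs(x[nrow(x), ]) + 2
    tr <- traj_from_x(x)
    profs <- translocation_profiles(tr)
    ir <- profs$irreversible$tau
    rv <- profs$reversible$tau
    expect_true(all(ir <= rv + 1e-9))
    # totals: identical when the last entrance crossing is a first passage
    last_up <- max(subset(crossing_events(tr), dir > 0)$time)
    if (abs(max(first_passage_times(tr)) - last_up) < 1e-9)
      expect_equal(ir[length(ir)], rv[length(rv)])
  }
})

test_that("monotone trajectories give identical profiles under both definitions", {
  n <- 10
  tau_true <- sort(runif(n, 5, 50))
  x <- outer(seq(0, 60, by = 0.5), tau_true, function(t, tt) 0.2 * (t - tt))
  tr <- traj_from_x(x, times = seq(0, 60, by = 0.5))
  profs <- translocation_profiles(tr)
  expect_equal(profs$irreversible$tau, profs$reversible$tau, tolerance = 1e-9)
  expect_equal(profs$irreversible$tau[-1], tau_true, tolerance = 1e-9)
})

test_that("waiting times: constant gaps and dwell-time partition", {
  # uniform crossing schedule: irreversible waiting time is the spacing
  prof <- irreversible_profile(seq(2, 20, by = 2))
  w <- waiting_time(prof)
  expect_equal(w$w[-1], rep(2, 9))
  # reversible dwell times sum to the total translocation time
  set.seed(11)
  x <- matrix(cumsum(rnorm(50 * 5, mean = 0.12, sd = 0.5)), ncol = 5) - 2
  x[nrow(x), ] <- abs(x[nrow(x), ]) + 2
  tr <- traj_from_x(x)
  pr <- reversible_profile(tr)
  expect_equal(sum(pr$w), pr$tau[nrow(pr)] - tr$times[1])
})

test_that("Savitzky-Golay filter reproduces low-order polynomials exactly", {
  t <- seq_len(41)
  y <- 2 + 0.5 * t - 0.03 * t^2 + 0.001 * t^3
  expect_equal(sg_smooth(y, window = 9, order = 3), y, tolerance = 1e-8)
  const <- rep(3.7, 25)
  expect_equal(sg_smooth(const), const)
  expect_error(sg_smooth(rnorm(5), window = 9), "window")
})

test_that("Savitzky-Golay filter reduces white-noise variance", {
  # Monte-Carlo oracle: smoothing must shrink the variance of pure noise
  set.seed(123)
  ratios <- replicate(20, {
    y <- rnorm(200)
    var(sg_smooth(y, 9, 3)) / var(y)
  })
  expect_true(all(ratios < 1))
  expect_lt(mean(ratios), 0.6)
})
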