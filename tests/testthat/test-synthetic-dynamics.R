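# Oracle: a single uncoupled subsystem must match an independently written
# fixed-step RK4 integration of the classic Lorenz equations.
test_that("single uncoupled subsystem matches a hand-rolled RK4 oracle", {
  cfg <- lorenz_config(n_subsystems = 1, coupling = 0, dt = 0.01,
                       sample_every = 1L, n_samples = 200L,
                       transient_steps = 0L, seed = 11)
  traj <- simulate_coupled_lorenz(cfg)
  y0 <- with_seed(derive_seeds(11, 3)[1], runif(3, -10, 10))
  ref <- reference_lorenz_rk4(y0, n_steps = 200, dt = 0.01)
  expect_equal(unname(traj$values), ref[, 2:201], tolerance = 1e-10)
})

test_that("uncoupled ring decomposes into independent Lorenz systems", {
  # With coupling = 0 each subsystem evolves autonomously; integrating the
  # 3-subsystem ring must agree with integrating each subsystem alone from
  # its own slice of the shared initial condition.
  cfg <- lorenz_config(n_subsystems = 3, coupling = 0, dt = 0.01,
                       sample_every = 2L, n_samples = 50L,
                       transient_steps = 0L, seed = 5)
  traj <- simulate_coupled_lorenz(cfg)
  y0 <- with_seed(derive_seeds(5, 3)[1], runif(9, -10, 10))
  for (j in 1:3) {
    rows <- (3 * j - 2):(3 * j)
    ref <- reference_lorenz_rk4(y0[rows], n_steps = 100, dt = 0.01)
    expect_equal(unname(traj$values[rows, ]),
                 ref[, seq(3, 101, by = 2)], tolerance = 1e-9)
  }
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  cfg <- lorenz_config(n_subsystems = 4, n_samples = 30, seed = 9)
  t1 <- simulate_coupled_lorenz(cfg)
  t2 <- simulate_coupled_lorenz(cfg)
  expect_identical(t1$values, t2$values)
  cfg2 <- lorenz_config(n_subsystems = 4, n_samples = 30, seed = 10)
  expect_false(identical(simulate_coupled_lorenz(cfg2)$values, t1$values))
})

test_that("dimensions, names and sampling times are as configured", {
  cfg <- lorenz_config(n_subsystems = 2, n_samples = 25, dt = 0.01,
                       sample_every = 5L, transient_steps = 100L, seed = 1)
  traj <- simulate_coupled_lorenz(cfg)
  expect_equal(dim(traj$values), c(6, 25))
  expect_equal(rownames(traj$values), c("x1", "y1", "z1", "x2", "y2", "z2"))
  expect_equal(diff(traj$times), rep(0.05, 24), tolerance = 1e-12)
  expect_equal(traj$times[1], 100 * 0.01 + 0.05, tolerance = 1e-12)
})

test_that("observation noise has the requested distribution and is additive", {
  cfg <- lorenz_config(n_subsystems = 10, n_samples = 200, seed = 2)
  clean <- simulate_coupled_lorenz(cfg)
  cfg_noisy <- lorenz_config(n_subsystems = 10, n_samples = 200, seed = 2,
                             noise_strength = 1)
  noisy <- simulate_coupled_lorenz(cfg_noisy)
  eps <- noisy$values - clean$values
  expect_equal(sd(eps), 1, tolerance = 0.05)        # 6000 draws
  expect_equal(mean(eps), 0, tolerance = 0.05)
  expect_gt(shapiro.test(eps[seq_len(500)])$p.value, 1e-4)
})

test_that("add_observation_noise with strength 0 is the identity", {
  traj <- fixture_trajectory()
  expect_identical(add_observation_noise(traj, 0)$values, traj$values)
})

test_that("time-varying regime switches parameters on schedule", {
  # Compare a time-varying run against a time-invariant run whose fixed
  # parameters equal the first scheduled draw: they must agree exactly up
  # to the first switch and diverge after it.
  cfg <- lorenz_config(n_subsystems = 2, n_samples = 60, dt = 0.01,
                       sample_every = 5L, transient_steps = 0L,
                       time_varying = TRUE, switch_period = 1, seed = 21)
  tv <- simulate_coupled_lorenz(cfg)
  sched_seed <- derive_seeds(21, 3)[2]
  n_seg <- ceiling(60 * 5 * 0.01 / 1) + 1
  sched <- with_seed(sched_seed, {
    cbind(runif(n_seg, 8, 12), runif(n_seg, 22.4, 33.6),
          runif(n_seg, 8 / 3 * 0.8, 8 / 3 * 1.2))
  })
  cfg_fix <- lorenz_config(n_subsystems = 2, n_samples = 60, dt = 0.01,
                           sample_every = 5L, transient_steps = 0L,
                           sigma = sched[1, 1], rho = sched[1, 2],
                           beta = sched[1, 3],
                           param_ranges = cfg$param_ranges, seed = 21)
  fx <- simulate_coupled_lorenz(cfg_fix)
  # samples at times 0.05 * k; switch at t = 1, and the RK4 step ending
  # exactly there already evaluates the new parameters, so samples 1..19
  # are shared.
  expect_equal(tv$values[, 1:19], fx$values[, 1:19], tolerance = 1e-10)
  expect_gt(max(abs(tv$values[, 40:60] - fx$values[, 40:60])), 1e-3)
})

test_that("trajectory CSV round-trips", {
  traj <- simulate_coupled_lorenz(lorenz_config(n_subsystems = 2, n_samples = 12, seed = 4))
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_equal(unname(back), unname(traj$values), tolerance = 1e-12,
               ignore_attr = "times")
  expect_equal(attr(back, "times"), traj$times, tolerance = 1e-9)
  expect_true(file.exists(sub("\\.csv$", ".json", f)))
})

test_that("invalid configurations are rejected", {
  expect_error(lorenz_config(n_subsystems = 0), "n_subsystems")
  expect_error(lorenz_config(dt = 0), "dt")
  expect_error(lorenz_config(noise_strength = -1), "noise")
  expect_error(lorenz_config(time_varying = TRUE, switch_period = 0), "switch_period")
})

test_that("divergent integration raises an informative error", {
  cfg <- lorenz_config(n_subsystems = 3, coupling = 50, n_samples = 50, seed = 1)
  expect_error(suppressWarnings(simulate_coupled_lorenz(cfg)), "diverged")
})
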