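# Engine: fields, forces, Euler-Maruyama propagation, the integrate /
# get_particle_data contract and boundaries.

test_that("concentration field evaluates the gaussian profile", {
  f <- concentration_field(c(2, 3), c0 = 1.5, sigma = 1)
  expect_equal(field_value(f, c(2, 3)), 1.5)                 # max at source
  expect_lt(field_value(f, c(200, 3)), 1e-300)               # decay limit
  f1 <- concentration_field(c(0, 0), c0 = 1, sigma = 1)
  expect_equal(field_value(f1, c(1, 0)), exp(-0.5), tolerance = 1e-12)
  # matrix input matches elementwise evaluation, positivity everywhere
  X <- matrix(rnorm(20), 10, 2)
  v <- field_value(f1, X)
  expect_equal(v, apply(X, 1, function(x) field_value(f1, x)))
  expect_true(all(v > 0))
})

test_that("WCA force has the correct cutoff, magnitude and direction", {
  rc <- 2^(1 / 6)
  expect_equal(wca_force(c(rc, 0), 1, 1), c(0, 0))
  expect_equal(wca_force(c(3, 1), 1, 1), c(0, 0))
  # hand-evaluated 24*eps*(2*sigma^12/r^13 - sigma^6/r^7) at r = 1 -> 24
  f <- wca_force(c(1, 0), eps = 1, sigma = 1)
  expect_equal(f, c(24, 0), tolerance = 1e-12)
  expect_warning(wca_force(c(0.3, 0), 1, 1), "capped")
  # repulsive: force on i points away from j
  f2 <- wca_force(c(-0.9, 0), 1, 1)
  expect_lt(f2[1], 0)
  # pairwise accumulation matches the two-body evaluation
  pos <- rbind(c(0, 0), c(0.9, 0))
  F2 <- swarmlearn:::pair_forces_wca(pos, 1, 1)
  expect_equal(F2[1, ], wca_force(c(-0.9, 0), 1, 1))
  expect_equal(F2[2, ], -F2[1, ])
})

test_that("zero-temperature passive system is a fixed point of step", {
  cs <- grid_state(rbind(c(1, 1), c(2, 2)))
  p <- system_params(temperature = 0, dt = 0.1, boundary = "none")
  eng <- new_engine(cs, p)
  integrate_system(eng, passive_force_function(), 3, 5)
  out <- get_particle_data(eng)
  expect_equal(colloid_positions(out), colloid_positions(cs),
               ignore_attr = TRUE)
  expect_equal(colloid_directors(out), colloid_directors(cs),
               ignore_attr = TRUE)
})

test_that("deterministic ballistic displacement is gamma_t^-1 F dt along e", {
  dirs <- rbind(c(1, 0), c(0, 1), c(sqrt(0.5), sqrt(0.5)))
  cs <- colloid_state(0:2, rep(0L, 3), matrix(1, 3, 2), dirs)
  p <- system_params(temperature = 0, dt = 0.05, gamma_t = 4,
                     boundary = "none")
  eng <- new_engine(cs, p)
  set <- action_set(go = action(force = 2))
  ff <- stub_force_function(action(force = 2))
  integrate_system(eng, ff, 1, 1)
  expected <- matrix(1, 3, 2) + (2 / 4) * 0.05 * dirs
  expect_equal(colloid_positions(get_particle_data(eng)), expected,
               ignore_attr = TRUE, tolerance = 1e-14)
})

test_that("integrate accounting: slices, inner steps, initial snapshot", {
  cs <- grid_state(matrix(runif(10), 5, 2))
  p <- system_params(dt = 0.01, boundary = "none")
  eng <- new_engine(cs, p)
  traj0 <- integrate_system(eng, passive_force_function(), 0, 10)
  expect_equal(n_snapshots(traj0), 1)          # only the initial snapshot
  ff <- stub_force_function()
  traj <- integrate_system(eng, ff, 5, 10)
  expect_equal(ff$calls, 5L)                   # one policy query per slice
  expect_equal(eng$stats$steps, 50L)           # 5 x 10 inner steps
  expect_equal(n_snapshots(traj), 6)           # initial + one per slice
})

test_that("kill switch raised at slice 3 leaves a 3+1 snapshot trajectory", {
  cs <- grid_state(matrix(runif(6), 3, 2))
  eng <- new_engine(cs, system_params(boundary = "none"))
  ff <- stub_force_function(kill_at = 3)
  traj <- integrate_system(eng, ff, 10, 2)
  expect_equal(n_snapshots(traj), 4)
  expect_equal(eng$halted_at_slice, 3L)
})

test_that("get_particle_data returns stable-id snapshots, not references", {
  cs <- grid_state(matrix(runif(14), 7, 2))
  eng <- new_engine(cs, system_params(boundary = "none"))
  d1 <- get_particle_data(eng)
  expect_equal(nrow(d1), 7)
  d1$x <- d1$x + 100                      # mutate the snapshot
  d2 <- get_particle_data(eng)
  expect_equal(d2$x, cs$x)                # engine unaffected
  expect_identical(d1$id, d2$id)          # same ids in same order
})

test_that("new_direction overrides the torque update and renormalizes", {
  cs <- grid_state(rbind(c(5, 5)))
  p <- system_params(temperature = 0, dt = 0.1, boundary = "none")
  eng <- new_engine(cs, p)
  # torque plus override: override wins
  a <- action(force = 0, torque = c(0, 0, 100), new_direction = c(3, 4))
  ff <- stub_force_function(a)
  integrate_system(eng, ff, 1, 1)
  e <- colloid_directors(get_particle_data(eng))
  expect_equal(as.numeric(e), c(0.6, 0.8), tolerance = 1e-12)
})

test_that("positive torque rotates the director counterclockwise", {
  cs <- grid_state(rbind(c(5, 5)))
  p <- system_params(temperature = 0, dt = 0.1, gamma_r = 2,
                     boundary = "none")
  eng <- new_engine(cs, p)
  ff <- stub_force_function(action(torque = c(0, 0, 1)))
  integrate_system(eng, ff, 1, 1)
  e <- as.numeric(colloid_directors(get_particle_data(eng)))
  ang <- atan2(e[2], e[1])
  expect_equal(ang, 1 / 2 * 0.1, tolerance = 1e-12)   # gamma_r^-1 M dt
})

test_that("directors stay unit norm through noisy integration", {
  cs <- grid_state(matrix(runif(40, 2, 8), 20, 2))
  p <- system_params(temperature = 2, dt = 0.01, boundary = "none", seed = 9)
  eng <- new_engine(cs, p)
  integrate_system(eng, passive_force_function(), 10, 10)
  e <- colloid_directors(get_particle_data(eng))
  expect_true(all(abs(sqrt(rowSums(e^2)) - 1) < 1e-9))
})

test_that("periodic boundaries wrap positions and bound image distances", {
  cs <- grid_state(matrix(runif(60, 0, 5), 30, 2))
  p <- system_params(box = c(5, 5), temperature = 1, dt = 0.05,
                     boundary = "periodic", seed = 4)
  eng <- new_engine(cs, p)
  integrate_system(eng, passive_force_function(), 20, 5)
  pos <- eng$pos
  expect_true(all(pos >= 0 & pos < 5))
  # minimum-image pair distances never exceed half the box diagonal
  half_diag <- sqrt(sum((c(5, 5) / 2)^2))
  for (i in 1:5) {
    dx <- minimum_image(sweep(pos, 2, pos[i, ]), c(5, 5))
    expect_true(all(sqrt(rowSums(dx^2)) <= half_diag + 1e-12))
  }
})

test_that("reflective boundaries keep particles inside the box", {
  cs <- grid_state(matrix(runif(40, 0, 4), 20, 2))
  p <- system_params(box = c(4, 4), temperature = 1, dt = 0.05,
                     boundary = "reflective", seed = 8)
  eng <- new_engine(cs, p)
  ff <- stub_force_function(action(force = 20))   # strong driving into walls
  integrate_system(eng, ff, 30, 5)
  expect_true(all(eng$pos >= 0 & eng$pos <= 4))
})

test_that("thermal noise has correct first and second moments", {
  n <- 1e5
  cs <- grid_state(matrix(5, 1, 2))
  p <- system_params(temperature = 1, gamma_t = 1, dt = 1,
                     boundary = "none", seed = 21)
  eng <- new_engine(cs, p)
  draws <- with_stream(eng$streams, "engine",
                       matrix(rnorm(2 * n), n, 2))
  mu <- colMeans(draws)
  expect_true(all(abs(mu) < 4 / sqrt(n)))
  cv <- cov(draws)
  expect_equal(diag(cv), c(1, 1), tolerance = 0.05, ignore_attr = TRUE)
  expect_lt(abs(cv[1, 2]), 0.05)
})

test_that("identical seed and config give bit-identical trajectories", {
  run <- function() {
    fx <- make_fixture("chemotaxis-arena", N = 4, seed = 13)
    streams <- rng_streams(13)
    eng <- fx$engine_factory(streams)
    ff <- make_force_function(fx$agents, streams = streams, record = FALSE)
    integrate_system(eng, ff, 5, 5)
  }
  t1 <- run()
  t2 <- run()
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$directors, t2$directors)
})

test_that("orientation decorrelates as exp(-D_r t) for a free 2D particle", {
  fx <- make_fixture("free-diffusion", N = 1500, seed = 31)
  streams <- rng_streams(31)
  eng <- fx$engine_factory(streams)
  traj <- integrate_system(eng, passive_force_function(), 20, 10)
  res <- analyze_orientation_acf(traj, c(4, 10, 20))
  for (r in seq_len(nrow(res))) {
    theory <- exp(-res$lag_time[r])      # D_r = T / gamma_r = 1
    expect_lt(abs(res$acf[r] - theory), 3 * res$se[r])
  }
})
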