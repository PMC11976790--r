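# Force-function routing, classical rules, episode recording.

make_test_field <- function() concentration_field(c(10, 10), 1, 4)

test_that("calc_action routes controlled types and zeroes passive ones", {
  pos <- matrix(runif(10, 2, 8), 5, 2)
  cs <- colloid_state(0:4, c(0L, 0L, 0L, 9L, 9L), pos,
                      matrix(rep(c(1, 0), each = 5), 5, 2))
  set <- default_action_set()
  ag <- swarm_agent(0L, set, observable = obs_position(c(10, 10)),
                    kind = "trainable",
                    policy = biased_policy(2, 4, prefer = 1L))
  ff <- make_force_function(ag, streams = rng_streams(2), record = FALSE)
  acts <- ff$calc_action(cs)
  expect_length(acts, 5)
  # controlled colloids got the stub policy's first action
  for (i in 1:3) expect_equal(acts[[i]]$force, index_to_action(set, 1)$force)
  # passive colloids got zero actions
  for (i in 4:5) {
    expect_equal(acts[[i]]$force, 0)
    expect_equal(acts[[i]]$torque, c(0, 0, 0))
  }
})

test_that("strict mode rejects unknown particle types", {
  cs <- grid_state(matrix(5, 2, 2), type = 3L)
  ag <- swarm_agent(0L, default_action_set(),
                    observable = obs_position(c(10, 10)),
                    policy = biased_policy(2, 4))
  ff <- make_force_function(ag, streams = rng_streams(1), strict = TRUE)
  expect_error(ff$calc_action(cs), "unknown particle type")
})

test_that("mixed trainable and classical agents are routed to the right
           controller", {
  field <- make_test_field()
  pos <- rbind(c(3, 3), c(4, 4), c(12, 10), c(14, 10))
  cs <- colloid_state(0:3, c(0L, 0L, 1L, 1L), pos,
                      matrix(rep(c(1, 0), each = 4), 4, 2))
  set <- default_action_set()
  ag_rl <- swarm_agent(0L, set, observable = obs_position(c(20, 20)),
                       policy = biased_policy(2, 4, prefer = 4L))
  # instrumented classical rule: records which colloids it served
  served <- integer(0)
  rule <- function(colloids, self) {
    served <<- c(served, colloids$id[self])
    action(force = 99)
  }
  ag_cl <- swarm_agent(1L, set, kind = "classical", rule = rule)
  ff <- make_force_function(list(ag_rl, ag_cl), streams = rng_streams(3),
                            record = FALSE)
  acts <- ff$calc_action(cs)
  expect_equal(sort(served), c(2L, 3L))
  expect_equal(acts[[3]]$force, 99)
  expect_equal(acts[[4]]$force, 99)
  expect_equal(acts[[1]]$force, 0)     # do_nothing from the biased policy
})

test_that("calc_action does not mutate the colloid list it receives", {
  cs <- grid_state(matrix(runif(8, 2, 8), 4, 2))
  snapshot <- as.data.frame(cs)
  ag <- swarm_agent(0L, default_action_set(),
                    observable = obs_position(c(10, 10)),
                    policy = biased_policy(2, 4))
  ff <- make_force_function(ag, streams = rng_streams(5), record = FALSE)
  ff$calc_action(cs)
  expect_identical(as.data.frame(cs), snapshot)
})

test_that("frozen policy and fixed streams reproduce identical action
           sequences", {
  run_once <- function() {
    set.seed(40)
    pol <- policy_network(2, 4, hidden = c(8))
    ag <- swarm_agent(0L, default_action_set(),
                      observable = obs_position(c(10, 10)), policy = pol)
    ff <- make_force_function(ag, streams = rng_streams(17), record = TRUE)
    cs <- grid_state(matrix(runif(12, 2, 8), 6, 2))
    for (k in 1:5) ff$calc_action(cs)
    unlist(ff$buffers[[1]]$idx)
  }
  expect_identical(run_once(), run_once())
})

test_that("episode buffers record log-probabilities and lagged rewards", {
  field <- make_test_field()
  set <- default_action_set()
  ag <- swarm_agent(0L, set,
                    observable = obs_concentration_change(field, scale = 1),
                    task = task_gradient_climb(field, scale = 1),
                    policy = biased_policy(1, 4, prefer = 1L))
  ff <- make_force_function(ag, streams = rng_streams(7), record = TRUE)
  cs1 <- grid_state(rbind(c(5, 10), c(6, 10)))
  cs2 <- grid_state(rbind(c(6, 10), c(7, 10)))   # both moved up-gradient
  ff$calc_action(cs1)
  ff$calc_action(cs2)
  ff$finalize(cs2)
  b <- ff$buffers[[1]]
  expect_length(b$idx, 2)
  expect_true(all(unlist(b$logp) <= 0))
  # reward recorded at slice 2 belongs to the slice-1 action and is the
  # positive concentration gain
  gain <- field_value(field, c(6, 10)) - field_value(field, c(5, 10))
  expect_equal(b$reward[[1]][1], gain, tolerance = 1e-12)
  expect_equal(b$reward[[2]], c(0, 0))  # finalize saw no further motion
})

test_that("steer-to-gradient rule turns toward the source and translates
           when aligned", {
  field <- make_test_field()
  set <- default_action_set()
  rule <- classical_steer_to_gradient(field, set, tol = 0.2)
  # director already pointing at the source -> translate
  cs <- colloid_state(0L, 0L, matrix(c(5, 10), 1), matrix(c(1, 0), 1))
  expect_equal(rule(cs, 1)$force, index_to_action(set, 1)$force)
  # source 90 degrees to the left -> counterclockwise torque
  cs <- colloid_state(0L, 0L, matrix(c(10, 5), 1), matrix(c(1, 0), 1))
  expect_gt(rule(cs, 1)$torque[3], 0)
  # source to the right -> clockwise
  cs <- colloid_state(0L, 0L, matrix(c(10, 15), 1), matrix(c(1, 0), 1))
  expect_lt(rule(cs, 1)$torque[3], 0)
})

test_that("the classical rule weakly increases alignment over a noise-free
           slice", {
  field <- make_test_field()
  # tau0 chosen so one slice rotates by at most the tolerance angle: the
  # rule can then never overshoot past the uphill direction
  set <- default_action_set(f0 = 5, tau0 = 2)
  rule <- classical_steer_to_gradient(field, set, tol = 0.2)
  ag <- swarm_agent(0L, set, kind = "classical", rule = rule)
  p <- system_params(temperature = 0, dt = 0.02, box = c(20, 20),
                     boundary = "reflective")
  bearing <- function(pos, e) {
    g <- field$source - pos
    abs(atan2(e[1] * g[2] - e[2] * g[1], sum(e * g)))
  }
  set.seed(12)
  for (i in 1:20) {
    pos <- matrix(runif(2, 2, 18), 1)
    # exclude starts so close to the source that a translating particle
    # overshoots it within one slice
    if (sqrt(sum((pos - field$source)^2)) < 1.5) next
    th <- runif(1, 0, 2 * pi)
    e0 <- c(cos(th), sin(th))
    cs <- colloid_state(0L, 0L, pos, matrix(e0, 1))
    chosen <- rule(cs, 1)
    before <- bearing(pos, e0)
    eng <- new_engine(cs, p)
    ff <- make_force_function(ag, streams = rng_streams(i), record = FALSE)
    integrate_system(eng, ff, 1, 5)
    out <- get_particle_data(eng)
    after <- bearing(colloid_positions(out)[1, ],
                     colloid_directors(out)[1, ])
    if (chosen$force == 0) {
      # a rotation action strictly reduces the misalignment angle
      expect_lt(after, before)
    } else {
      # translation is only chosen when already aligned within tolerance,
      # and the bearing stays near-aligned over a single slice
      expect_lte(before, 0.2 + 1e-12)
      expect_lte(after, 0.35)
    }
  }
})
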