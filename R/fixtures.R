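#' Synthetic test systems (fixtures)
#'
#' Reproducible desk-scale systems used throughout the test suite and as
#' starting points for user runs. Given a scenario name, particle count and
#' seed, `make_fixture` returns everything a trainer needs: an engine
#' factory (drawing initial conditions from the "init" RNG stream so runs
#' are fully determined by the seed), agent declarations, sensible trainer
#' defaults and a terminal evaluation metric.
#'
#' Scenarios:
#' \describe{
#'   \item{free-diffusion}{N passive particles, no interactions, unbounded;
#'     validates the diffusive limit MSD = 2 d D_t t.}
#'   \item{abp-gas}{N active Brownian particles with constant propulsion and
#'     no steering (a classical always-translate agent); validates the
#'     active MSD closed form.}
#'   \item{chemotaxis-arena}{A Gaussian chemoattractant field in a
#'     reflective box with N trainable agents using the 4-action set, a
#'     concentration-change observable and the positive-gain chemotaxis
#'     reward.}
#'   \item{rod-arena}{A rigid bead-chain rod plus N pusher agents rewarded
#'     for rotating it.}
#'   \item{bandit}{A 2-armed bandit stub engine with rewards fixed per
#'     action (arm 1 pays 1, arm 2 pays 0); validates the RL mathematics
#'     end to end.}
#' }
#'
#' @param scenario scenario name (see Details).
#' @param N number of controlled particles.
#' @param seed master seed; fully determines the generated system.
#' @param ... scenario parameter overrides (see the individual builders).
#' @return a list of class `swarm_fixture` with elements `engine_factory`,
#'   `agents`, `params`, `trainer_defaults`, `metric_fn`, `field` (where
#'   applicable) and `config` (a serializable description).
#' @export
make_fixture <- function(scenario = c("free-diffusion", "abp-gas",
                                      "chemotaxis-arena", "rod-arena",
                                      "bandit"),
                         N = 100, seed = 1, ...) {
  scenario <- match.arg(scenario)
  # network initialization and any other construction-time randomness is
  # derived from the fixture seed, so fixture generation is a pure function
  # of (scenario, N, seed, ...)
  old_seed <- get_rseed()
  on.exit(set_rseed(old_seed))
  set.seed((abs(as.integer(seed)) + 77003L) %% 2147483647L)
  fx <- switch(scenario,
    "free-diffusion" = fixture_free_diffusion(N, seed, ...),
    "abp-gas" = fixture_abp_gas(N, seed, ...),
    "chemotaxis-arena" = fixture_chemotaxis(N, seed, ...),
    "rod-arena" = fixture_rod_arena(N, seed, ...),
    "bandit" = fixture_bandit(seed, ...)
  )
  fx$scenario <- scenario
  fx$seed <- seed
  class(fx) <- "swarm_fixture"
  fx
}

#' @export
print.swarm_fixture <- function(x, ...) {
  cat("<swarm_fixture> ", x$scenario, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

random_state <- function(N, box, d, margin = 0) {
  pos <- matrix(stats::runif(N * d), N, d)
  pos <- sweep(pos, 2, box - 2 * margin, "*") + margin
  if (d == 2) {
    th <- stats::runif(N, 0, 2 * pi)
    dirs <- cbind(cos(th), sin(th))
  } else {
    z <- stats::runif(N, -1, 1)
    phi <- stats::runif(N, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    dirs <- cbind(s * cos(phi), s * sin(phi), z)
  }
  colloid_state(seq_len(N) - 1L, rep(0L, N), pos, dirs)
}

fixture_free_diffusion <- function(N, seed, temperature = 1, gamma_t = 1,
                                   gamma_r = 1, dt = 0.005) {
  params <- system_params(dimension = 2, box = c(50, 50),
                          temperature = temperature, gamma_t = gamma_t,
                          gamma_r = gamma_r, dt = dt, boundary = "none",
                          seed = seed)
  factory <- function(streams) {
    init <- with_stream(streams, "init",
                        random_state(N, params$box, 2))
    new_engine(init, params, streams = streams)
  }
  list(engine_factory = factory, agents = list(), params = params,
       trainer_defaults = trainer_config(n_slices = 30, steps_per_slice = 10,
                                         seed = seed),
       metric_fn = NULL,
       config = list(scenario = "free-diffusion", N = N, seed = seed,
                     system = params_to_list(params)))
}

fixture_abp_gas <- function(N, seed, f_act = 5, temperature = 1,
                            gamma_t = 1, gamma_r = 1, dt = 0.005) {
  params <- system_params(dimension = 2, box = c(50, 50),
                          temperature = temperature, gamma_t = gamma_t,
                          gamma_r = gamma_r, dt = dt, boundary = "none",
                          seed = seed)
  set <- action_set(propel = action(force = f_act))
  agent <- swarm_agent(0L, set, kind = "classical",
                       rule = function(colloids, self)
                         index_to_action(set, 1L))
  factory <- function(streams) {
    init <- with_stream(streams, "init", random_state(N, params$box, 2))
    new_engine(init, params, streams = streams)
  }
  list(engine_factory = factory, agents = list(agent), params = params,
       trainer_defaults = trainer_config(n_slices = 100,
                                         steps_per_slice = 20, seed = seed),
       metric_fn = NULL, f_act = f_act,
       config = list(scenario = "abp-gas", N = N, seed = seed,
                     f_act = f_act, system = params_to_list(params)))
}

fixture_chemotaxis <- function(N = 10, seed = 1, box = c(20, 20),
                               temperature = 0.1, gamma_t = 1, gamma_r = 1,
                               dt = 0.01, f0 = 10, tau0 = 15,
                               sigma_c = 4, c0 = 1,
                               obs_scale = 30, reward_scale = 10,
                               hidden = c(64, 64), eta = 1e-3,
                               algorithm = "vpg", margin = 4) {
  params <- system_params(dimension = 2, box = box,
                          temperature = temperature, gamma_t = gamma_t,
                          gamma_r = gamma_r, dt = dt,
                          boundary = "reflective", seed = seed)
  field <- concentration_field(box / 2, c0 = c0, sigma = sigma_c)
  set <- default_action_set(f0 = f0, tau0 = tau0)
  obs <- obs_concentration_change(field, scale = obs_scale)
  task <- task_gradient_climb(field, scale = reward_scale, clip = TRUE)
  agent <- swarm_agent(0L, set, observable = obs, task = task,
                       kind = "trainable", hidden = hidden,
                       variant = "shared",
                       hyperparams = training_hyperparams(
                         gamma = 0.9, eta = eta, algorithm = algorithm,
                         entropy_coef = 0.01,
                         standardize_advantages = TRUE))
  factory <- function(streams) {
    init <- with_stream(streams, "init",
                        random_state(N, params$box, 2, margin = margin))
    new_engine(init, params, streams = streams)
  }
  metric_fn <- function(engine) mean(field_value(field, engine$pos))
  list(engine_factory = factory, agents = list(agent), params = params,
       field = field,
       trainer_defaults = trainer_config(mode = "episodic",
                                         n_episodes = 300, n_slices = 20,
                                         steps_per_slice = 5, seed = seed),
       metric_fn = metric_fn,
       config = list(scenario = "chemotaxis-arena", N = N, seed = seed,
                     sigma_c = sigma_c, c0 = c0, f0 = f0, tau0 = tau0,
                     obs_scale = obs_scale, reward_scale = reward_scale,
                     system = params_to_list(params)))
}

fixture_rod_arena <- function(N = 6, seed = 1, box = c(20, 20),
                              n_beads = 7, bead_spacing = 1.0,
                              temperature = 0.05, dt = 0.002,
                              f0 = 10, tau0 = 15, hidden = c(32, 32)) {
  params <- system_params(dimension = 2, box = box,
                          temperature = temperature, gamma_t = 1,
                          gamma_r = 1, dt = dt, boundary = "reflective",
                          interactions = list(kind = "wca", eps = 1,
                                              sigma = 1),
                          seed = seed)
  rod_ids <- N + seq_len(n_beads) - 1L
  set <- default_action_set(f0 = f0, tau0 = tau0)
  task <- task_rod_rotation(rod_ids, scale = 1,
                            slice_dt = dt * 10, direction = 1)
  obs <- multi_sensing(list(obs_position(box),
                            obs_neighbour_count(radius = 3)))
  agent <- swarm_agent(0L, set, observable = obs, task = task,
                       kind = "trainable", hidden = hidden,
                       hyperparams = training_hyperparams(gamma = 0.95))
  factory <- function(streams) {
    ctr <- box / 2
    bead_pos <- cbind(ctr[1] + (seq_len(n_beads) -
                                  (n_beads + 1) / 2) * bead_spacing,
                      rep(ctr[2], n_beads))
    pushers <- with_stream(streams, "init", {
      th <- stats::runif(N, 0, 2 * pi)
      rr <- 4 + stats::runif(N, 0, 2)
      list(pos = cbind(ctr[1] + rr * cos(th), ctr[2] + rr * sin(th)),
           ang = stats::runif(N, 0, 2 * pi))
    })
    pos <- rbind(pushers$pos, bead_pos)
    dirs <- rbind(cbind(cos(pushers$ang), sin(pushers$ang)),
                  matrix(rep(c(1, 0), each = n_beads), n_beads, 2))
    init <- colloid_state(c(seq_len(N) - 1L, rod_ids),
                          c(rep(0L, N), rep(1L, n_beads)), pos, dirs,
                          radius = 0.5)
    new_engine(init, params, streams = streams,
               rigid_bodies = list(list(ids = rod_ids,
                                        gamma_t = n_beads,
                                        gamma_r = 2 * n_beads)))
  }
  metric_fn <- function(engine) {
    rix <- match(rod_ids, engine$ids)
    axis <- engine$pos[rix[length(rix)], ] - engine$pos[rix[1], ]
    atan2(axis[2], axis[1])
  }
  list(engine_factory = factory, agents = list(agent), params = params,
       rod_ids = rod_ids,
       trainer_defaults = trainer_config(n_episodes = 50, n_slices = 20,
                                         steps_per_slice = 10, seed = seed),
       metric_fn = metric_fn,
       config = list(scenario = "rod-arena", N = N, seed = seed,
                     n_beads = n_beads, system = params_to_list(params)))
}

# ---- bandit stub engine -----------------------------------------------------

# A 2-state environment whose "position" x encodes the last arm pulled;
# rewards are looked up from a fixed table by the bandit task.
fixture_bandit <- function(seed = 1, reward_table = c(1, 0),
                           eta = 0.05, algorithm = "vpg") {
  n_arms <- length(reward_table)
  acts <- lapply(seq_len(n_arms) - 1, function(k) action(force = k))
  names(acts) <- paste0("arm", seq_len(n_arms))
  set <- action_set(acts)
  obs <- constant_observable()
  task <- bandit_task(reward_table)
  agent <- swarm_agent(0L, set, observable = obs, task = task,
                       kind = "trainable", hidden = c(16,  16),
                       variant = "shared",
                       hyperparams = training_hyperparams(
                         gamma = 0.99, eta = eta, algorithm = algorithm,
                         optimizer = "sgd", entropy_coef = 0,
                         standardize_advantages = FALSE))
  factory <- function(streams) bandit_engine()
  list(engine_factory = factory, agents = list(agent), params = NULL,
       reward_table = reward_table,
       trainer_defaults = trainer_config(mode = "episodic",
                                         n_episodes = 500, n_slices = 1,
                                         steps_per_slice = 1, seed = seed),
       metric_fn = NULL,
       config = list(scenario = "bandit", seed = seed,
                     reward_table = reward_table))
}

constant_observable <- function() {
  ob <- new.env(parent = emptyenv())
  ob$dim <- 1L
  ob$kind <- "constant"
  ob$compute <- function(colloids, idx) matrix(1, length(idx), 1)
  ob$reset <- function() invisible(NULL)
  class(ob) <- "swarm_observable"
  ob
}

bandit_task <- function(reward_table) {
  tk <- new.env(parent = emptyenv())
  tk$kind <- "bandit-table"
  tk$killed <- FALSE
  tk$call <- function(colloids, idx) {
    arm <- round(colloids$x[idx]) + 1
    ifelse(arm >= 1 & arm <= length(reward_table),
           reward_table[pmax(pmin(arm, length(reward_table)), 1)], 0)
  }
  tk$kill_switch <- function() tk$killed
  tk$reset <- function() tk$killed <- FALSE
  class(tk) <- "swarm_task"
  tk
}

#' @export
get_particle_data.bandit_engine <- function(engine) {
  colloid_state(0L, 0L, matrix(c(engine$x, 0), 1, 2),
                matrix(c(1, 0), 1, 2))
}

#' @export
integrate_system.bandit_engine <- function(engine, force_function, n_slices,
                                           steps_per_slice) {
  ff <- force_function
  for (s in seq_len(n_slices)) {
    actions <- ff$calc_action(get_particle_data(engine))
    engine$x <- actions[[1]]$force      # arm index encoded in the force
    engine$slice <- engine$slice + 1L
    if (!is.null(ff$kill_switch) && isTRUE(ff$kill_switch())) break
  }
  invisible(NULL)
}

#' @export
reset_engine.bandit_engine <- function(engine, colloids) {
  engine$x <- 0
  engine$slice <- 0L
  invisible(engine)
}

bandit_engine <- function() {
  eng <- new.env(parent = emptyenv())
  eng$x <- 0
  eng$slice <- 0L
  class(eng) <- "bandit_engine"
  eng
}
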