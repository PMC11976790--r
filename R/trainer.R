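#' Trainer configuration
#'
#' @param mode "episodic" (fresh environment every episode), "semi-episodic"
#'   (update every episode, environment reset only every `reset_after`
#'   episodes or on a task-triggered kill), or "continuous" (one persistent
#'   environment, update every `update_every` slices).
#' @param n_episodes number of training episodes (episodic modes).
#' @param n_slices control slices per episode.
#' @param steps_per_slice inner integration steps per slice.
#' @param reset_after environment reset cadence, in episodes (semi-episodic).
#' @param slice_budget total slice budget (continuous mode).
#' @param update_every slices between updates (continuous mode).
#' @param checkpoint_every write a checkpoint every this many episodes
#'   (NULL disables).
#' @param checkpoint_file path for periodic checkpoints.
#' @param seed master seed for all trainer RNG streams.
#' @return a list of class `trainer_config`.
#' @export
trainer_config <- function(mode = c("episodic", "semi-episodic",
                                    "continuous"),
                           n_episodes = 100, n_slices = 20,
                           steps_per_slice = 10, reset_after = 1,
                           slice_budget = 1000, update_every = 20,
                           checkpoint_every = NULL, checkpoint_file = NULL,
                           seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_episodes >= 1, n_slices >= 1, steps_per_slice >= 1,
            reset_after >= 1, update_every >= 1)
  structure(list(mode = mode, n_episodes = as.integer(n_episodes),
                 n_slices = as.integer(n_slices),
                 steps_per_slice = as.integer(steps_per_slice),
                 reset_after = as.integer(reset_after),
                 slice_budget = as.integer(slice_budget),
                 update_every = as.integer(update_every),
                 checkpoint_every = checkpoint_every,
                 checkpoint_file = checkpoint_file,
                 seed = as.integer(seed)),
            class = "trainer_config")
}

update_agents <- function(agents, buffers, episode, metrics) {
  for (ai in seq_along(agents)) {
    a <- agents[[ai]]
    if (a$kind != "trainable" || is.null(a$task)) next
    batch <- collect_batch(buffers[[ai]])
    if (is.null(batch)) next
    diag <- policy_update(a$policy, batch$X, batch$a_idx,
                          batch$rewards_list, a$hyperparams)
    metrics[[length(metrics) + 1]] <- data.frame(
      episode = episode, agent_type = a$particle_type,
      mean_reward = mean(unlist(batch$rewards_list)),
      mean_return = diag$mean_return,
      actor_loss = diag$actor_loss, critic_loss = diag$critic_loss,
      entropy = diag$entropy, n_steps = batch$T_, n_particles = batch$n)
  }
  metrics
}

#' Episodic / semi-episodic training
#'
#' For each episode the environment is (re)built from the factory according
#' to the reset rule, run for the episode's slices (ending early if a task's
#' kill switch fires), the episode buffers are assembled, returns and
#' advantages computed, and one actor-critic update per trainable agent
#' performed. In episodic mode every episode gets a fresh environment; in
#' semi-episodic mode updates happen every episode but the environment is
#' only rebuilt after every `reset_after` episodes (or after a kill).
#'
#' @param engine_factory `function(streams)` returning a fresh, initialized
#'   engine; it should draw any random initial conditions from the "init"
#'   stream of `streams` so runs are reproducible and resumable.
#' @param agents a list of [swarm_agent()]s (updated in place).
#' @param config a [trainer_config()].
#' @param streams optional [rng_streams()]; defaults to streams derived from
#'   `config$seed`.
#' @return `list(agents, metrics, factory_calls, episode_slices, streams)`;
#'   `metrics` has one row per update and agent.
#' @export
train_episodic <- function(engine_factory, agents, config, streams = NULL) {
  stopifnot(inherits(config, "trainer_config"))
  if (inherits(agents, "swarm_agent")) agents <- list(agents)
  if (is.null(streams)) streams <- rng_streams(config$seed)
  semi <- config$mode == "semi-episodic"
  ff <- make_force_function(agents, streams = streams, record = TRUE)
  metrics <- list()
  factory_calls <- 0L
  episode_slices <- integer(0)
  engine <- NULL
  for (ep in seq_len(config$n_episodes)) {
    if (is.null(engine)) {
      engine <- engine_factory(streams)
      factory_calls <- factory_calls + 1L
    }
    ff$reset_episode()
    integrate_system(engine, ff, config$n_slices, config$steps_per_slice)
    ff$finalize(get_particle_data(engine))
    killed <- ff$kill_switch()
    episode_slices <- c(episode_slices, ff$slice)
    metrics <- update_agents(agents, ff$buffers, ep, metrics)
    if (!is.null(config$checkpoint_every) &&
        ep %% config$checkpoint_every == 0 &&
        !is.null(config$checkpoint_file)) {
      save_checkpoint(agents, streams, config$checkpoint_file,
                      extra = list(episode = ep))
    }
    # reset rule for the next episode
    if (!semi || killed || ep %% config$reset_after == 0) {
      engine <- NULL
      if (semi && ep %% config$reset_after == 0 && ep < config$n_episodes + 1) {
        engine <- engine_factory(streams)
        factory_calls <- factory_calls + 1L
      }
    } else {
      reset_engine(engine, get_particle_data(engine))
    }
  }
  list(agents = agents, metrics = do.call(rbind, metrics),
       factory_calls = factory_calls, episode_slices = episode_slices,
       streams = streams)
}

#' Continuous training
#'
#' Runs one persistent engine up to `slice_budget` slices, performing an
#' actor-critic update every `update_every` slices without resetting the
#' environment. If a task raises its kill switch, training ends (it does not
#' reset); an incomplete final block is discarded.
#'
#' @param engine a persistent engine.
#' @param agents list of [swarm_agent()]s.
#' @param config a [trainer_config()] with mode "continuous".
#' @param streams optional [rng_streams()].
#' @return `list(agents, metrics, slices_run, ended_by_kill, streams)`.
#' @export
train_continuous <- function(engine, agents, config, streams = NULL) {
  stopifnot(inherits(config, "trainer_config"))
  if (inherits(agents, "swarm_agent")) agents <- list(agents)
  if (is.null(streams)) streams <- rng_streams(config$seed)
  ff <- make_force_function(agents, streams = streams, record = TRUE)
  metrics <- list()
  slices_run <- 0L
  update_no <- 0L
  ended_by_kill <- FALSE
  n_blocks <- config$slice_budget %/% config$update_every
  for (blk in seq_len(n_blocks)) {
    ff$clear_buffers()
    before <- engine$slice
    integrate_system(engine, ff, config$update_every,
                     config$steps_per_slice)
    done <- engine$slice - before
    slices_run <- slices_run + done
    if (done < config$update_every) {     # killed mid-block: discard
      ended_by_kill <- TRUE
      break
    }
    ff$finalize(get_particle_data(engine))
    update_no <- update_no + 1L
    metrics <- update_agents(agents, ff$buffers, update_no, metrics)
    if (ff$kill_switch()) {
      ended_by_kill <- TRUE
      break
    }
  }
  list(agents = agents, metrics = do.call(rbind, metrics),
       slices_run = slices_run, ended_by_kill = ended_by_kill,
       streams = streams)
}

#' Frozen-policy evaluation rollouts
#'
#' Runs `n_runs` rollouts with frozen parameters (greedy argmax or sampled
#' actions, flagged) and returns the mean and standard error of the episode
#' reward plus an optional task-specific terminal metric.
#'
#' @param engine_factory `function(streams)` returning a fresh engine.
#' @param agents list of [swarm_agent()]s (not modified).
#' @param n_runs number of rollouts.
#' @param seed seed for the evaluation streams.
#' @param n_slices,steps_per_slice episode geometry.
#' @param greedy use argmax actions instead of sampling?
#' @param metric_fn optional `function(engine)` evaluated after each rollout
#'   (e.g. mean sensed concentration at the final snapshot).
#' @return `list(mean_reward, se_reward, rewards, metric, metric_values)`.
#' @export
evaluate_policy <- function(engine_factory, agents, n_runs = 10, seed = 1,
                            n_slices = 20, steps_per_slice = 10,
                            greedy = FALSE, metric_fn = NULL) {
  if (inherits(agents, "swarm_agent")) agents <- list(agents)
  streams <- rng_streams(seed)
  rewards <- numeric(n_runs)
  metric_values <- if (is.null(metric_fn)) NULL else numeric(n_runs)
  for (run in seq_len(n_runs)) {
    ff <- make_force_function(agents, streams = streams, record = TRUE,
                              greedy = greedy)
    engine <- engine_factory(streams)
    integrate_system(engine, ff, n_slices, steps_per_slice)
    ff$finalize(get_particle_data(engine))
    tot <- 0
    for (b in ff$buffers) if (length(b$reward)) tot <- tot + sum(unlist(b$reward))
    rewards[run] <- tot
    if (!is.null(metric_fn)) metric_values[run] <- metric_fn(engine)
    for (a in agents) {
      if (!is.null(a$task)) a$task$reset()
      if (!is.null(a$observable)) a$observable$reset()
    }
  }
  list(mean_reward = mean(rewards),
       se_reward = stats::sd(rewards) / sqrt(n_runs),
       rewards = rewards,
       metric = if (is.null(metric_fn)) NULL else mean(metric_values),
       metric_values = metric_values)
}
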