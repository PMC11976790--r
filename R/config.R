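#' Run configuration documents
#'
#' A run is described by a single YAML (or JSON) document with a `fixture`
#' block naming a scenario from [make_fixture()] plus parameter overrides,
#' an optional `trainer` block overriding [trainer_config()] fields, and an
#' optional `simulate` block (slices and steps per slice for plain
#' simulation runs). Fixtures serialize to this same schema, so any
#' generated system can be re-run from its config file.
#'
#' @param file path to a YAML or JSON config.
#' @return the validated configuration list.
#' @export
read_config <- function(file) {
  cfg <- if (grepl("\\.json$", file)) jsonlite::read_json(file,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(file)
  validate_config(cfg)
}

#' @param cfg a configuration list.
#' @rdname read_config
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$fixture) || is.null(cfg$fixture$scenario))
    stop("config must contain a fixture block with a scenario name")
  sc <- cfg$fixture$scenario
  ok <- c("free-diffusion", "abp-gas", "chemotaxis-arena", "rod-arena",
          "bandit")
  if (!sc %in% ok)
    stop("unknown scenario '", sc, "'; valid: ", paste(ok, collapse = ", "))
  if (!is.null(cfg$trainer$mode) &&
      !cfg$trainer$mode %in% c("episodic", "semi-episodic", "continuous"))
    stop("invalid trainer mode")
  for (f in c("n_episodes", "n_slices", "steps_per_slice", "reset_after"))
    if (!is.null(cfg$trainer[[f]]) && cfg$trainer[[f]] < 1)
      stop("trainer field ", f, " must be >= 1")
  cfg
}

config_fixture <- function(cfg) {
  fb <- cfg$fixture
  builder <- switch(fb$scenario,
    "free-diffusion" = fixture_free_diffusion,
    "abp-gas" = fixture_abp_gas,
    "chemotaxis-arena" = fixture_chemotaxis,
    "rod-arena" = fixture_rod_arena,
    "bandit" = fixture_bandit)
  keep <- intersect(names(fb), names(formals(builder)))
  args <- fb[keep]
  if ("box" %in% names(args)) args$box <- as.numeric(unlist(args$box))
  do.call(make_fixture, c(list(scenario = fb$scenario), args))
}

config_trainer <- function(cfg, fx) {
  tc <- fx$trainer_defaults
  for (f in names(cfg$trainer)) tc[[f]] <- cfg$trainer[[f]]
  class(tc) <- "trainer_config"
  tc
}

#' Run a plain simulation from a config
#'
#' Builds the fixture, runs the engine under the declared (classical or
#' passive) agents, and writes the trajectory.
#'
#' @param cfg configuration list (see [read_config()]).
#' @param out output trajectory path (JSON).
#' @return the [trajectory_record()], invisibly.
#' @export
run_simulate <- function(cfg, out = NULL) {
  fx <- config_fixture(cfg)
  if (fx$scenario == "bandit") stop("the bandit fixture has no simulation")
  streams <- rng_streams(fx$seed)
  engine <- fx$engine_factory(streams)
  ff <- if (length(fx$agents)) {
    make_force_function(fx$agents, streams = streams, record = FALSE)
  } else passive_force_function()
  n_slices <- cfg$simulate$n_slices %||% fx$trainer_defaults$n_slices
  sps <- cfg$simulate$steps_per_slice %||% fx$trainer_defaults$steps_per_slice
  traj <- integrate_system(engine, ff, n_slices, sps)
  if (!is.null(out)) write_trajectory(traj, out)
  invisible(traj)
}

#' Train agents from a config
#'
#' @param cfg configuration list.
#' @param out_dir output directory for `metrics.csv` and `checkpoint.json`
#'   (NULL to skip writing).
#' @return the training result list (see [train_episodic()]).
#' @export
run_train <- function(cfg, out_dir = NULL) {
  fx <- config_fixture(cfg)
  if (!length(fx$agents)) stop("fixture declares no agents to train")
  tc <- config_trainer(cfg, fx)
  res <- if (tc$mode == "continuous") {
    streams <- rng_streams(tc$seed)
    train_continuous(fx$engine_factory(streams), fx$agents, tc,
                     streams = streams)
  } else {
    train_episodic(fx$engine_factory, fx$agents, tc)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    save_checkpoint(fx$agents, res$streams,
                    file.path(out_dir, "checkpoint.json"),
                    extra = list(scenario = fx$scenario, seed = fx$seed))
  }
  res
}

#' Evaluate a (possibly checkpointed) policy from a config
#'
#' @param cfg configuration list.
#' @param checkpoint optional checkpoint path restored before evaluation.
#' @param n_runs number of frozen-policy rollouts.
#' @param seed evaluation seed.
#' @param greedy argmax actions instead of sampling?
#' @return the summary list from [evaluate_policy()].
#' @export
run_evaluate <- function(cfg, checkpoint = NULL, n_runs = 20, seed = 1,
                         greedy = FALSE) {
  fx <- config_fixture(cfg)
  if (!length(fx$agents)) stop("fixture declares no agents to evaluate")
  if (!is.null(checkpoint)) load_checkpoint(checkpoint, fx$agents)
  evaluate_policy(fx$engine_factory, fx$agents, n_runs = n_runs,
                  seed = seed,
                  n_slices = fx$trainer_defaults$n_slices,
                  steps_per_slice = fx$trainer_defaults$steps_per_slice,
                  greedy = greedy, metric_fn = fx$metric_fn)
}

#' Write a fixture's config document
#'
#' @param fx a fixture from [make_fixture()].
#' @param file output YAML path.
#' @return the path, invisibly.
#' @export
write_fixture_config <- function(fx, file) {
  yaml::write_yaml(list(fixture = fx$config), file)
  invisible(file)
}
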