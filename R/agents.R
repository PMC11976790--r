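#' Agent declarations
#'
#' An agent bundles the full sensing/control/objective stack for one particle
#' type: its action set, observable, task, and either a trainable
#' actor-critic policy or a classical (rule-based) controller. Each particle
#' type may be controlled by at most one agent; types with no agent are
#' passive and receive zero actions.
#'
#' @param particle_type integer type label this agent controls.
#' @param action_set an [action_set()].
#' @param observable a `swarm_observable` (required for trainable agents).
#' @param task a `swarm_task` providing rewards and the kill switch (optional
#'   for classical agents).
#' @param kind "trainable" (actor-critic) or "classical".
#' @param policy a [policy_network()]; built automatically from the
#'   observable dimension and action-set size when omitted.
#' @param hidden,variant network architecture used when `policy` is omitted.
#' @param hyperparams a [training_hyperparams()].
#' @param sampling "categorical" or "gumbel" action sampling.
#' @param rule for classical agents: `function(colloids, self)` returning a
#'   [action()] for the colloid in row `self`.
#' @param exploration optional `list(zeta = , eps = , T_ep = )` random
#'   exploration with decay; NULL disables.
#' @param rnd optional [rnd_module()] adding intrinsic novelty rewards.
#' @param reward_aggregation "individual" per-particle rewards or
#'   "team_average" (every particle of the group receives the group mean).
#' @return a list of class `swarm_agent`.
#' @export
swarm_agent <- function(particle_type, action_set, observable = NULL,
                        task = NULL, kind = c("trainable", "classical"),
                        policy = NULL, hidden = c(128, 128),
                        variant = "shared",
                        hyperparams = training_hyperparams(),
                        sampling = c("categorical", "gumbel"),
                        rule = NULL, exploration = NULL, rnd = NULL,
                        reward_aggregation = c("individual",
                                               "team_average")) {
  kind <- match.arg(kind)
  sampling <- match.arg(sampling)
  reward_aggregation <- match.arg(reward_aggregation)
  stopifnot(inherits(action_set, "action_set"))
  if (kind == "trainable") {
    if (is.null(observable)) stop("trainable agents require an observable")
    if (is.null(policy))
      policy <- policy_network(observable$dim, length(action_set),
                               hidden = hidden, variant = variant)
    if (policy$input_dim != observable$dim)
      stop("policy input size does not match observable dimension")
    if (policy$n_actions != length(action_set))
      stop("policy output size does not match action set")
  } else {
    if (is.null(rule)) stop("classical agents require a rule")
  }
  structure(list(particle_type = as.integer(particle_type),
                 action_set = action_set, observable = observable,
                 task = task, kind = kind, policy = policy,
                 hyperparams = hyperparams, sampling = sampling,
                 rule = rule, exploration = exploration, rnd = rnd,
                 reward_aggregation = reward_aggregation),
            class = "swarm_agent")
}

#' @export
print.swarm_agent <- function(x, ...) {
  cat("<swarm_agent> type ", x$particle_type, ", ", x$kind, ", ",
      length(x$action_set), " actions\n", sep = "")
  invisible(x)
}

#' Classical steer-to-gradient rule
#'
#' The reference rule-based controller: rotate toward increasing sensed
#' concentration, translate once aligned. The signed angle between the
#' director and the local uphill direction selects counterclockwise rotation
#' when the source lies to the left, clockwise when to the right, and
#' translation when within `tol` radians of alignment. Deterministic.
#'
#' @param field a [concentration_field()] (2D).
#' @param set the agent's [action_set()] (must contain `translate`,
#'   `rotate_clockwise`, `rotate_counterclockwise`).
#' @param tol alignment tolerance in radians.
#' @return a rule function `function(colloids, self)`.
#' @export
classical_steer_to_gradient <- function(field, set, tol = 0.2) {
  force(field); force(set); force(tol)
  function(colloids, self) {
    pos <- as.numeric(colloids[self, c("x", "y")])
    e <- as.numeric(colloids[self, c("ex", "ey")])
    g <- field$source[1:2] - pos        # uphill direction of the gaussian
    if (sum(g^2) == 0) return(index_to_action(set, action_to_index(set, "translate")))
    ang <- atan2(e[1] * g[2] - e[2] * g[1], sum(e * g))
    nm <- if (abs(ang) <= tol) "translate"
    else if (ang > 0) "rotate_counterclockwise"
    else "rotate_clockwise"
    index_to_action(set, action_to_index(set, nm))
  }
}

zero_action <- function() action()

#' Build the force function connecting agents to an engine
#'
#' The force function is the narrow interface through which control code
#' sees the environment. Its `calc_action(colloids)` method routes each
#' particle type to its controlling agent: observables are computed, the
#' policy (or classical rule) is evaluated, actions are sampled and mapped
#' back to [action()] objects; passive types receive zero actions. During
#' training (`record = TRUE`) the per-particle (observable, chosen index,
#' log-probability, value) tuples and task rewards are recorded into episode
#' buffers, with reward \eqn{r_{t+1}} attributed to the action \eqn{a_t}
#' taken one slice earlier; the final action's reward is filled in by
#' `finalize()` after the last slice. `kill_switch()` is the OR over all
#' agent tasks. RNG use: action sampling draws from the "action" stream,
#' exploration from "exploration", RND rehearsal from "rnd".
#'
#' @param agents list of [swarm_agent()]s (distinct particle types).
#' @param streams an [rng_streams()] object.
#' @param record record episode buffers and rewards (training mode)?
#' @param strict error on colloid types with no agent (instead of treating
#'   them as passive)?
#' @param slice_dt duration of one slice (sets the exploration clock).
#' @param greedy take argmax actions instead of sampling (evaluation)?
#' @return an environment of class `force_function`.
#' @export
make_force_function <- function(agents, streams = rng_streams(1),
                                record = TRUE, strict = FALSE,
                                slice_dt = 1, greedy = FALSE) {
  if (inherits(agents, "swarm_agent")) agents <- list(agents)
  types <- vapply(agents, function(a) a$particle_type, integer(1))
  if (anyDuplicated(types))
    stop("each particle type may be controlled by at most one agent")
  ff <- new.env(parent = emptyenv())
  ff$agents <- agents
  ff$streams <- streams
  ff$record <- record
  ff$slice <- 0L          # within-episode slice counter
  ff$global_time <- 0     # cumulative simulation time (exploration clock)
  ff$buffers <- lapply(agents, function(a) new.env(parent = emptyenv()))
  for (b in ff$buffers) {
    b$obs <- list(); b$idx <- list(); b$logp <- list()
    b$value <- list(); b$reward <- list(); b$intrinsic <- list()
  }

  step_rewards <- function(a, colloids, sel, obs) {
    r <- a$task$call(colloids, sel)
    intr <- 0
    if (!is.null(a$rnd)) {
      nov <- rnd_novelty(a$rnd, obs)
      with_stream(ff$streams, "rnd", rnd_update(a$rnd, obs, steps = 1))
      intr <- a$rnd$weight * nov
      r <- r + intr
    }
    if (a$reward_aggregation == "team_average") r <- rep(mean(r), length(r))
    list(reward = r, intrinsic = intr)
  }

  ff$calc_action <- function(colloids) {
    n <- nrow(colloids)
    actions <- replicate(n, zero_action(), simplify = FALSE)
    if (strict) {
      known <- colloids$type %in% types
      if (!all(known))
        stop("unknown particle type(s): ",
             paste(unique(colloids$type[!known]), collapse = ", "))
    }
    k <- ff$slice + 1L
    for (ai in seq_along(ff$agents)) {
      a <- ff$agents[[ai]]
      sel <- which(colloids$type == a$particle_type)
      if (!length(sel)) next
      b <- ff$buffers[[ai]]
      if (a$kind == "classical") {
        for (i in sel) actions[[i]] <- a$rule(colloids, i)
        if (ff$record && !is.null(a$task)) a$task$call(colloids, sel)
        next
      }
      obs <- a$observable$compute(colloids, sel)
      if (ff$record && !is.null(a$task)) {
        rw <- step_rewards(a, colloids, sel, obs)
        if (k > 1L) {
          b$reward[[k - 1L]] <- rw$reward
          b$intrinsic[[k - 1L]] <- rw$intrinsic
        }
      }
      fwd <- policy_forward(a$policy, obs)
      if (greedy) {
        idx <- max.col(fwd$probs, ties.method = "first")
      } else {
        idx <- with_stream(ff$streams, "action",
                           sample_actions_matrix(fwd$probs, a$sampling))
      }
      if (!is.null(a$exploration)) {
        zeta_t <- explore_decay(a$exploration$zeta, a$exploration$eps,
                                ff$global_time, a$exploration$T_ep)
        idx <- with_stream(ff$streams, "exploration",
                           maybe_explore_vec(idx, zeta_t,
                                             length(a$action_set)))
      }
      if (ff$record) {
        b$obs[[k]] <- obs
        b$idx[[k]] <- idx
        b$logp[[k]] <- log_prob_of(fwd$probs, idx)
        b$value[[k]] <- fwd$value
      }
      for (j in seq_along(sel))
        actions[[sel[j]]] <- index_to_action(a$action_set, idx[j])
    }
    ff$slice <- k
    ff$global_time <- ff$global_time + slice_dt
    actions
  }

  ff$kill_switch <- function() {
    any(vapply(ff$agents, function(a) {
      !is.null(a$task) && isTRUE(a$task$kill_switch())
    }, logical(1)))
  }

  # fill in the last action's reward from the post-slice state
  ff$finalize <- function(colloids) {
    k <- ff$slice
    if (k < 1L || !ff$record) return(invisible(NULL))
    for (ai in seq_along(ff$agents)) {
      a <- ff$agents[[ai]]
      if (a$kind != "trainable" || is.null(a$task)) next
      sel <- which(colloids$type == a$particle_type)
      if (!length(sel)) next
      obs <- a$observable$compute(colloids, sel)
      rw <- step_rewards(a, colloids, sel, obs)
      b <- ff$buffers[[ai]]
      b$reward[[k]] <- rw$reward
      b$intrinsic[[k]] <- rw$intrinsic
    }
    invisible(NULL)
  }

  # drop collected data but keep task/observable histories (continuous mode)
  ff$clear_buffers <- function() {
    ff$slice <- 0L
    for (b in ff$buffers) {
      b$obs <- list(); b$idx <- list(); b$logp <- list()
      b$value <- list(); b$reward <- list(); b$intrinsic <- list()
    }
    invisible(NULL)
  }

  # start a new episode: clear buffers, reset tasks/observables; the
  # exploration clock keeps running across episodes
  ff$reset_episode <- function() {
    ff$clear_buffers()
    for (a in ff$agents) {
      if (!is.null(a$task)) a$task$reset()
      if (!is.null(a$observable)) a$observable$reset()
    }
    invisible(NULL)
  }

  class(ff) <- "force_function"
  ff
}

#' A force function applying zero actions to every colloid
#' @return a `force_function` whose kill switch never fires.
#' @export
passive_force_function <- function() {
  ff <- new.env(parent = emptyenv())
  ff$calc_action <- function(colloids) {
    replicate(nrow(colloids), zero_action(), simplify = FALSE)
  }
  ff$kill_switch <- function() FALSE
  ff$finalize <- function(colloids) invisible(NULL)
  ff$reset_episode <- function() invisible(NULL)
  class(ff) <- "force_function"
  ff
}

# Assemble one agent's episode buffer into a pooled, particle-major batch:
# X (sum_T x dim), a_idx, logp, and per-particle reward/value time series.
collect_batch <- function(buffer) {
  T_ <- length(buffer$idx)
  if (T_ == 0) return(NULL)
  n <- length(buffer$idx[[1]])
  dim_ <- ncol(buffer$obs[[1]])
  if (length(buffer$reward) < T_)
    stop("episode buffer incomplete: missing final reward (call finalize)")
  X <- matrix(NA_real_, n * T_, dim_)
  a_idx <- integer(n * T_)
  logp <- numeric(n * T_)
  rewards_list <- vector("list", n)
  for (j in seq_len(n)) {
    rows <- (j - 1) * T_ + seq_len(T_)
    for (t in seq_len(T_)) {
      X[rows[t], ] <- buffer$obs[[t]][j, ]
      a_idx[rows[t]] <- buffer$idx[[t]][j]
      logp[rows[t]] <- buffer$logp[[t]][j]
    }
    rewards_list[[j]] <- vapply(seq_len(T_),
                                function(t) buffer$reward[[t]][j], numeric(1))
  }
  list(X = X, a_idx = a_idx, logp = logp, rewards_list = rewards_list,
       T_ = T_, n = n)
}
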