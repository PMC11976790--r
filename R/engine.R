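#' System parameters for the Langevin engine
#'
#' Collects everything the integrator needs. All quantities are in reduced
#' units with \eqn{k_B = 1}: energies in units of the thermal scale, lengths
#' in particle diameters, friction coefficients set the time scale through
#' \eqn{D_t = k_B T / \gamma_t} and \eqn{D_r = k_B T / \gamma_r}.
#'
#' @param dimension spatial dimension, 2 or 3.
#' @param box numeric box edge lengths (length `dimension`).
#' @param temperature absolute temperature T >= 0 (reduced units, k_B = 1).
#' @param gamma_t translational friction; a single value or a named vector
#'   keyed by particle type label.
#' @param gamma_r rotational friction; same conventions.
#' @param dt integration time step, > 0.
#' @param boundary one of "none" (unbounded), "periodic" (minimum image,
#'   positions wrapped), "reflective" (specular walls).
#' @param interactions `list(kind = "none")` or
#'   `list(kind = "wca", eps = , sigma = )`.
#' @param seed engine RNG seed (recorded in trajectory metadata).
#' @param external_force optional `function(pos_matrix)` returning an n x d
#'   force matrix (e.g. an optical or gravitational field); NULL for none.
#' @return an object of class `system_params`.
#' @export
system_params <- function(dimension = 2, box = c(10, 10), temperature = 1,
                          gamma_t = 1, gamma_r = 1, dt = 0.01,
                          boundary = c("none", "periodic", "reflective"),
                          interactions = list(kind = "none"),
                          seed = 42, external_force = NULL) {
  boundary <- match.arg(boundary)
  stopifnot(dimension %in% c(2, 3), length(box) == dimension, all(box > 0),
            temperature >= 0, all(gamma_t > 0), all(gamma_r > 0), dt > 0)
  if (!interactions$kind %in% c("none", "wca"))
    stop("interactions kind must be 'none' or 'wca'")
  if (interactions$kind == "wca") {
    if (is.null(interactions$eps)) interactions$eps <- 1
    if (is.null(interactions$sigma)) interactions$sigma <- 1
    stopifnot(interactions$eps > 0, interactions$sigma > 0)
  }
  structure(list(dimension = as.integer(dimension), box = as.numeric(box),
                 temperature = temperature, gamma_t = gamma_t,
                 gamma_r = gamma_r, dt = dt, boundary = boundary,
                 interactions = interactions, seed = as.integer(seed),
                 external_force = external_force),
            class = "system_params")
}

per_type_value <- function(val, types) {
  if (length(val) == 1 && is.null(names(val)))
    return(rep(as.numeric(val), length(types)))
  out <- as.numeric(val[as.character(types)])
  if (anyNA(out)) stop("missing friction value for some particle type")
  out
}

#' Create a Langevin dynamics engine
#'
#' The engine owns the particle state and propagates it with the
#' Euler-Maruyama discretization of the overdamped Langevin equations:
#' positions advance by
#' \deqn{\Delta r = \gamma_t^{-1}(F^{act}\hat e + F^{int} + F^{ext})\Delta t
#'   + \sqrt{2 k_B T \gamma_t^{-1} \Delta t}\,\xi,}
#' and in 2D the director angle by
#' \deqn{\Delta\theta = \gamma_r^{-1} M_z \Delta t
#'   + \sqrt{2 k_B T \gamma_r^{-1} \Delta t}\,\xi_r,}
#' with independent standard-normal noise per component and step. Positive
#' torque rotates counterclockwise (the steering direction \eqn{\hat n} is
#' \eqn{\hat e} rotated +90 degrees). In 3D 'the director is rotated by the
#' angular increment vector and renormalized. An action's `new_direction`,
#' when set, overrides the whole rotational update for that slice.
#'
#' @param colloids initial [colloid_state()].
#' @param params a [system_params()].
#' @param streams optional [rng_streams()]; created from `params$seed` if
#'   omitted. The engine draws only from the "engine" stream.
#' @param rigid_bodies optional list of rigid-body specs, each
#'   `list(ids = <colloid ids>, gamma_t = , gamma_r = )`: the listed colloids
#'   move as one rigid unit updated from the net force and torque on its
#'   members (2D only).
#' @return an environment of class `swarm_engine`.
#' @export
new_engine <- function(colloids, params, streams = NULL,
                       rigid_bodies = NULL) {
  stopifnot(inherits(colloids, "colloid_state"),
            inherits(params, "system_params"))
  d <- params$dimension
  if (colloid_dim(colloids) != d) stop("colloid/params dimension mismatch")
  eng <- new.env(parent = emptyenv())
  eng$pos <- colloid_positions(colloids)
  eng$dirs <- colloid_directors(colloids)
  eng$unwrap <- eng$pos
  eng$ids <- colloids$id
  eng$types <- colloids$type
  eng$radius <- colloids$radius
  eng$N <- nrow(colloids)
  eng$d <- d
  eng$params <- params
  eng$gamma_t <- per_type_value(params$gamma_t, colloids$type)
  eng$gamma_r <- per_type_value(params$gamma_r, colloids$type)
  eng$time <- 0
  eng$slice <- 0L
  eng$stats <- list(steps = 0L, action_queries = 0L)
  eng$streams <- if (is.null(streams)) rng_streams(params$seed) else streams
  eng$traj <- new.env(parent = emptyenv())
  eng$traj$time <- list()
  eng$traj$pos <- list()
  eng$traj$unwrap <- list()
  eng$traj$dirs <- list()
  eng$warned_dt <- FALSE
  if (!is.null(rigid_bodies)) {
    if (d != 2) stop("rigid bodies supported in 2D only")
    eng$rigid <- lapply(rigid_bodies, function(rb) {
      idx <- match(rb$ids, eng$ids)
      if (anyNA(idx)) stop("rigid body references unknown colloid id")
      list(idx = idx,
           gamma_t = if (is.null(rb$gamma_t)) length(idx) else rb$gamma_t,
           gamma_r = if (is.null(rb$gamma_r)) length(idx) else rb$gamma_r)
    })
  } else eng$rigid <- NULL
  class(eng) <- "swarm_engine"
  record_snapshot(eng)
  eng
}

record_snapshot <- function(eng) {
  k <- length(eng$traj$time) + 1L
  eng$traj$time[[k]] <- eng$time
  eng$traj$pos[[k]] <- eng$pos
  eng$traj$unwrap[[k]] <- eng$unwrap
  eng$traj$dirs[[k]] <- eng$dirs
  invisible(eng)
}

rotate2 <- function(v, ang) {
  cbind(cos(ang) * v[, 1] - sin(ang) * v[, 2],
        sin(ang) * v[, 1] + cos(ang) * v[, 2])
}

# One Euler-Maruyama step. `am` is the output of actions_to_matrices().
engine_step <- function(eng, am) {
  p <- eng$params
  dt <- p$dt
  N <- eng$N
  d <- eng$d
  # deterministic forces
  f <- am$force * eng$dirs
  if (p$interactions$kind == "wca") {
    f_int <- pair_forces_wca(eng$pos, p$interactions$eps, p$interactions$sigma,
                             box = if (p$boundary == "periodic") p$box else NULL)
    f <- f + f_int
  }
  if (!is.null(p$external_force)) f <- f + p$external_force(eng$pos)
  if (anyNA(f) || any(!is.finite(f)))
    stop("non-finite force encountered: unstable parameters")
  # thermal noise (always drawn, keeping the engine stream aligned across
  # action choices)
  noise <- with_stream(eng$streams, "engine", {
    list(t = matrix(stats::rnorm(N * d), N, d),
         r = if (d == 2) stats::rnorm(N) else matrix(stats::rnorm(N * 3), N, 3))
  })
  inv_gt <- 1 / eng$gamma_t
  disp <- f * (inv_gt * dt) +
    sqrt(2 * p$temperature * inv_gt * dt) * noise$t
  if (p$interactions$kind == "wca" && !eng$warned_dt) {
    if (max(abs(disp)) >= 0.1 * p$interactions$sigma) {
      warning("per-step displacement >= 0.1 sigma; reduce dt for stable WCA")
      eng$warned_dt <- TRUE
    }
  }
  free <- rep(TRUE, N)
  if (!is.null(eng$rigid)) for (rb in eng$rigid) free[rb$idx] <- FALSE

  # rotational update (free particles)
  inv_gr <- 1 / eng$gamma_r
  if (d == 2) {
    dtheta <- am$torque_z * (inv_gr * dt) +
      sqrt(2 * p$temperature * inv_gr * dt) * noise$r
    newdirs <- rotate2(eng$dirs, dtheta)
  } else {
    dphi <- am$torque3 * (inv_gr * dt) +
      sqrt(2 * p$temperature * inv_gr * dt) * noise$r
    # e' = e + dphi x e, renormalized (small-rotation Euler update)
    e <- eng$dirs
    cr <- cbind(dphi[, 2] * e[, 3] - dphi[, 3] * e[, 2],
                dphi[, 3] * e[, 1] - dphi[, 1] * e[, 3],
                dphi[, 1] * e[, 2] - dphi[, 2] * e[, 1])
    newdirs <- e + cr
  }
  # direction override takes precedence over the torque update
  ov <- which(!is.na(am$new_dir[, 1]))
  if (length(ov)) newdirs[ov, ] <- am$new_dir[ov, , drop = FALSE]
  nrm <- sqrt(rowSums(newdirs^2))
  newdirs <- newdirs / nrm

  eng$pos[free, ] <- eng$pos[free, , drop = FALSE] + disp[free, , drop = FALSE]
  eng$unwrap[free, ] <- eng$unwrap[free, , drop = FALSE] +
    disp[free, , drop = FALSE]
  eng$dirs[free, ] <- newdirs[free, , drop = FALSE]

  # rigid bodies: net force/torque -> rigid translation + rotation (2D)
  if (!is.null(eng$rigid)) {
    for (rb in eng$rigid) {
      idx <- rb$idx
      fc <- colSums(f[idx, , drop = FALSE])
      ctr <- colMeans(eng$pos[idx, , drop = FALSE])
      rel <- sweep(eng$pos[idx, , drop = FALSE], 2, ctr)
      tz <- sum(rel[, 1] * f[idx, 2] - rel[, 2] * f[idx, 1])
      body_noise <- with_stream(eng$streams, "engine",
                                list(t = stats::rnorm(2), r = stats::rnorm(1)))
      dc <- fc / rb$gamma_t * dt +
        sqrt(2 * p$temperature / rb$gamma_t * dt) * body_noise$t
      dth <- tz / rb$gamma_r * dt +
        sqrt(2 * p$temperature / rb$gamma_r * dt) * body_noise$r
      newrel <- rotate2(rel, dth)
      eng$pos[idx, ] <- sweep(newrel, 2, ctr + dc, "+")
      eng$unwrap[idx, ] <- eng$unwrap[idx, , drop = FALSE] +
        (eng$pos[idx, , drop = FALSE] -
           (rel + matrix(ctr, length(idx), 2, byrow = TRUE)))
      eng$dirs[idx, ] <- rotate2(eng$dirs[idx, , drop = FALSE], dth)
    }
  }

  apply_boundaries(eng)
  eng$time <- eng$time + dt
  eng$stats$steps <- eng$stats$steps + 1L
  invisible(eng)
}

apply_boundaries <- function(eng) {
  p <- eng$params
  if (p$boundary == "none") return(invisible(eng))
  box <- p$box
  if (p$boundary == "periodic") {
    eng$pos <- eng$pos %% matrix(box, eng$N, eng$d, byrow = TRUE)
  } else {
    # specular reflection: mirror the position, flip the director component
    for (k in seq_len(eng$d)) {
      L <- box[k]
      x <- eng$pos[, k]
      bad <- which(x < 0 | x > L)
      while (length(bad)) {
        xl <- x[bad]
        xl <- ifelse(xl < 0, -xl, xl)
        xl <- ifelse(xl > L, 2 * L - xl, xl)
        eng$dirs[bad, k] <- -eng$dirs[bad, k]
        x[bad] <- xl
        bad <- bad[xl < 0 | xl > L]
      }
      eng$pos[, k] <- x
    }
  }
  invisible(eng)
}

#' Read out the current particle state
#'
#' Returns a snapshot of the engine's colloids as a [colloid_state()] data
#' frame (positions, unit directors, ids, types, radii). The snapshot is a
#' copy: mutating it does not alter the engine. Ids are stable across calls.
#'
#' @param engine an engine object.
#' @return a [colloid_state()] data frame.
#' @export
get_particle_data <- function(engine) UseMethod("get_particle_data")

#' @export
get_particle_data.swarm_engine <- function(engine) {
  colloid_state(engine$ids, engine$types, engine$pos, engine$dirs,
                engine$radius)
}

#' Run the engine under a force function
#'
#' The central environment contract: loop `n_slices` times, querying the
#' force function once per slice for fresh per-particle actions, then apply
#' those actions at each of `steps_per_slice` inner Euler-Maruyama steps (the
#' chosen action is held constant within the slice). One snapshot is appended
#' per slice; the run halts early, at the end of the current slice, if the
#' force function's kill switch is raised.
#'
#' @param engine an engine object.
#' @param force_function a [force_function] (see [make_force_function()] or
#'   [passive_force_function()]).
#' @param n_slices number of control slices (>= 0).
#' @param steps_per_slice inner integration steps per slice (>= 1).
#' @return a [trajectory_record()] covering the engine's full history,
#'   invisibly also stored on the engine.
#' @export
integrate_system <- function(engine, force_function, n_slices,
                             steps_per_slice) {
  UseMethod("integrate_system")
}

#' @export
integrate_system.swarm_engine <- function(engine, force_function, n_slices,
                                          steps_per_slice) {
  stopifnot(n_slices >= 0, steps_per_slice >= 1)
  ff <- force_function
  for (s in seq_len(n_slices)) {
    colloids <- get_particle_data(engine)
    actions <- ff$calc_action(colloids)
    if (length(actions) != nrow(colloids))
      stop("force function returned ", length(actions), " actions for ",
           nrow(colloids), " colloids")
    engine$stats$action_queries <- engine$stats$action_queries + 1L
    am <- actions_to_matrices(actions, engine$d)
    for (k in seq_len(steps_per_slice)) engine_step(engine, am)
    engine$slice <- engine$slice + 1L
    record_snapshot(engine)
    if (!is.null(ff$kill_switch) && isTRUE(ff$kill_switch())) {
      engine$halted_at_slice <- engine$slice
      break
    }
  }
  trajectory_record(engine)
}

#' @export
print.swarm_engine <- function(x, ...) {
  cat("<swarm_engine> ", x$N, " colloids, ", x$d, "D, t = ",
      signif(x$time, 4), ", ", length(x$traj$time), " snapshots, boundary ",
      x$params$boundary, "\n", sep = "")
  invisible(x)
}

#' Reset engine particle state
#'
#' Restores positions/directors to a given colloid state and clears the
#' trajectory, keeping RNG streams running (used by semi-episodic training).
#'
#' @param engine a `swarm_engine`.
#' @param colloids a [colloid_state()].
#' @export
reset_engine <- function(engine, colloids) UseMethod("reset_engine")

#' @export
reset_engine.swarm_engine <- function(engine, colloids) {
  engine$pos <- colloid_positions(colloids)
  engine$dirs <- colloid_directors(colloids)
  engine$unwrap <- engine$pos
  engine$time <- 0
  engine$slice <- 0L
  engine$traj <- new.env(parent = emptyenv())
  engine$traj$time <- list()
  engine$traj$pos <- list()
  engine$traj$unwrap <- list()
  engine$traj$dirs <- list()
  engine$halted_at_slice <- NULL
  record_snapshot(engine)
  invisible(engine)
}
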