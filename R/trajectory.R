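#' Trajectory records
#'
#' A time-stamped history of system snapshots: arrays `positions`,
#' `positions_unwrapped` and `directors` of shape `[n_snapshots, N, d]`,
#' vectors `ids`, `types`, `time`, and metadata (the full [system_params()]
#' and seed). Snapshot 1 is the initial condition; one snapshot is appended
#' per control slice. Under periodic boundaries `positions` are wrapped into
#' the box while `positions_unwrapped` accumulate raw displacements (the
#' quantity mean-squared displacements must be computed from).
#'
#' @param engine a `swarm_engine`.
#' @return an object of class `trajectory_record`.
#' @export
trajectory_record <- function(engine) {
  stopifnot(inherits(engine, "swarm_engine"))
  S <- length(engine$traj$time)
  N <- engine$N
  d <- engine$d
  arr <- function(lst) {
    a <- array(NA_real_, c(S, N, d))
    for (k in seq_len(S)) a[k, , ] <- lst[[k]]
    a
  }
  structure(list(
    positions = arr(engine$traj$pos),
    positions_unwrapped = arr(engine$traj$unwrap),
    directors = arr(engine$traj$dirs),
    ids = engine$ids, types = engine$types,
    time = unlist(engine$traj$time),
    params = engine$params, seed = engine$streams$master,
    halted_at_slice = engine$halted_at_slice
  ), class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat("<trajectory_record> ", dim(x$positions)[1], " snapshots x ",
      dim(x$positions)[2], " colloids x ", dim(x$positions)[3],
      "D, t in [0, ", signif(max(x$time), 4), "]\n", sep = "")
  invisible(x)
}

#' Number of snapshots in a trajectory
#' @param traj a [trajectory_record()].
#' @export
n_snapshots <- function(traj) dim(traj$positions)[1]

#' Write / read a trajectory
#'
#' `write_trajectory` serializes the hierarchical record (positions,
#' directors, types, ids, time, plus the full configuration and seed as
#' attributes) to JSON, or to a flat CSV table with one row per
#' (snapshot, colloid).
#'
#' @param traj a [trajectory_record()].
#' @param file output path.
#' @param format "json" (full record) or "csv" (flat export).
#' @export
write_trajectory <- function(traj, file, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      positions = traj$positions,
      positions_unwrapped = traj$positions_unwrapped,
      directors = traj$directors,
      ids = traj$ids, types = traj$types, time = traj$time,
      attributes = list(config = params_to_list(traj$params),
                        seed = traj$seed)
    )
    jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  } else {
    df <- as.data.frame(traj)
    utils::write.csv(df, file, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(list(
    positions = obj$positions,
    positions_unwrapped = obj$positions_unwrapped,
    directors = obj$directors,
    ids = obj$ids, types = obj$types, time = obj$time,
    params = do.call(system_params, obj$attributes$config),
    seed = obj$attributes$seed, halted_at_slice = NULL
  ), class = "trajectory_record")
}

params_to_list <- function(p) {
  list(dimension = p$dimension, box = p$box, temperature = p$temperature,
       gamma_t = p$gamma_t, gamma_r = p$gamma_r, dt = p$dt,
       boundary = p$boundary, interactions = p$interactions, seed = p$seed)
}

#' @export
as.data.frame.trajectory_record <- function(x, ...) {
  S <- dim(x$positions)[1]; N <- dim(x$positions)[2]; d <- dim(x$positions)[3]
  pc <- c("x", "y", "z")[seq_len(d)]
  dc <- c("ex", "ey", "ez")[seq_len(d)]
  out <- data.frame(
    snapshot = rep(seq_len(S), each = N),
    time = rep(x$time, each = N),
    id = rep(x$ids, S), type = rep(x$types, S)
  )
  for (k in seq_len(d)) out[[pc[k]]] <- as.vector(t(x$positions[, , k]))
  for (k in seq_len(d)) out[[dc[k]]] <- as.vector(t(x$directors[, , k]))
  out
}
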