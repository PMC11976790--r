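#' Tasks: per-particle rewards and the kill switch
#'
#' A task measures how well the system is doing and returns one reward per
#' controlled colloid; large positive values mean the task is being achieved.
#' Every task is an environment with `$call(colloids, idx)` returning a
#' reward vector for the controlled subset, `$kill_switch()` returning a
#' latched logical (once TRUE it stays TRUE) that stops the running engine at
#' the end of the current slice, and `$reset()` clearing history and the
#' switch for a new episode.
#'
#' `task_gradient_climb` rewards chemotaxis: \eqn{r_i = s \cdot \max(0,
#' c(x_i, t) - c(x_i, t-1))} — the positive gain in sensed concentration
#' between slices (negative gains are clipped to 0 by default, mirroring
#' bacterial-style positive reinforcement; set `clip = FALSE` for the signed
#' variant). An optional threshold on the mean sensed concentration raises
#' the kill switch once reached.
#'
#' @param field a [concentration_field()].
#' @param scale multiplicative reward scale.
#' @param clip clip negative gains to zero?
#' @param threshold optional mean-concentration level that latches the kill
#'   switch.
#' @return a task environment (class `swarm_task`).
#' @export
task_gradient_climb <- function(field, scale = 1, clip = TRUE,
                                threshold = NULL) {
  tk <- new.env(parent = emptyenv())
  tk$kind <- "gradient-climbing"
  tk$prev <- NULL
  tk$killed <- FALSE
  tk$call <- function(colloids, idx) {
    pos <- colloid_positions(colloids)[idx, , drop = FALSE]
    cur <- field_value(field, pos)
    key <- as.character(colloids$id[idx])
    if (is.null(tk$prev)) tk$prev <- stats::setNames(numeric(0), character(0))
    new_ids <- !(key %in% names(tk$prev))
    if (any(new_ids)) tk$prev[key[new_ids]] <- cur[new_ids]
    gain <- cur - unname(tk$prev[key])
    tk$prev[key] <- cur
    if (!is.null(threshold) && mean(cur) >= threshold) tk$killed <- TRUE
    r <- if (clip) pmax(gain, 0) else gain
    scale * r
  }
  tk$kill_switch <- function() tk$killed
  tk$reset <- function() {
    tk$prev <- NULL
    tk$killed <- FALSE
  }
  class(tk) <- "swarm_task"
  tk
}

#' @description
#' `task_rod_rotation` rewards rotating a tracked rigid body (a bead-chain
#' rod): every controlled colloid receives \eqn{r = s \cdot \omega}, the
#' signed angular velocity of the rod axis over the last slice (unwrapped to
#' \eqn{(-\pi, \pi]}), positive when the rotation has the target sense.
#'
#' @param rod_ids colloid ids forming the rod (axis = first to last bead).
#' @param slice_dt time between task evaluations (slice duration).
#' @param direction +1 to reward counterclockwise rotation, -1 clockwise.
#' @rdname task_gradient_climb
#' @export
task_rod_rotation <- function(rod_ids, scale = 1, slice_dt = 1,
                              direction = 1) {
  tk <- new.env(parent = emptyenv())
  tk$kind <- "rod-rotation"
  tk$prev_angle <- NULL
  tk$killed <- FALSE
  tk$call <- function(colloids, idx) {
    rix <- match(rod_ids, colloids$id)
    if (anyNA(rix)) stop("rod ids not present in colloid state")
    pos <- colloid_positions(colloids)
    axis <- unname(pos[rix[length(rix)], ] - pos[rix[1], ])
    ang <- atan2(axis[2], axis[1])
    if (is.null(tk$prev_angle)) tk$prev_angle <- ang
    dth <- ang - tk$prev_angle
    dth <- atan2(sin(dth), cos(dth))   # unwrap to (-pi, pi]
    tk$prev_angle <- ang
    omega <- dth / slice_dt
    rep(scale * direction * omega, length(idx))
  }
  tk$kill_switch <- function() tk$killed
  tk$reset <- function() {
    tk$prev_angle <- NULL
    tk$killed <- FALSE
  }
  class(tk) <- "swarm_task"
  tk
}

#' @description
#' `task_time_limit` contributes zero reward and latches the kill switch
#' after a fixed number of slices.
#' @param n_slices slice count after which the switch latches.
#' @rdname task_gradient_climb
#' @export
task_time_limit <- function(n_slices) {
  tk <- new.env(parent = emptyenv())
  tk$kind <- "time-limit"
  tk$count <- 0L
  tk$killed <- FALSE
  tk$call <- function(colloids, idx) {
    tk$count <- tk$count + 1L
    if (tk$count >= n_slices) tk$killed <- TRUE
    numeric(length(idx))
  }
  tk$kill_switch <- function() tk$killed
  tk$reset <- function() {
    tk$count <- 0L
    tk$killed <- FALSE
  }
  class(tk) <- "swarm_task"
  tk
}

#' Combine several tasks
#'
#' Rewards are the elementwise sum of the member tasks' rewards; the
#' composite kill switch is the logical OR of the members' switches (and thus
#' latched as soon as any member latches).
#'
#' @param tasks a non-empty list of tasks.
#' @return a composite task.
#' @export
multitask <- function(tasks) {
  if (length(tasks) == 0) stop("at least one task required")
  tk <- new.env(parent = emptyenv())
  tk$kind <- "multitasking"
  tk$parts <- tasks
  tk$call <- function(colloids, idx) {
    Reduce(`+`, lapply(tasks, function(t) t$call(colloids, idx)))
  }
  tk$kill_switch <- function() {
    any(vapply(tasks, function(t) isTRUE(t$kill_switch()), logical(1)))
  }
  tk$reset <- function() for (t in tasks) t$reset()
  class(tk) <- "swarm_task"
  tk
}

#' @export
print.swarm_task <- function(x, ...) {
  cat("<swarm_task> ", x$kind, "\n", sep = "")
  invisible(x)
}
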