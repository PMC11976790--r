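#' Control actions
#'
#' An action is the control primitive applied to one particle for one time
#' slice: a propulsion force magnitude applied along the particle's director,
#' a steering torque (only the out-of-plane z component acts in 2D), and an
#' optional direction override. When `new_direction` is supplied the torque is
#' ignored for that slice and the director is assigned directly.
#'
#' @param force propulsion force magnitude, >= 0 (reduced units).
#' @param torque length-3 numeric torque vector.
#' @param new_direction optional unit vector replacing the director.
#' @return an object of class `swarm_action`.
#' @export
action <- function(force = 0, torque = c(0, 0, 0), new_direction = NULL) {
  stopifnot(is.numeric(force), length(force) == 1, force >= 0,
            is.numeric(torque), length(torque) == 3)
  if (!is.null(new_direction)) {
    nd <- as.numeric(new_direction)
    n <- sqrt(sum(nd^2))
    if (n == 0) stop("new_direction must be non-zero")
    nd <- nd / n
    stopifnot(abs(sqrt(sum(nd^2)) - 1) < 1e-9)
  } else nd <- NULL
  structure(list(force = force, torque = as.numeric(torque),
                 new_direction = nd),
            class = "swarm_action")
}

#' Ordered action sets
#'
#' An ordered, named collection of [action()]s. The order is fixed and defines
#' the categorical action indexing used by policies: index i always maps to the
#' i-th action of the set.
#'
#' @param ... named `swarm_action` objects.
#' @return an object of class `action_set`.
#' @export
action_set <- function(...) {
  acts <- list(...)
  if (length(acts) == 1 && is.list(acts[[1]]) &&
      !inherits(acts[[1]], "swarm_action"))
    acts <- acts[[1]]
  if (length(acts) == 0) stop("action set must be non-empty")
  if (is.null(names(acts)) || any(names(acts) == ""))
    stop("all actions must be named")
  if (!all(vapply(acts, inherits, logical(1), "swarm_action")))
    stop("all elements must be swarm_action objects")
  structure(acts, class = "action_set")
}

#' The four-action microswimmer control set
#'
#' translate (force `f0` along the director), rotate_clockwise (torque `-tau0`
#' about z), rotate_counterclockwise (`+tau0`), and do_nothing. This mirrors
#' the standard discrete steering repertoire of externally actuated
#' microswimmers.
#'
#' @param f0 translation force magnitude.
#' @param tau0 steering torque magnitude.
#' @return an [action_set()] of length 4.
#' @export
default_action_set <- function(f0 = 10, tau0 = 10) {
  action_set(
    translate = action(force = f0),
    rotate_clockwise = action(torque = c(0, 0, -tau0)),
    rotate_counterclockwise = action(torque = c(0, 0, tau0)),
    do_nothing = action()
  )
}

#' @export
length.action_set <- function(x) length(unclass(x))

#' Map a categorical index to its action and back
#' @param set an [action_set()].
#' @param i 1-based action index.
#' @return [index_to_action()]: the `swarm_action`; [action_to_index()]: the
#'   1-based index of an action's name within the set.
#' @export
index_to_action <- function(set, i) {
  stopifnot(inherits(set, "action_set"), i >= 1, i <= length(set))
  unclass(set)[[i]]
}

#' @param name action name.
#' @rdname index_to_action
#' @export
action_to_index <- function(set, name) {
  ix <- match(name, names(set))
  if (is.na(ix)) stop("unknown action: ", name)
  ix
}

#' @export
print.action_set <- function(x, ...) {
  cat("<action_set> ", length(x), " actions: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# internal: convert a list of per-colloid actions into column vectors/matrices
# consumed by the vectorized engine step
actions_to_matrices <- function(actions, d) {
  n <- length(actions)
  force <- numeric(n)
  torque_z <- numeric(n)
  torque3 <- matrix(0, n, 3)
  new_dir <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    a <- actions[[i]]
    if (!inherits(a, "swarm_action")) stop("actions must be swarm_action objects")
    force[i] <- a$force
    torque_z[i] <- a$torque[3]
    torque3[i, ] <- a$torque
    if (!is.null(a$new_direction)) {
      if (length(a$new_direction) != d)
        stop("new_direction dimension mismatch")
      new_dir[i, ] <- a$new_direction
    }
  }
  list(force = force, torque_z = torque_z, torque3 = torque3,
       new_dir = new_dir)
}
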