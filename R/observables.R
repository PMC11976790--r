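#' Observables: per-particle state descriptions
#'
#' An observable condenses the full system state into the limited sensing of
#' a micro-agent: a fixed-length feature vector per controlled colloid. Every
#' observable is an environment with a known output dimension (`$dim`), a
#' `$compute(colloids, idx)` method returning a `length(idx) x dim` matrix
#' for the controlled subset `idx` of the full colloid table, and a
#' `$reset()` method clearing any slice-indexed internal history. `compute`
#' never mutates the colloid table it receives.
#'
#' `obs_concentration_change` emulates an agent that senses only a local
#' scalar concentration and cannot tell directions: it returns the (scaled)
#' change in sensed field value between the current and the previous slice.
#' On the first slice the previous value is initialized to the current one,
#' so the first output is 0.
#'
#' @param field a [concentration_field()].
#' @param scale multiplicative scaling of the change signal.
#' @return an observable environment (class `swarm_observable`).
#' @export
obs_concentration_change <- function(field, scale = 1) {
  ob <- new.env(parent = emptyenv())
  ob$dim <- 1L
  ob$kind <- "concentration-change"
  ob$prev <- NULL   # named by colloid id
  ob$compute <- function(colloids, idx) {
    pos <- colloid_positions(colloids)[idx, , drop = FALSE]
    cur <- field_value(field, pos)
    key <- as.character(colloids$id[idx])
    if (is.null(ob$prev)) ob$prev <- stats::setNames(numeric(0), character(0))
    new_ids <- !(key %in% names(ob$prev))
    if (any(new_ids)) ob$prev[key[new_ids]] <- cur[new_ids]
    delta <- cur - unname(ob$prev[key])
    ob$prev[key] <- cur
    matrix(delta * scale, ncol = 1)
  }
  ob$reset <- function() ob$prev <- NULL
  class(ob) <- "swarm_observable"
  ob
}

#' @description
#' `obs_neighbour_count` senses crowding: the number of other colloids within
#' a finite sensing radius (scaled).
#' @param radius sensing radius.
#' @param box periodic box lengths for minimum-image distances, or NULL.
#' @rdname obs_concentration_change
#' @export
obs_neighbour_count <- function(radius, scale = 1, box = NULL) {
  ob <- new.env(parent = emptyenv())
  ob$dim <- 1L
  ob$kind <- "neighbour-count"
  ob$compute <- function(colloids, idx) {
    pos <- colloid_positions(colloids)
    counts <- vapply(idx, function(i) {
      dx <- sweep(pos, 2, pos[i, ])
      if (!is.null(box)) dx <- minimum_image(dx, box)
      sum(rowSums(dx^2) <= radius^2) - 1L
    }, numeric(1))
    matrix(counts * scale, ncol = 1)
  }
  ob$reset <- function() invisible(NULL)
  class(ob) <- "swarm_observable"
  ob
}

#' @description
#' `obs_position` exposes the particle's own position, rescaled by the box.
#' @rdname obs_concentration_change
#' @export
obs_position <- function(box) {
  ob <- new.env(parent = emptyenv())
  ob$dim <- length(box)
  ob$kind <- "position"
  ob$compute <- function(colloids, idx) {
    pos <- colloid_positions(colloids)[idx, , drop = FALSE]
    sweep(pos, 2, as.numeric(box), "/")
  }
  ob$reset <- function() invisible(NULL)
  class(ob) <- "swarm_observable"
  ob
}

#' Concatenate several observables into one sensor suite
#'
#' Blocks are concatenated in declaration order; the output dimension is the
#' sum of the parts.
#'
#' @param observables a non-empty list of observables.
#' @return a composite observable.
#' @export
multi_sensing <- function(observables) {
  if (length(observables) == 0) stop("at least one observable required")
  ob <- new.env(parent = emptyenv())
  ob$dim <- sum(vapply(observables, function(o) o$dim, integer(1)))
  ob$kind <- "multi-sensing"
  ob$parts <- observables
  ob$compute <- function(colloids, idx) {
    do.call(cbind, lapply(observables, function(o) o$compute(colloids, idx)))
  }
  ob$reset <- function() for (o in observables) o$reset()
  class(ob) <- "swarm_observable"
  ob
}

#' @export
print.swarm_observable <- function(x, ...) {
  cat("<swarm_observable> ", x$kind, ", dim ", x$dim, "\n", sep = "")
  invisible(x)
}
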