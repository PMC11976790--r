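#' Colloid state tables
#'
#' Per-particle state is exchanged between the engine and all control code as
#' a plain data frame with one row per colloid: `id` (integer >= 0), `type`
#' (integer group label), position columns (`x`, `y`[, `z`]), director columns
#' (`ex`, `ey`[, `ez`]; unit norm), and `radius`. The data frame is a snapshot:
#' mutating it never alters the engine's internal state.
#'
#' @param id integer ids (>= 0, unique).
#' @param type integer type labels (one agent may control one type).
#' @param position n x d matrix of positions (d = 2 or 3).
#' @param director n x d matrix of unit directors.
#' @param radius particle radii, recycled to n.
#' @return a `data.frame` of class `colloid_state`.
#' @export
colloid_state <- function(id, type, position, director, radius = 1) {
  position <- as.matrix(position)
  director <- as.matrix(director)
  d <- ncol(position)
  stopifnot(d %in% c(2, 3), all(dim(position) == dim(director)),
            length(id) == nrow(position), length(type) == nrow(position),
            all(id >= 0), !anyDuplicated(id), all(is.finite(position)),
            all(is.finite(director)))
  nrm <- sqrt(rowSums(director^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("directors must be unit vectors")
  director <- director / nrm
  radius <- rep_len(as.numeric(radius), nrow(position))
  stopifnot(all(radius > 0))
  pos_cols <- c("x", "y", "z")[seq_len(d)]
  dir_cols <- c("ex", "ey", "ez")[seq_len(d)]
  df <- data.frame(id = as.integer(id), type = as.integer(type))
  df[pos_cols] <- split(position, col(position))
  df[dir_cols] <- split(director, col(director))
  df$radius <- radius
  class(df) <- c("colloid_state", "data.frame")
  df
}

#' @param colloids a `colloid_state` data frame.
#' @return [colloid_positions()] / [colloid_directors()]: an n x d matrix.
#' @rdname colloid_state
#' @export
colloid_positions <- function(colloids) {
  d <- colloid_dim(colloids)
  m <- as.matrix(colloids[, c("x", "y", "z")[seq_len(d)], drop = FALSE])
  dimnames(m) <- NULL
  m
}

#' @rdname colloid_state
#' @export
colloid_directors <- function(colloids) {
  d <- colloid_dim(colloids)
  m <- as.matrix(colloids[, c("ex", "ey", "ez")[seq_len(d)], drop = FALSE])
  dimnames(m) <- NULL
  m
}

colloid_dim <- function(colloids) if ("z" %in% names(colloids)) 3L else 2L

#' @export
print.colloid_state <- function(x, ...) {
  cat("<colloid_state> ", nrow(x), " colloids, ",
      colloid_dim(x), "D, types: ",
      paste(sort(unique(x$type)), collapse = ", "), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
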