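#' Policy checkpoints
#'
#' A checkpoint stores, per agent, the flattened network parameter arrays
#' (key -> array, with dimensions), the optimizer moments, and the trainer's
#' full RNG stream states, plus a hash of the agent configuration. Restoring
#' a checkpoint and continuing therefore reproduces an uninterrupted run
#' exactly. Floating-point values are serialized as "%.17g" strings, which
#' round-trip IEEE doubles bit-exactly through JSON.
#'
#' @param agents list of [swarm_agent()]s.
#' @param streams the trainer's [rng_streams()].
#' @param file output path (JSON).
#' @param extra named list of additional metadata (e.g. episode counter).
#' @return the file path, invisibly.
#' @export
save_checkpoint <- function(agents, streams, file, extra = list()) {
  if (inherits(agents, "swarm_agent")) agents <- list(agents)
  enc_num <- function(x) {
    list(dim = dim(x) %||% length(x),
         data = sprintf("%.17g", as.numeric(x)))
  }
  enc_tree <- function(tree) {
    fl <- flatten_tree(tree)
    lapply(fl, enc_num)
  }
  payload <- list(
    format = "swarmlearn-checkpoint-v1",
    config_hash = agents_config_hash(agents),
    rng_state = stream_states(streams),
    extra = extra,
    agents = lapply(agents, function(a) {
      if (a$kind != "trainable") return(list(kind = a$kind))
      st <- a$policy$opt_state
      list(kind = a$kind, particle_type = a$particle_type,
           variant = a$policy$variant,
           params = enc_tree(a$policy$params),
           opt_m = if (!is.null(st)) enc_tree(st$m),
           opt_v = if (!is.null(st)) enc_tree(st$v),
           opt_t = if (!is.null(st)) st$t else 0L)
    })
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restore a checkpoint into an agent list
#'
#' Parameters, optimizer state and (optionally) the trainer RNG streams are
#' restored in place. The agents must have the same architecture as when the
#' checkpoint was written; a configuration-hash mismatch produces a warning.
#'
#' @param file checkpoint path.
#' @param agents agent list to restore into (modified in place).
#' @param streams optional [rng_streams()] to restore stream states into.
#' @return the checkpoint metadata (`extra` list), invisibly.
#' @export
load_checkpoint <- function(file, agents, streams = NULL) {
  if (inherits(agents, "swarm_agent")) agents <- list(agents)
  payload <- jsonlite::read_json(file, simplifyVector = FALSE)
  if (!identical(payload$format, "swarmlearn-checkpoint-v1"))
    stop("not a recognized checkpoint file")
  if (!identical(payload$config_hash, agents_config_hash(agents)))
    warning("checkpoint configuration hash does not match these agents")
  dec_num <- function(e) {
    x <- as.numeric(unlist(e$data))
    d <- unlist(e$dim)
    if (length(d) > 1) dim(x) <- d
    x
  }
  dec_into <- function(tree, flat, prefix = "p") {
    if (is.list(tree)) {
      nms <- if (is.null(names(tree))) seq_along(tree) else names(tree)
      for (i in seq_along(tree))
        tree[[i]] <- dec_into(tree[[i]], flat, paste0(prefix, ".", nms[i]))
      tree
    } else {
      v <- dec_num(flat[[prefix]])
      if (is.null(dim(v)) && !is.null(dim(tree))) dim(v) <- dim(tree)
      v
    }
  }
  for (ai in seq_along(agents)) {
    a <- agents[[ai]]
    rec <- payload$agents[[ai]]
    if (a$kind != "trainable") next
    a$policy$params <- dec_into(a$policy$params, rec$params)
    if (length(rec$opt_m) > 0) {
      a$policy$opt_state <- list(
        m = dec_into(tree_zero(a$policy$params), rec$opt_m),
        v = dec_into(tree_zero(a$policy$params), rec$opt_v),
        t = as.integer(rec$opt_t))
    }
  }
  if (!is.null(streams)) {
    restore_stream_states(streams,
                          lapply(payload$rng_state, function(s) unlist(s)))
  }
  invisible(payload$extra)
}

# cheap FNV-1a hash of the agents' structural configuration
agents_config_hash <- function(agents) {
  desc <- vapply(agents, function(a) {
    paste(a$kind, a$particle_type, length(a$action_set),
          if (!is.null(a$policy))
            paste(a$policy$variant, a$policy$input_dim,
                  paste(a$policy$hidden, collapse = "x"),
                  a$policy$n_actions)
          else "rule", collapse = "|")
  }, character(1))
  s <- paste(desc, collapse = ";")
  h <- 216613626
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}
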