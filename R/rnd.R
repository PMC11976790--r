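#' Random network distillation (RND) intrinsic reward
#'
#' Novelty of a state is the squared error between a frozen, randomly
#' initialized target embedding network and a trained predictor network:
#' \eqn{n(s) = \lVert f_{target}(s) - f_{pred}(s) \rVert^2}. States the
#' predictor has been trained on score low; unseen states score high, so the
#' novelty acts as an intrinsic exploration reward added to the task reward
#' with a configurable weight. Two variants are provided: the plain one
#' trains only on each incoming batch, the memory variant additionally keeps
#' a bounded FIFO buffer of past states and rehearses minibatches from it,
#' which preserves low novelty on states seen long ago.
#'
#' @param input_dim observable dimension.
#' @param hidden hidden width of both networks (one hidden layer).
#' @param embed_dim embedding dimension.
#' @param eta predictor learning rate.
#' @param memory keep a FIFO state memory and rehearse from it?
#' @param memory_size FIFO capacity (states).
#' @param minibatch rehearsal minibatch size.
#' @param weight intrinsic-reward weight when combined with task rewards.
#' @return an environment of class `rnd_module`.
#' @export
rnd_module <- function(input_dim, hidden = 64, embed_dim = 16, eta = 1e-3,
                       memory = FALSE, memory_size = 4096, minibatch = 128,
                       weight = 0.1) {
  rnd <- new.env(parent = emptyenv())
  rnd$input_dim <- as.integer(input_dim)
  rnd$target <- mlp_init(c(input_dim, hidden, embed_dim))
  rnd$predictor <- mlp_init(c(input_dim, hidden, embed_dim))
  rnd$eta <- eta
  rnd$memory <- memory
  rnd$memory_size <- as.integer(memory_size)
  rnd$minibatch <- as.integer(minibatch)
  rnd$weight <- weight
  rnd$buffer <- NULL   # rows = remembered states
  rnd$opt_state <- NULL
  class(rnd) <- "rnd_module"
  rnd
}

#' Novelty (intrinsic reward) of a batch of states
#'
#' @param rnd an [rnd_module()].
#' @param states n x input_dim matrix of state vectors (or one vector).
#' @return non-negative novelty per state.
#' @export
rnd_novelty <- function(rnd, states) {
  if (!is.matrix(states)) states <- matrix(states, nrow = 1)
  if (ncol(states) != rnd$input_dim)
    stop("state dimension mismatch: got ", ncol(states),
         ", expected ", rnd$input_dim)
  tg <- mlp_forward(rnd$target, states)$out
  pr <- mlp_forward(rnd$predictor, states)$out
  rowSums((tg - pr)^2)
}

#' Train the RND predictor on a batch of states
#'
#' Performs `steps` gradient steps minimizing the mean novelty of the batch
#' (the memory variant appends the batch to its FIFO buffer first and trains
#' on minibatches sampled from the buffer). The target network is never
#' modified.
#'
#' @param rnd an [rnd_module()].
#' @param states n x input_dim matrix of states.
#' @param steps number of gradient steps (0 leaves the module unchanged).
#' @return the module, invisibly (updated in place).
#' @export
rnd_update <- function(rnd, states, steps = 1) {
  if (!is.matrix(states)) states <- matrix(states, nrow = 1)
  if (nrow(states) == 0) stop("non-empty state batch required")
  if (rnd$memory) {
    rnd$buffer <- rbind(rnd$buffer, states)
    if (nrow(rnd$buffer) > rnd$memory_size) {
      keep <- (nrow(rnd$buffer) - rnd$memory_size + 1):nrow(rnd$buffer)
      rnd$buffer <- rnd$buffer[keep, , drop = FALSE]
    }
  }
  for (s in seq_len(steps)) {
    batch <- if (rnd$memory) {
      n <- nrow(rnd$buffer)
      take <- if (n <= rnd$minibatch) seq_len(n)
      else sample.int(n, rnd$minibatch)
      rnd$buffer[take, , drop = FALSE]
    } else states
    tg <- mlp_forward(rnd$target, batch)$out
    fw <- mlp_forward(rnd$predictor, batch)
    dout <- 2 * (fw$out - tg) / nrow(batch)
    bk <- mlp_backward(rnd$predictor, fw$cache, dout)
    upd <- update_params(rnd$predictor,
                         tree_map(function(x) -x, bk$grads),
                         rnd$eta, method = "adam", state = rnd$opt_state)
    rnd$predictor <- upd$params
    rnd$opt_state <- upd$state
  }
  invisible(rnd)
}

#' @export
print.rnd_module <- function(x, ...) {
  cat("<rnd_module> input ", x$input_dim, " -> embed ",
      ncol(x$target[[length(x$target)]]$W),
      if (x$memory) paste0(", FIFO memory ", x$memory_size) else "",
      ", weight ", x$weight, "\n", sep = "")
  invisible(x)
}
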