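#' Exploration-probability decay
#'
#' The random-exploration policy takes a uniformly random action with
#' probability \eqn{\zeta'} and the policy's action otherwise, where the
#' exploration probability decays with simulation time as
#' \deqn{\zeta' = e^{-\epsilon\, t / T}\, \zeta,}
#' with initial probability \eqn{\zeta}, decay rate \eqn{\epsilon \ge 0} and
#' episode duration T.
#'
#' @param zeta initial exploration probability in \[0, 1\].
#' @param eps decay rate >= 0.
#' @param t simulation time (same units as `T_ep`).
#' @param T_ep duration of a single training episode, > 0.
#' @return decayed exploration probability \eqn{\zeta'}.
#' @examples
#' explore_decay(0.8, 1, t = 1, T_ep = 1)  # 0.8 * exp(-1)
#' @export
explore_decay <- function(zeta, eps, t, T_ep) {
  if (T_ep <= 0) stop("episode duration T must be positive")
  stopifnot(zeta >= 0, zeta <= 1, eps >= 0)
  exp(-eps * t / T_ep) * zeta
}

#' Mix a policy action with random exploration
#'
#' With probability `zeta` returns a uniformly random index from
#' `1:n_actions`; otherwise returns the policy's `action_index`. The log
#' probability recorded for training remains the policy's log-probability of
#' whatever action was executed.
#'
#' @param action_index the policy's sampled index.
#' @param zeta current exploration probability in \[0, 1\].
#' @param n_actions size of the action set.
#' @return the executed action index.
#' @export
maybe_explore <- function(action_index, zeta, n_actions) {
  stopifnot(zeta >= 0, zeta <= 1, n_actions >= 1)
  if (zeta > 0 && stats::runif(1) < zeta)
    sample.int(n_actions, 1)
  else action_index
}

# vectorized over a batch of indices
maybe_explore_vec <- function(action_index, zeta, n_actions) {
  n <- length(action_index)
  if (zeta <= 0) return(action_index)
  u <- stats::runif(n)
  repl <- u < zeta
  if (any(repl))
    action_index[repl] <- sample.int(n_actions, sum(repl), replace = TRUE)
  action_index
}
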