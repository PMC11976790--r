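#' Discounted expected returns
#'
#' \deqn{G_t = \sum_{t'=t}^{T-1} \gamma^{t'-t} r_{t'}} computed by the exact
#' backward recursion \eqn{G_t = r_t + \gamma G_{t+1}}, \eqn{G_{T-1} =
#' r_{T-1}}.
#'
#' @param rewards reward vector (length T >= 1).
#' @param gamma discount factor in \[0, 1\].
#' @return vector of returns, same length.
#' @examples
#' expected_returns(c(1, 0, 2), gamma = 0.5)  # 1.5, 1.0, 2.0
#' @export
expected_returns <- function(rewards, gamma) {
  T_ <- length(rewards)
  if (T_ < 1) stop("empty reward vector")
  stopifnot(gamma >= 0, gamma <= 1)
  G <- numeric(T_)
  G[T_] <- rewards[T_]
  if (T_ > 1) for (t in (T_ - 1):1) G[t] <- rewards[t] + gamma * G[t + 1]
  G
}

#' Advantage function
#'
#' \eqn{A_t = G_t - V_t}: returns minus the critic's value baseline,
#' optionally standardized to zero mean and unit variance over the batch (a
#' common variance-reduction device; a degenerate batch with near-zero spread
#' is only centred, never divided by ~0).
#'
#' @param G returns vector.
#' @param V value-estimate vector, same length.
#' @param standardize standardize over the batch?
#' @return advantage vector.
#' @export
advantage <- function(G, V, standardize = FALSE) {
  if (length(G) != length(V)) stop("length mismatch between G and V")
  A <- G - V
  if (standardize) A <- standardize_advantages(A)
  A
}

standardize_advantages <- function(A) {
  A <- A - mean(A)
  s <- stats::sd(A)
  if (is.finite(s) && s > 1e-8) A <- A / s
  A
}

#' Generalized advantage estimation
#'
#' With TD residuals \eqn{\delta_t = r_t + \gamma V_{t+1} - V_t} (terminal
#' bootstrap \eqn{V_T = 0}),
#' \deqn{A_t = \sum_{l \ge 0} (\gamma\lambda)^l \delta_{t+l}.}
#' At \eqn{\lambda = 1} this telescopes to \eqn{G_t - V_t}; at
#' \eqn{\lambda = 0} it is the one-step TD error.
#'
#' @param rewards reward vector (length T).
#' @param values value-estimate vector (length T).
#' @param gamma discount factor.
#' @param lambda GAE mixing parameter in \[0, 1\].
#' @return advantage vector of length T.
#' @export
gae <- function(rewards, values, gamma, lambda) {
  T_ <- length(rewards)
  if (length(values) != T_) stop("length mismatch between rewards and values")
  stopifnot(T_ >= 1, gamma >= 0, gamma <= 1, lambda >= 0, lambda <= 1)
  v_next <- c(values[-1], 0)
  delta <- rewards + gamma * v_next - values
  A <- numeric(T_)
  A[T_] <- delta[T_]
  if (T_ > 1) for (t in (T_ - 1):1) A[t] <- delta[t] + gamma * lambda * A[t + 1]
  A
}

#' Vanilla policy-gradient (REINFORCE-with-baseline) loss
#'
#' \eqn{-\sum_t \log\pi(a_t|s_t) A_t}, negated so that minimizing the loss
#' performs gradient ascent on the policy objective. Advantages are treated
#' as constants (no gradient flows through A).
#'
#' @param log_probs log-probabilities of the taken actions.
#' @param A advantage vector (same length).
#' @return scalar loss.
#' @export
vpg_loss <- function(log_probs, A) {
  if (length(log_probs) != length(A)) stop("length mismatch")
  if (anyNA(log_probs) || anyNA(A)) stop("NaN in loss inputs")
  -sum(log_probs * A)
}

#' Clipped-surrogate (PPO) loss
#'
#' With probability ratio \eqn{\rho_t = \exp(\log\pi_{new} - \log\pi_{old})},
#' \deqn{L = -\sum_t \min(\rho_t A_t,\;
#'   \mathrm{clip}(\rho_t, 1-\epsilon, 1+\epsilon) A_t).}
#' The old log-probabilities carry no gradient. At \eqn{\rho = 1} the loss
#' reduces to the unclipped surrogate \eqn{-\sum \rho_t A_t}.
#'
#' @param log_probs_new current-policy log-probabilities of taken actions.
#' @param log_probs_old collection-time log-probabilities (constants).
#' @param A advantage vector.
#' @param eps_clip clip radius \eqn{\epsilon > 0} (default 0.2).
#' @return scalar loss.
#' @export
ppo_loss <- function(log_probs_new, log_probs_old, A, eps_clip = 0.2) {
  stopifnot(length(log_probs_new) == length(A),
            length(log_probs_old) == length(A), eps_clip > 0)
  rho <- exp(log_probs_new - log_probs_old)
  if (any(!is.finite(rho))) stop("non-finite probability ratio")
  clipped <- pmin(pmax(rho, 1 - eps_clip), 1 + eps_clip)
  -sum(pmin(rho * A, clipped * A))
}

#' Critic regression loss
#'
#' Mean squared error between predicted state values and the realized
#' expected returns.
#' @param V predicted values.
#' @param G expected returns (same length).
#' @return scalar MSE.
#' @export
critic_loss <- function(V, G) {
  if (length(V) != length(G)) stop("length mismatch between V and G")
  mean((V - G)^2)
}

#' Training hyperparameters
#'
#' @param gamma discount factor in \[0, 1\].
#' @param lambda GAE lambda in \[0, 1\] (1 recovers plain returns-minus-value
#'   advantages).
#' @param eps_clip PPO clip radius > 0.
#' @param eta learning rate > 0.
#' @param epochs gradient epochs per collected batch (PPO re-evaluates the
#'   ratio each epoch; VPG uses 1).
#' @param entropy_coef entropy-bonus coefficient >= 0 (0 disables).
#' @param standardize_advantages standardize advantages per batch?
#' @param algorithm "vpg" or "ppo".
#' @param optimizer "adam" (default) or "sgd".
#' @param value_coef weight of the critic loss in the combined update.
#' @param use_gae use GAE for the actor's advantages (the critic always
#'   regresses on full returns)?
#' @return list of class `training_hyperparams`.
#' @export
training_hyperparams <- function(gamma = 0.99, lambda = 0.95, eps_clip = 0.2,
                                 eta = 1e-3, epochs = 4, entropy_coef = 0.01,
                                 standardize_advantages = TRUE,
                                 algorithm = c("vpg", "ppo"),
                                 optimizer = c("adam", "sgd"),
                                 value_coef = 0.5, use_gae = FALSE) {
  algorithm <- match.arg(algorithm)
  optimizer <- match.arg(optimizer)
  stopifnot(gamma >= 0, gamma <= 1, lambda >= 0, lambda <= 1, eps_clip > 0,
            eta > 0, epochs >= 1, entropy_coef >= 0, value_coef >= 0)
  structure(list(gamma = gamma, lambda = lambda, eps_clip = eps_clip,
                 eta = eta, epochs = as.integer(epochs),
                 entropy_coef = entropy_coef,
                 standardize_advantages = standardize_advantages,
                 algorithm = algorithm, optimizer = optimizer,
                 value_coef = value_coef, use_gae = use_gae),
            class = "training_hyperparams")
}

# ---- loss gradients w.r.t. network outputs ----------------------------------

# Gradient of the combined (actor + entropy + value_coef * critic) loss with
# respect to logits and values, for one forward pass. Entropy H = -sum p log p
# per row; d(-H)/dz_j = p_j (log p_j + H).
loss_grads <- function(probs, value, a_idx, A, G, hp, old_logp = NULL) {
  n <- nrow(probs)
  onehot <- matrix(0, n, ncol(probs))
  onehot[cbind(seq_len(n), a_idx)] <- 1
  if (hp$algorithm == "vpg") {
    dlogits <- -A * (onehot - probs)
  } else {
    logp_new <- log_prob_of(probs, a_idx)
    rho <- exp(logp_new - old_logp)
    clipped <- pmin(pmax(rho, 1 - hp$eps_clip), 1 + hp$eps_clip)
    unclipped_active <- (rho * A) <= (clipped * A)
    coef <- ifelse(unclipped_active, rho * A, 0)
    dlogits <- -coef * (onehot - probs)
  }
  if (hp$entropy_coef > 0) {
    logp <- log(pmax(probs, 1e-8))
    H <- -rowSums(probs * logp)
    dlogits <- dlogits + hp$entropy_coef * probs * (logp + H)
  }
  dvalue <- hp$value_coef * 2 * (value - G) / n
  list(dlogits = dlogits, dvalue = dvalue)
}

# One full actor-critic update on a pooled batch. Mutates policy (params and
# optimizer state). Returns diagnostics.
policy_update <- function(policy, X, a_idx, rewards_list, hp) {
  # rewards_list: list of per-particle reward vectors (episode time series);
  # X and a_idx are stacked in the same particle-major order.
  G <- unlist(lapply(rewards_list, expected_returns, gamma = hp$gamma))
  fwd0 <- policy_forward(policy, X)
  V0 <- fwd0$value
  if (hp$use_gae) {
    offs <- c(0, cumsum(vapply(rewards_list, length, 1L)))
    A <- unlist(lapply(seq_along(rewards_list), function(i) {
      sel <- (offs[i] + 1):offs[i + 1]
      gae(rewards_list[[i]], V0[sel], hp$gamma, hp$lambda)
    }))
  } else {
    A <- G - V0
  }
  if (hp$standardize_advantages) A <- standardize_advantages(A)
  old_logp <- log_prob_of(fwd0$probs, a_idx)
  epochs <- if (hp$algorithm == "vpg") 1L else hp$epochs
  actor_l <- critic_l <- ent <- NA_real_
  for (ep in seq_len(epochs)) {
    fwd <- if (ep == 1) fwd0 else policy_forward(policy, X)
    g <- loss_grads(fwd$probs, fwd$value, a_idx, A, G, hp,
                    old_logp = old_logp)
    grads <- policy_backward(policy, fwd$cache, g$dlogits, g$dvalue)
    # losses are minimized; update_params ascends, so negate
    neg <- tree_map(function(x) -x, grads)
    upd <- update_params(policy$params, neg, hp$eta, method = hp$optimizer,
                         state = policy$opt_state)
    policy$params <- upd$params
    policy$opt_state <- upd$state
    if (ep == epochs) {
      logp_new <- log_prob_of(fwd$probs, a_idx)
      actor_l <- if (hp$algorithm == "vpg") vpg_loss(logp_new, A)
      else ppo_loss(logp_new, old_logp, A, hp$eps_clip)
      critic_l <- critic_loss(fwd$value, G)
      lp <- log(pmax(fwd$probs, 1e-8))
      ent <- mean(-rowSums(fwd$probs * lp))
    }
  }
  list(actor_loss = actor_l, critic_loss = critic_l, entropy = ent,
       mean_return = mean(G))
}
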