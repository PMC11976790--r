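# Independent oracles and instrumented stubs shared across tests.

# O(T^2) brute-force discounted returns: direct double loop over the sum
# G_t = sum_{t' >= t} gamma^(t'-t) r_t'
brute_force_returns <- function(rewards, gamma) {
  T_ <- length(rewards)
  vapply(seq_len(T_), function(t) {
    sum(gamma^(seq(t, T_) - t) * rewards[t:T_])
  }, numeric(1))
}

# O(T^2) brute-force GAE: A_t = sum_{l>=0} (gamma*lambda)^l delta_{t+l}
brute_force_gae <- function(rewards, values, gamma, lambda) {
  T_ <- length(rewards)
  v_next <- c(values[-1], 0)
  delta <- rewards + gamma * v_next - values
  vapply(seq_len(T_), function(t) {
    l <- seq(t, T_) - t
    sum((gamma * lambda)^l * delta[t:T_])
  }, numeric(1))
}

# force function applying a fixed action to every colloid; counts calls and
# optionally raises the kill switch during its k-th calc_action call
stub_force_function <- function(act = action(), kill_at = Inf) {
  ff <- new.env(parent = emptyenv())
  ff$calls <- 0L
  ff$killed <- FALSE
  ff$calc_action <- function(colloids) {
    ff$calls <- ff$calls + 1L
    if (ff$calls >= kill_at) ff$killed <- TRUE
    replicate(nrow(colloids), act, simplify = FALSE)
  }
  ff$kill_switch <- function() ff$killed
  ff$finalize <- function(colloids) invisible(NULL)
  ff$reset_episode <- function() invisible(NULL)
  class(ff) <- "force_function"
  ff
}

# a policy whose forward pass deterministically prefers one action: zero
# weights everywhere, a large bias on the chosen logit
biased_policy <- function(input_dim, n_actions, prefer = 1L) {
  pol <- policy_network(input_dim, n_actions, hidden = c(4),
                        zero_final = TRUE)
  b <- numeric(n_actions)
  b[prefer] <- 50
  pol$params$actor[[1]]$b <- b
  pol
}

# simple 2D state constructors
grid_state <- function(pos, dirs = NULL, type = 0L) {
  n <- nrow(pos)
  if (is.null(dirs)) dirs <- matrix(rep(c(1, 0), each = n), n, 2)
  colloid_state(seq_len(n) - 1L, rep(as.integer(type), n), pos, dirs)
}
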