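# Training mathematics: returns, advantages, GAE, losses, updates, networks.

test_that("expected returns satisfy the discounted-sum definition", {
  expect_equal(expected_returns(c(1, 1, 1), 1), c(3, 2, 1))
  r <- c(0.3, -1, 2, 0.5)
  expect_equal(expected_returns(r, 0), r)
  expect_equal(expected_returns(c(1, 0, 2), 0.5), c(1.5, 1.0, 2.0))
  expect_error(expected_returns(numeric(0), 0.9), "empty")
  # recursion G_t = r_t + gamma G_{t+1} holds exactly
  set.seed(2)
  r <- rnorm(30)
  G <- expected_returns(r, 0.93)
  expect_equal(G[-30], r[-30] + 0.93 * G[-1], tolerance = 1e-14)
})

test_that("expected returns match the brute-force double loop", {
  set.seed(10)
  for (i in 1:200) {
    T_ <- sample(1:50, 1)
    r <- rnorm(T_)
    g <- runif(1)
    expect_equal(expected_returns(r, g), brute_force_returns(r, g),
                 tolerance = 1e-10)
  }
})

test_that("advantage is G - V with an optional standardization", {
  G <- c(1.5, 1, 2)
  expect_equal(advantage(G, G), c(0, 0, 0))
  expect_equal(advantage(G, rep(0, 3)), G)
  expect_equal(advantage(G, c(1, 1, 1)), c(0.5, 0, 1))
  A <- advantage(rnorm(50), rnorm(50), standardize = TRUE)
  expect_equal(mean(A), 0, tolerance = 1e-12)
  expect_equal(sd(A), 1, tolerance = 1e-12)
  expect_error(advantage(1:3, 1:2), "mismatch")
})

test_that("GAE limits: lambda=1 telescopes to G - V, lambda=0 is the TD error", {
  set.seed(3)
  for (i in 1:50) {
    T_ <- sample(2:20, 1)
    r <- rnorm(T_); v <- rnorm(T_)
    g <- runif(1)
    expect_equal(gae(r, v, g, 1), expected_returns(r, g) - v,
                 tolerance = 1e-12)
    delta <- r + g * c(v[-1], 0) - v
    expect_equal(gae(r, v, g, 0), delta, tolerance = 1e-12)
  }
})

test_that("GAE matches the brute-force summation on random sequences", {
  set.seed(4)
  for (i in 1:100) {
    T_ <- 20
    r <- rnorm(T_); v <- rnorm(T_)
    expect_equal(gae(r, v, 0.99, 0.95),
                 brute_force_gae(r, v, 0.99, 0.95), tolerance = 1e-10)
  }
})

test_that("policy-gradient loss has the right value, sign and gradient", {
  expect_equal(vpg_loss(log(c(0.5, 0.5)), c(0, 0)), 0)
  expect_equal(vpg_loss(log(0.25), 2), -2 * log(0.25))
  expect_error(vpg_loss(c(NA, 0), c(1, 1)), "NaN")
  # one positive-advantage update strictly increases the taken action's
  # probability; negative advantage decreases it
  for (Aval in c(1, -1)) {
    set.seed(5)
    pol <- policy_network(2, 3, hidden = c(8))
    x <- matrix(c(0.3, -0.2), 1)
    p0 <- policy_forward(pol, x)$probs[1, 2]
    fwd <- policy_forward(pol, x)
    g <- swarmlearn:::loss_grads(fwd$probs, fwd$value, 2L, Aval, 0,
                                 training_hyperparams(entropy_coef = 0,
                                                      algorithm = "vpg",
                                                      value_coef = 0))
    grads <- swarmlearn:::policy_backward(pol, fwd$cache, g$dlogits, g$dvalue)
    upd <- update_params(pol$params,
                         swarmlearn:::tree_map(function(x) -x, grads),
                         1e-3, method = "sgd")
    pol$params <- upd$params
    p1 <- policy_forward(pol, x)$probs[1, 2]
    if (Aval > 0) expect_gt(p1, p0) else expect_lt(p1, p0)
  }
})

test_that("PPO loss reduces to the unclipped surrogate at ratio one and
           clips gradients outside the trust region", {
  set.seed(6)
  lp <- log(runif(10, 0.1, 0.9))
  A <- rnorm(10)
  expect_equal(ppo_loss(lp, lp, A, 0.2), -sum(A), tolerance = 1e-12)
  # clipped branch: rho = 1 + 2 eps with A > 0 contributes the clipped value
  eps <- 0.2
  lp_old <- log(0.2)
  lp_new <- lp_old + log(1 + 2 * eps)
  expect_equal(ppo_loss(lp_new, lp_old, 1, eps), -(1 + eps))
  # and its gradient w.r.t. the new log-prob is zero
  h <- 1e-7
  d <- (ppo_loss(lp_new + h, lp_old, 1, eps) -
          ppo_loss(lp_new - h, lp_old, 1, eps)) / (2 * h)
  expect_equal(d, 0)
  # pessimistic bound: loss >= negative unclipped surrogate
  for (i in 1:50) {
    lpo <- log(runif(5, 0.05, 0.95))
    lpn <- lpo + rnorm(5, sd = 0.5)
    Ai <- rnorm(5)
    expect_gte(ppo_loss(lpn, lpo, Ai, 0.2),
               -sum(exp(lpn - lpo) * Ai) - 1e-12)
  }
})

test_that("critic loss is the mean squared regression error", {
  G <- rnorm(10)
  expect_equal(critic_loss(G, G), 0)
  expect_equal(critic_loss(G + 1, G), 1)
  V <- rnorm(10)
  expect_equal(critic_loss(V, G), mean((V - G)^2), tolerance = 1e-12)
})

test_that("update rule implements plain gradient ascent and leaves
           parameters untouched for zero gradients or zero learning rate", {
  p <- list(a = matrix(1, 1, 1))
  g <- list(a = matrix(2, 1, 1))
  expect_equal(update_params(p, g, 0.1)$params$a[1, 1], 1.2)
  expect_equal(update_params(p, list(a = matrix(0, 1, 1)), 0.1)$params, p)
  expect_equal(update_params(p, g, 0)$params, p)
})

test_that("policy networks produce normalized probabilities and honest
           gradients in both shared and disjoint variants", {
  for (variant in c("shared", "disjoint")) {
    set.seed(7)
    pol <- policy_network(4, 5, hidden = c(8, 8), variant = variant,
                          zero_final = TRUE)
    X <- matrix(rnorm(400), 100, 4)
    fwd <- policy_forward(pol, X)
    # zero final weights -> uniform distribution
    expect_equal(fwd$probs, matrix(0.2, 100, 5), tolerance = 1e-12,
                 ignore_attr = TRUE)
    pol2 <- policy_network(4, 5, hidden = c(8, 8), variant = variant)
    f2 <- policy_forward(pol2, X)
    expect_equal(rowSums(f2$probs), rep(1, 100), tolerance = 1e-6)
    expect_true(all(f2$probs >= 0))
    # deterministic given params and input
    expect_identical(f2$probs, policy_forward(pol2, X)$probs)
    # finite-difference check of d log pi(a|s) / d theta for several weights
    x <- X[1, , drop = FALSE]
    a <- 3L
    fwd1 <- policy_forward(pol2, x)
    onehot <- matrix(0, 1, 5); onehot[1, a] <- 1
    gr <- swarmlearn:::policy_backward(pol2, fwd1$cache,
                                       onehot - fwd1$probs, 0)
    eps <- 1e-6
    probes <- list(c(1, 1, 2), c(1, 3, 4))
    for (pr in probes) {
      grp <- if (variant == "shared") "trunk" else "actor"
      w0 <- pol2$params[[grp]][[pr[1]]]$W[pr[2], pr[3]]
      pol2$params[[grp]][[pr[1]]]$W[pr[2], pr[3]] <- w0 + eps
      lp_p <- log(policy_forward(pol2, x)$probs[1, a])
      pol2$params[[grp]][[pr[1]]]$W[pr[2], pr[3]] <- w0 - eps
      lp_m <- log(policy_forward(pol2, x)$probs[1, a])
      pol2$params[[grp]][[pr[1]]]$W[pr[2], pr[3]] <- w0
      fd <- (lp_p - lp_m) / (2 * eps)
      an <- gr[[grp]][[pr[1]]]$W[pr[2], pr[3]]
      expect_equal(an, fd, tolerance = 1e-4)
    }
  }
})

test_that("sampled policy gradient is an unbiased estimate of the softmax
           bandit gradient", {
  # two-armed softmax bandit, gamma = 1: pi = softmax(z), rewards (1, 0);
  # analytic gradient of J = p1*1 + p2*0 w.r.t. z1 is p1*(1-p1)
  set.seed(8)
  z <- c(0.4, -0.3)
  p <- exp(z) / sum(exp(z))
  n <- 1e4
  arms <- sample.int(2, n, replace = TRUE, prob = p)
  rewards <- ifelse(arms == 1, 1, 0)
  # REINFORCE estimate: grad_z1 log pi(a) * r = (1[a=1] - p1) * r
  est <- (as.numeric(arms == 1) - p[1]) * rewards
  analytic <- p[1] * (1 - p[1])
  se <- sd(est) / sqrt(n)
  expect_lt(abs(mean(est) - analytic), 3 * se)
})

test_that("losses stay finite for probabilities clamped away from zero", {
  probs <- matrix(c(1 - 1e-12, 1e-12), 1)
  lp <- log_prob_of(probs, 2L)
  expect_true(is.finite(lp))
  expect_lte(lp, 0)
  expect_true(is.finite(vpg_loss(lp, 5)))
})
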