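#' Dense multilayer perceptrons (internal building block)
#'
#' Plain fully connected networks with tanh hidden activations and a linear
#' output layer, with hand-written backpropagation. These back the policy
#' (actor-critic) networks and the random-network-distillation pair. Weights
#' are initialized N(0, 1/fan_in); biases at zero.
#'
#' @param sizes integer vector of layer widths, input first, output last.
#' @param zero_final if TRUE the final layer's weights and biases are zero
#'   (useful to start from a uniform policy).
#' @return a list of layers, each `list(W, b)`.
#' @keywords internal
mlp_init <- function(sizes, zero_final = FALSE) {
  stopifnot(length(sizes) >= 2)
  L <- length(sizes) - 1
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    W <- matrix(stats::rnorm(fan_in * sizes[l + 1], sd = 1 / sqrt(fan_in)),
                fan_in, sizes[l + 1])
    b <- numeric(sizes[l + 1])
    if (zero_final && l == L) W[] <- 0
    layers[[l]] <- list(W = W, b = b)
  }
  layers
}

# forward pass; X is n x d_in. out_tanh: apply tanh to the final layer too
# (used for trunks). Returns list(out, cache).
mlp_forward <- function(layers, X, out_tanh = FALSE) {
  X <- as.matrix(X)
  L <- length(layers)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(X), length(layers[[l]]$b), byrow = TRUE)
    acts[[l + 1]] <- if (l < L || out_tanh) tanh(Z) else Z
  }
  list(out = acts[[L + 1]], cache = list(acts = acts, out_tanh = out_tanh))
}

# backward pass: dout is n x d_out gradient w.r.t. the network output.
# Returns list(grads = per-layer list(W, b), dX = n x d_in).
mlp_backward <- function(layers, cache, dout) {
  acts <- cache$acts
  L <- length(layers)
  grads <- vector("list", L)
  dZ <- if (cache$out_tanh) dout * (1 - acts[[L + 1]]^2) else dout
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], dZ), b = colSums(dZ))
    if (l > 1) {
      dA <- dZ %*% t(layers[[l]]$W)
      dZ <- dA * (1 - acts[[l]]^2)
    } else {
      dX <- dZ %*% t(layers[[l]]$W)
    }
  }
  list(grads = grads, dX = dX)
}

#' Actor-critic policy networks
#'
#' A policy maps a feature vector (observable) to a categorical distribution
#' over an action set plus a scalar state-value estimate. Two
#' parameterizations are available: `"shared"` uses one tanh trunk with a
#' linear actor head (|A| logits, softmax) and a linear critic head (1 unit);
#' `"disjoint"` uses two fully separate networks. Defaults: 2 hidden layers
#' of 128 tanh units each.
#'
#' @param input_dim observable dimension.
#' @param n_actions size of the action set.
#' @param hidden integer vector of hidden-layer widths.
#' @param variant "shared" (one trunk, two heads) or "disjoint".
#' @param zero_final zero-initialize the actor output layer (uniform initial
#'   policy) and critic output layer (zero initial values).
#' @return an object of class `policy_network` (a mutable environment holding
#'   parameters and, once training starts, optimizer state).
#' @export
policy_network <- function(input_dim, n_actions, hidden = c(128, 128),
                           variant = c("shared", "disjoint"),
                           zero_final = FALSE) {
  variant <- match.arg(variant)
  pol <- new.env(parent = emptyenv())
  pol$input_dim <- as.integer(input_dim)
  pol$n_actions <- as.integer(n_actions)
  pol$variant <- variant
  pol$hidden <- as.integer(hidden)
  if (variant == "shared") {
    pol$params <- list(
      trunk = mlp_init(c(input_dim, hidden)),
      actor = mlp_init(c(hidden[length(hidden)], n_actions),
                       zero_final = zero_final),
      critic = mlp_init(c(hidden[length(hidden)], 1),
                        zero_final = zero_final)
    )
  } else {
    pol$params <- list(
      actor = mlp_init(c(input_dim, hidden, n_actions),
                       zero_final = zero_final),
      critic = mlp_init(c(input_dim, hidden, 1), zero_final = zero_final)
    )
  }
  pol$opt_state <- NULL
  class(pol) <- "policy_network"
  pol
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Evaluate a policy network
#'
#' Deterministic given parameters and input: softmax action probabilities
#' (each row sums to 1) and an unbounded scalar value per input row.
#'
#' @param policy a [policy_network()].
#' @param X feature matrix (n x input_dim) or a single feature vector.
#' @return `list(probs = n x |A| matrix, value = length-n vector, cache)`.
#' @export
policy_forward <- function(policy, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != policy$input_dim)
    stop("feature dimension ", ncol(X), " does not match network input ",
         policy$input_dim)
  p <- policy$params
  if (policy$variant == "shared") {
    tr <- mlp_forward(p$trunk, X, out_tanh = TRUE)
    ac <- mlp_forward(p$actor, tr$out)
    cr <- mlp_forward(p$critic, tr$out)
    cache <- list(trunk = tr$cache, actor = ac$cache, critic = cr$cache)
    logits <- ac$out
    value <- as.vector(cr$out)
  } else {
    ac <- mlp_forward(p$actor, X)
    cr <- mlp_forward(p$critic, X)
    cache <- list(actor = ac$cache, critic = cr$cache)
    logits <- ac$out
    value <- as.vector(cr$out)
  }
  list(probs = softmax_rows(logits), value = value, logits = logits,
       cache = cache)
}

# gradient of a scalar loss w.r.t. all policy parameters, given gradients
# w.r.t. the actor logits (n x |A|) and the value outputs (length n).
policy_backward <- function(policy, cache, dlogits, dvalue) {
  p <- policy$params
  dvalue <- matrix(dvalue, ncol = 1)
  if (policy$variant == "shared") {
    ba <- mlp_backward(p$actor, cache$actor, dlogits)
    bc <- mlp_backward(p$critic, cache$critic, dvalue)
    bt <- mlp_backward(p$trunk, cache$trunk, ba$dX + bc$dX)
    list(trunk = bt$grads, actor = ba$grads, critic = bc$grads)
  } else {
    ba <- mlp_backward(p$actor, cache$actor, dlogits)
    bc <- mlp_backward(p$critic, cache$critic, dvalue)
    list(actor = ba$grads, critic = bc$grads)
  }
}

#' Log-probabilities with clamping
#'
#' Probabilities are bounded away from zero by 1e-8 before the log, so all
#' losses stay finite; log-probabilities are always <= 0.
#' @param probs probability matrix (rows sum to 1).
#' @param idx 1-based column index per row.
#' @return numeric vector of log pi(a|s), one per row.
#' @export
log_prob_of <- function(probs, idx) {
  p <- probs[cbind(seq_len(nrow(probs)), idx)]
  log(pmin(pmax(p, 1e-8), 1))
}

# ---- generic parameter-tree arithmetic (params are nested lists of W/b) ----

tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- vector("list", length(t1))
    names(out) <- names(t1)
    for (i in seq_along(t1))
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    out
  } else do.call(f, trees)
}

tree_zero <- function(tree) tree_map(function(x) x * 0, tree)

flatten_tree <- function(tree, prefix = "p") {
  if (is.list(tree)) {
    nms <- if (is.null(names(tree))) seq_along(tree) else names(tree)
    out <- list()
    for (i in seq_along(tree))
      out <- c(out, flatten_tree(tree[[i]], paste0(prefix, ".", nms[i])))
    out
  } else {
    stats::setNames(list(tree), prefix)
  }
}

#' Gradient-ascent parameter update
#'
#' Applies \eqn{\theta' = \theta + \eta g} (plain variant) or an Adam-style
#' adaptive step in the same ascent direction (default for training). Pure
#' function of its inputs and optimizer state.
#'
#' @param params parameter tree (nested lists of arrays).
#' @param grads gradient tree of the objective J (ascent direction), same
#'   structure.
#' @param eta learning rate.
#' @param method "sgd" (plain) or "adam".
#' @param state optimizer state from a previous call (NULL to initialize).
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return `list(params, state)`.
#' @export
update_params <- function(params, grads, eta, method = c("sgd", "adam"),
                          state = NULL, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8) {
  method <- match.arg(method)
  if (method == "sgd")
    return(list(params = tree_map(function(p, g) p + eta * g, params, grads),
                state = state))
  if (is.null(state))
    state <- list(m = tree_zero(params), v = tree_zero(params), t = 0L)
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) {
    p + eta * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

#' @export
print.policy_network <- function(x, ...) {
  cat("<policy_network> ", x$variant, ", input ", x$input_dim,
      " -> hidden (", paste(x$hidden, collapse = ", "), ") -> ",
      x$n_actions, " actions + value\n", sep = "")
  invisible(x)
}
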