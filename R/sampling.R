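#' Sample an action index from a categorical distribution
#'
#' Two equivalent strategies are provided: `"categorical"` draws by inverse
#' CDF; `"gumbel"` draws via the Gumbel-max trick,
#' \eqn{\arg\max_i (\log p_i + g_i)} with \eqn{g_i \sim} Gumbel(0, 1). Both
#' return index i with probability \eqn{p_i}.
#'
#' @param probs probability vector (non-negative, sums to 1 within 1e-6).
#' @param strategy "categorical" or "gumbel".
#' @return 1-based action index.
#' @export
sample_action <- function(probs, strategy = c("categorical", "gumbel")) {
  strategy <- match.arg(strategy)
  if (any(probs < 0) || any(!is.finite(probs)))
    stop("invalid probability vector")
  s <- sum(probs)
  if (s <= 0) stop("probabilities sum to zero")
  if (abs(s - 1) > 1e-6) stop("probabilities must sum to 1")
  if (strategy == "categorical") {
    u <- stats::runif(1)
    min(findInterval(u, cumsum(probs), left.open = TRUE) + 1L, length(probs))
  } else {
    g <- -log(-log(stats::runif(length(probs))))
    which.max(log(pmax(probs, 1e-300)) + g)
  }
}

# vectorized: one draw per row of a probability matrix
sample_actions_matrix <- function(probs, strategy = "categorical") {
  n <- nrow(probs)
  if (strategy == "categorical") {
    u <- stats::runif(n)
    cs <- t(apply(probs, 1, cumsum))
    pmin(as.integer(rowSums(cs < u) + 1L), ncol(probs))
  } else {
    g <- -log(-log(matrix(stats::runif(n * ncol(probs)), n)))
    max.col(log(pmax(probs, 1e-300)) + g, ties.method = "first")
  }
}
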