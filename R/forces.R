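#' Weeks-Chandler-Andersen pair force
#'
#' Purely repulsive Lennard-Jones-derived force, truncated and shifted at the
#' potential minimum \eqn{r_c = 2^{1/6}\sigma}: for \eqn{r < r_c} the force on
#' particle i from j has magnitude \eqn{24\epsilon(2\sigma^{12}/r^{13} -
#' \sigma^6/r^7)} directed along \eqn{r_{ij} = r_i - r_j}; it is identically
#' zero beyond the cutoff. Separations below \eqn{0.5\sigma} indicate a
#' near-singular overlap: the magnitude is capped at its value at
#' \eqn{0.5\sigma} and a warning is emitted.
#'
#' @param r_ij displacement vector from particle j to particle i.
#' @param eps interaction strength \eqn{\epsilon}.
#' @param sigma interaction diameter \eqn{\sigma}.
#' @return force vector on particle i (same length as `r_ij`).
#' @examples
#' wca_force(c(1, 0), eps = 1, sigma = 1)  # magnitude 24 along +x
#' @export
wca_force <- function(r_ij, eps = 1, sigma = 1) {
  r <- sqrt(sum(r_ij^2))
  if (r <= 0) stop("wca_force requires |r_ij| > 0")
  rc <- 2^(1 / 6) * sigma
  if (r >= rc) return(numeric(length(r_ij)))
  if (r < 0.5 * sigma) {
    warning("WCA overlap below 0.5 sigma; force capped")
    mag <- wca_magnitude(0.5 * sigma, eps, sigma)
  } else {
    mag <- wca_magnitude(r, eps, sigma)
  }
  mag * r_ij / r
}

wca_magnitude <- function(r, eps, sigma) {
  24 * eps * (2 * sigma^12 / r^13 - sigma^6 / r^7)
}

# Vectorized all-pairs WCA forces with optional periodic minimum image.
# pos: n x d matrix. Returns n x d matrix of net forces. O(n^2); intended for
# the interacting fixtures (n <= a few hundred).
pair_forces_wca <- function(pos, eps, sigma, box = NULL) {
  n <- nrow(pos)
  d <- ncol(pos)
  f <- matrix(0, n, d)
  if (n < 2) return(f)
  rc <- 2^(1 / 6) * sigma
  capped <- FALSE
  for (i in seq_len(n - 1)) {
    dx <- pos[rep(i, n - i), , drop = FALSE] -
      pos[(i + 1):n, , drop = FALSE]
    if (!is.null(box)) dx <- minimum_image(dx, box)
    r2 <- rowSums(dx^2)
    sel <- which(r2 < rc^2 & r2 > 0)
    if (!length(sel)) next
    r <- sqrt(r2[sel])
    rcap <- pmax(r, 0.5 * sigma)
    if (any(r < 0.5 * sigma)) capped <- TRUE
    mag <- wca_magnitude(rcap, eps, sigma)
    fij <- dx[sel, , drop = FALSE] * (mag / r)
    f[i, ] <- f[i, ] + colSums(fij)
    jj <- (i + sel)
    f[jj, ] <- f[jj, , drop = FALSE] - fij
  }
  if (capped) warning("WCA overlap below 0.5 sigma; force capped")
  f
}

#' Minimum-image displacement under periodic boundaries
#'
#' Wraps each component of a displacement into \eqn{[-L/2, L/2)} so pair
#' distances never exceed half the box diagonal.
#'
#' @param dx displacement vector or n x d matrix.
#' @param box numeric box edge lengths (length d).
#' @return wrapped displacement, same shape as `dx`.
#' @export
minimum_image <- function(dx, box) {
  if (is.matrix(dx)) {
    b <- matrix(box, nrow(dx), ncol(dx), byrow = TRUE)
  } else b <- box
  dx - b * round(dx / b)
}
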