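#' Gaussian chemoattractant concentration field
#'
#' A static, radially symmetric concentration profile
#' \deqn{c(x) = c_0 \exp(-|x - x_s|^2 / (2\sigma_c^2))}
#' used as the sensed chemical landscape in chemotaxis studies. The field is
#' positive everywhere and maximal at the source.
#'
#' @param source numeric source position (length d).
#' @param c0 amplitude at the source, > 0.
#' @param sigma decay length \eqn{\sigma_c}, > 0.
#' @return an object of class `concentration_field`.
#' @examples
#' f <- concentration_field(c(0, 0), c0 = 1, sigma = 1)
#' field_value(f, c(1, 0))  # exp(-0.5)
#' @export
concentration_field <- function(source, c0 = 1, sigma = 1) {
  stopifnot(is.numeric(source), length(source) >= 1,
            c0 > 0, sigma > 0, all(is.finite(source)))
  structure(list(source = as.numeric(source), c0 = c0, sigma = sigma,
                 form = "gaussian"),
            class = "concentration_field")
}

#' Evaluate a concentration field
#'
#' @param field a [concentration_field()].
#' @param x a position vector of length d, or an n x d matrix of positions.
#' @return scalar (vector input) or numeric vector of length n (matrix input).
#' @export
field_value <- function(field, x) {
  stopifnot(inherits(field, "concentration_field"))
  if (is.matrix(x)) {
    stopifnot(ncol(x) == length(field$source), all(is.finite(x)))
    d2 <- rowSums((x - matrix(field$source, nrow(x), ncol(x), byrow = TRUE))^2)
  } else {
    stopifnot(length(x) == length(field$source), all(is.finite(x)))
    d2 <- sum((x - field$source)^2)
  }
  field$c0 * exp(-d2 / (2 * field$sigma^2))
}

#' @export
print.concentration_field <- function(x, ...) {
  cat("<concentration_field> gaussian, c0 =", x$c0,
      "sigma =", x$sigma, "source = (",
      paste(signif(x$source, 4), collapse = ", "), ")\n")
  invisible(x)
}
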