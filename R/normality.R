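# Spearman rank correlation and the D'Agostino-Pearson omnibus normality test.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks).  With no
#' ties this equals the classical `1 - 6 * sum(d^2) / (n * (n^2 - 1))`
#' formula.
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be constant.
#' @return Correlation in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3), c(3, 1, 2)) # -0.5
spearman_rho <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop2("x and y lengths differ")
  if (length(x) < 3L) stop2("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop2("NA in input")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop2("Spearman correlation undefined for a constant vector")
  }
  stats::cor(rx, ry)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness transform and the Anscombe-Glynn kurtosis
#' transform into K-squared = Z1^2 + Z2^2, referred to a chi-square
#' distribution with 2 degrees of freedom.  Both transforms use the biased
#' sample moments (skewness `m3 / m2^1.5`, kurtosis `m4 / m2^2`), matching
#' the standard omnibus-test formulation.
#'
#' @param x Numeric vector, `n >= 8`, not constant.
#' @return Object of class `normality_result`: list with `k2_statistic`,
#'   `p_value`, `n`, `z_skewness`, `z_kurtosis`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop2("need at least 8 observations (got ", n, ")")
  if (anyNA(x)) stop2("NA in input")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop2("constant vector")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # Skewness: D'Agostino (1970) transformation to approximate normality.
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  # y = 0 (exactly symmetric sample) gives log(1) = 0: Z1 vanishes
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # Kurtosis: Anscombe & Glynn (1983) transformation.
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term2 <- sign(denom) * (abs((1 - 2 / a) / denom))^(1 / 3)
  z2 <- ((1 - 2 / (9 * a)) - term2) / sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  if (p == 0) p <- .Machine$double.xmin
  structure(list(k2_statistic = k2, p_value = p, n = n,
                 z_skewness = z1, z_kurtosis = z2),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("normality_result: K2 = %.4f, p = %.4g, n = %d\n",
              x$k2_statistic, x$p_value, x$n))
  invisible(x)
}
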