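#' @keywords internal
"_PACKAGE"

#' @importFrom stats var sd aov anova coef complete.cases cor cov dist
#'   fisher.test glm kmeans ks.test lm logLik mahalanobis pchisq pf plogis
#'   prcomp predict qchisq qnorm quantile rbinom rnorm runif setNames
#'   binom.test binomial wilcox.test qbeta fitted AIC approx fft reformulate
#' @importFrom utils read.csv write.csv modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integration on an arbitrary grid
#' @param x strictly increasing grid
#' @param y values at `x`
#' @return the integral as a scalar
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

stop_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == round(x) && x >= 0

## Linear interpolation of a curve onto a target grid; errors outside range.
interp_to_grid <- function(x, y, grid) {
  stop_if(min(grid) < min(x) - 1e-9 || max(grid) > max(x) + 1e-9,
          "grid [%g, %g] extends beyond curve support [%g, %g]",
          min(grid), max(grid), min(x), max(x))
  stats::approx(x, y, xout = grid, rule = 2)$y
}
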