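# Passing-Bablok method-comparison regression, implemented from scratch.
#
# Nonparametric fit of y = a + b x from the shifted median of all pairwise
# slopes; robust to outliers and free of distributional assumptions on the
# measurement errors. Used here to compare measured against expected
# (nominal) mast-cell percentages: a slope CI excluding 1 signals
# proportional bias, an intercept CI excluding 0 constant bias.

#' All pairwise slopes for a Passing-Bablok fit
#'
#' Computes `S_ij = (y_j - y_i) / (x_j - x_i)` for every pair `i < j` with
#' `x_i != x_j`. Slopes exactly equal to -1 are discarded (they carry no
#' information about the method relation under the procedure's symmetry
#' assumption); `K` counts the slopes below -1, which offsets the median so
#' the estimator stays equivariant under axis exchange.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, x not all identical.
#' @return List with `slopes` (sorted ascending) and `K`.
#' @export
pairwise_slopes <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("degenerate data: all x values identical", call. = FALSE)
  }
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- x[ij[, 2]] - x[ij[, 1]]
  dy <- y[ij[, 2]] - y[ij[, 1]]
  keep <- dx != 0
  s <- dy[keep] / dx[keep]
  s <- s[s != -1]
  list(slopes = sort(s), K = sum(s < -1))
}

shifted_median <- function(sorted_slopes, K) {
  n <- length(sorted_slopes)
  if (n %% 2 == 1) {
    sorted_slopes[(n + 1) / 2 + K]
  } else {
    mean(sorted_slopes[n / 2 + K + c(0L, 1L)])
  }
}

#' Fit a Passing-Bablok regression
#'
#' Slope is the K-shifted median of the sorted pairwise slopes; its
#' confidence bounds are the order statistics at ranks `M1 + K` and
#' `M2 + K`, where `M1 = round((N - C)/2)`, `M2 = N - M1 + 1` and
#' `C = z_{(1+gamma)/2} * sqrt(n(n-1)(2n+5)/18)` (normal approximation to
#' the Kendall-type rank statistic). The intercept is `median(y - b x)`, its
#' CI obtained by applying the same median to the slope CI bounds. Bias
#' flags are set when 1 falls outside the slope CI (proportional) or 0
#' outside the intercept CI (constant).
#'
#' @param x Reference / expected values.
#' @param y Test / measured values.
#' @param gamma Two-sided confidence level (default 0.95).
#' @return List of class `pb_fit` with `slope`, `slope_ci`, `intercept`,
#'   `intercept_ci`, `n_pairs`, `gamma`, `constant_bias`,
#'   `proportional_bias`.
#' @export
#' @examples
#' f <- pb_fit(c(1, 2, 3, 4), 2 * c(1, 2, 3, 4) + 1)
#' c(f$slope, f$intercept) # 2 1
pb_fit <- function(x, y, gamma = 0.95) {
  ps <- pairwise_slopes(x, y)
  s <- ps$slopes
  N <- length(s)
  b <- shifted_median(s, ps$K)
  n <- length(x)
  C <- qnorm((1 + gamma) / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  lo_idx <- M1 + ps$K
  hi_idx <- M2 + ps$K
  if (lo_idx < 1 || hi_idx > N) {
    stop("insufficient data for a ", gamma, " confidence interval (need ",
         "more pairs)", call. = FALSE)
  }
  b_lo <- s[lo_idx]
  b_hi <- s[hi_idx]
  a <- median(y - b * x)
  a_lo <- median(y - b_hi * x)
  a_hi <- median(y - b_lo * x)
  pb_result(slope = b, slope_ci = c(b_lo, b_hi),
            intercept = a, intercept_ci = c(a_lo, a_hi),
            n_pairs = n, gamma = gamma)
}

#' Construct a Passing-Bablok result from its components
#'
#' Low-level constructor; also usable to wrap externally reported slope and
#' intercept confidence intervals so that [assess_bias()] can render their
#' verdicts.
#'
#' @param slope,intercept Point estimates.
#' @param slope_ci,intercept_ci Length-2 `(low, high)` confidence bounds.
#' @param n_pairs Number of (x, y) pairs.
#' @param gamma Confidence level.
#' @return A list of class `pb_fit`.
#' @export
pb_result <- function(slope, slope_ci, intercept, intercept_ci,
                      n_pairs = NA_integer_, gamma = 0.95) {
  stopifnot(length(slope_ci) == 2, length(intercept_ci) == 2)
  if (!(slope_ci[1] <= slope && slope <= slope_ci[2])) {
    stop("slope must lie inside slope_ci", call. = FALSE)
  }
  if (!(intercept_ci[1] <= intercept && intercept <= intercept_ci[2])) {
    stop("intercept must lie inside intercept_ci", call. = FALSE)
  }
  structure(list(
    slope = slope, slope_ci = as.numeric(slope_ci),
    intercept = intercept, intercept_ci = as.numeric(intercept_ci),
    n_pairs = n_pairs, gamma = gamma,
    proportional_bias = !(slope_ci[1] <= 1 && 1 <= slope_ci[2]),
    constant_bias = !(intercept_ci[1] <= 0 && 0 <= intercept_ci[2])
  ), class = "pb_fit")
}

#' Bias verdicts from a Passing-Bablok fit
#'
#' The agreement is considered good when the slope CI contains 1 and the
#' intercept CI contains 0. A slope CI entirely above 1 indicates
#' proportional overestimation by the test method; entirely below 1,
#' underestimation.
#'
#' @param result A `pb_fit`.
#' @return List with `proportional_bias`, `constant_bias`, `direction`
#'   (`"overestimation"`, `"underestimation"` or `"none"`) and `good_fit`.
#' @export
assess_bias <- function(result) {
  stopifnot(inherits(result, "pb_fit"))
  direction <- if (!result$proportional_bias) "none"
  else if (result$slope > 1) "overestimation"
  else "underestimation"
  list(proportional_bias = result$proportional_bias,
       constant_bias = result$constant_bias,
       direction = direction,
       good_fit = !result$proportional_bias && !result$constant_bias)
}

#' @export
print.pb_fit <- function(x, ...) {
  ci <- function(v) sprintf("(%s CI: %.3f to %.3f)", format(x$gamma),
                            v[1], v[2])
  cat("<pb_fit> n = ", x$n_pairs, "\n",
      "  slope:     ", sprintf("%.3f ", x$slope), ci(x$slope_ci), "\n",
      "  intercept: ", sprintf("%.3f ", x$intercept), ci(x$intercept_ci),
      "\n", sep = "")
  v <- assess_bias(x)
  cat("  bias: ",
      if (v$good_fit) "none (good fit)"
      else paste0(if (v$proportional_bias)
        paste0("proportional (", v$direction, ") ") else "",
        if (v$constant_bias) "constant" else ""), "\n", sep = "")
  invisible(x)
}
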