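# Rank-score dual weights for the intercept-only (restricted) quantile fit
# of r at level tau: solve max r'a s.t. sum(a) = (1 - tau) n, a in [0,1]^n.
# Observations above the tau-quantile get 1, below get 0; the group tied at
# the marginal value shares the remaining budget equally.
rank_scores <- function(r, tau) {
  n <- length(r)
  budget <- (1 - tau) * n
  a <- numeric(n)
  if (budget <= 1e-12) return(a)
  v <- sort(r, decreasing = TRUE)
  pos <- min(ceiling(budget - 1e-9), n)
  mv <- v[pos]                       # marginal (cutoff) value
  full <- r > mv
  tied <- r == mv
  a[full] <- 1
  a[tied] <- (budget - sum(full)) / sum(tied)  # ties share the remainder
  a
}

# GJKP regression rank-score statistic for H0: slope = b0 in the simple
# quantile regression of y on x at level tau (iid score form). Vectorized
# over b0. Asymptotically N(0,1) under H0.
rank_score_stat <- function(x, y, tau, b0 = 0) {
  xc <- x - mean(x)
  denom <- sqrt(tau * (1 - tau) * sum(xc^2))
  vapply(b0, function(b) sum(xc * rank_scores(y - b * x, tau)) / denom,
         numeric(1))
}

#' Slope inference for a quantile-line fit
#'
#' Tests whether the slope of the \eqn{\tau}-th conditional-quantile line
#' differs from zero. The default `"rank"` method is the regression
#' rank-score test (iid form) with a confidence interval obtained by
#' inverting the test over the pairwise-slope breakpoints — the small-sample
#' standard for quantile regression. `"xy-bootstrap"` resamples (x, y) pairs
#' and reports a percentile interval.
#'
#' The significance flag equals "the confidence interval excludes zero";
#' for the rank method this is identical to rejecting at `alpha`, because
#' the interval is the acceptance region of the same statistic.
#'
#' @param x,y data (trait, climate).
#' @param tau quantile level in (0, 1).
#' @param method `"rank"` (default) or `"xy-bootstrap"`.
#' @param alpha significance level for the CI (default 0.05).
#' @param n_boot bootstrap replicates (bootstrap method only; minimum 100).
#' @param seed integer seed for the bootstrap resampling.
#' @param ci compute the confidence interval (rank method; the p-value alone
#'   is much cheaper for large simulation studies).
#' @return List with `p_value`, `ci` (length-2, possibly infinite),
#'   `significant`, `method`, `alpha`, `statistic` (rank method), `slope`.
#' @examples
#' set.seed(1)
#' x <- rnorm(48); y <- 2 * x + rnorm(48, sd = 0.1)
#' slope_inference(x, y, 0.95)$significant   # TRUE
#' @export
slope_inference <- function(x, y, tau, method = c("rank", "xy-bootstrap"),
                            alpha = 0.05, n_boot = 500L, seed = NULL,
                            ci = TRUE) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  fit <- fit_quantile(x, y, tau)
  if (method == "rank") {
    z <- stats::qnorm(1 - alpha / 2)
    t0 <- rank_score_stat(x, y, tau, 0)
    p <- 2 * stats::pnorm(-abs(t0))
    interval <- c(-Inf, Inf)
    if (ci) interval <- rank_inversion_ci(x, y, tau, z)
    list(p_value = p, ci = interval, significant = abs(t0) >= z,
         method = "rank", alpha = alpha, statistic = t0, slope = fit$slope)
  } else {
    if (n_boot < 100L) stop("slope_inference: n_boot must be at least 100")
    if (!is.null(seed)) set.seed(seed)
    n <- length(x)
    bs <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(x[idx])) < 2L) return(NA_real_)
      fit_quantile(x[idx], y[idx], tau)$slope
    })
    bs <- bs[is.finite(bs)]
    interval <- unname(stats::quantile(bs, c(alpha / 2, 1 - alpha / 2),
                                       type = 1))
    p <- 2 * min(mean(bs <= 0), mean(bs >= 0))
    list(p_value = p, ci = interval,
         significant = interval[1] > 0 || interval[2] < 0,
         method = "xy-bootstrap", alpha = alpha, statistic = NA_real_,
         slope = fit$slope)
  }
}

# Invert the rank-score test over candidate slopes b0. The statistic is a
# step function of b0, constant between pairwise slopes (y_j - y_i)/(x_j -
# x_i); evaluate at interval midpoints and return the breakpoints bounding
# the acceptance region {b0 : |T(b0)| < z}.
rank_inversion_ci <- function(x, y, tau, z) {
  pr <- utils::combn(length(x), 2L)
  dx <- x[pr[2L, ]] - x[pr[1L, ]]
  ok <- abs(dx) > 1e-12
  s <- sort(unique((y[pr[2L, ok]] - y[pr[1L, ok]]) / dx[ok]))
  K <- length(s)
  step <- max(diff(range(s)), 1)
  mids <- c(s[1L] - step,
            if (K > 1L) (s[-K] + s[-1L]) / 2,
            s[K] + step)
  tt <- rank_score_stat(x, y, tau, mids)
  acc <- which(abs(tt) < z)
  if (!length(acc)) {
    # acceptance region thinner than one interval: degenerate at the
    # breakpoint where T changes sign
    k <- which.min(abs(tt))
    return(c(s[max(k - 1L, 1L)], s[min(k, K)]))
  }
  lo <- if (min(acc) == 1L) -Inf else s[min(acc) - 1L]
  hi <- if (max(acc) == length(mids)) Inf else s[max(acc)]
  c(lo, hi)
}
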