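#' Pinball (check) loss
#'
#' The asymmetric absolute loss \eqn{\rho_\tau(u) = u(\tau - 1[u < 0])} whose
#' minimizer over a location parameter is the \eqn{\tau}-th quantile. This is
#' the objective minimized by all quantile-line fits in the package.
#'
#' @param residuals numeric vector of residuals \eqn{u_i}.
#' @param tau quantile level, strictly between 0 and 1.
#' @return Total loss \eqn{\sum_i \rho_\tau(u_i)} (a single nonnegative number).
#' @examples
#' pinball_loss(c(1, -1), 0.5)   # 1
#' pinball_loss(1, 0.95)         # 0.95
#' pinball_loss(-1, 0.95)        # 0.05
#' @export
pinball_loss <- function(residuals, tau) {
  stopifnot(is.numeric(residuals), length(tau) == 1L, tau > 0, tau < 1)
  sum(residuals * (tau - (residuals < 0)))
}

#' Fit a conditional-quantile line by exact linear programming
#'
#' Minimizes the pinball loss \eqn{\sum_i \rho_\tau(y_i - a - b x_i)} over
#' intercept \eqn{a} and slope \eqn{b} with a dense primal simplex on the
#' standard LP formulation (residual split into positive/negative parts).
#' The optimum is exact: it is attained at a basic solution, i.e. a line
#' interpolating two data points, so the fitted loss never exceeds the loss
#' of any line through two observations (see [fit_quantile_enum()] for the
#' enumeration reference).
#'
#' @param x predictor (trait) values; must not be constant.
#' @param y response (climate) values.
#' @param tau quantile level in (0, 1).
#' @return An object of class `"quantile_fit"`: a list with elements
#'   `intercept`, `slope`, `tau`, `loss`, `n`, `fitted`, `residuals`, and
#'   `frac_below` (share of observations strictly below the line).
#' @seealso [slope_inference()] for inference on the slope, [dqr()] for the
#'   full six-quantile fit.
#' @examples
#' x <- 1:8; y <- 2 * x + 1
#' f <- fit_quantile(x, y, 0.9)
#' c(f$intercept, f$slope)  # 1, 2 (exact interpolation, zero loss)
#' @export
fit_quantile <- function(x, y, tau) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(tau) == 1L, tau > 0, tau < 1)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("fit_quantile: need at least 3 complete observations")
  if (length(unique(x)) < 2L) stop("fit_quantile: predictor is constant")
  sol <- simplex_rq(x, y, tau)
  res <- y - sol$a - sol$b * x
  structure(list(intercept = sol$a, slope = sol$b, tau = tau,
                 loss = pinball_loss(res, tau), n = n,
                 fitted = sol$a + sol$b * x, residuals = res,
                 frac_below = mean(res < -1e-9)),
            class = "quantile_fit")
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("Quantile line (tau = %.2f, n = %d):\n", x$tau, x$n))
  cat(sprintf("  intercept %.6g  slope %.6g  pinball loss %.6g\n",
              x$intercept, x$slope, x$loss))
  invisible(x)
}

# Dense primal simplex for the quantile-regression LP:
#   min tau * 1'u + (1 - tau) * 1'v
#   s.t. a+ - a- + (b+ - b-) x + u - v = y,  all variables >= 0.
# Columns: a+, a-, b+, b-, u_1..u_n, v_1..v_n. The initial feasible basis
# takes u_i (y_i >= 0) or v_i (y_i < 0) per row. Dantzig pricing with a
# switch to Bland's rule after `bland_after` iterations guards against
# cycling under the heavy degeneracy typical of this LP.
simplex_rq <- function(x, y, tau, tol = 1e-9) {
  n <- length(y)
  m <- 2L * n + 4L
  A <- cbind(1, -1, x, -x, diag(n), -diag(n))
  cvec <- c(0, 0, 0, 0, rep(tau, n), rep(1 - tau, n))
  s <- ifelse(y >= 0, 1, -1)
  Tb <- A * s                      # B^{-1} A for the sign-diagonal basis
  xb <- y * s
  basis <- ifelse(y >= 0, 4L + seq_len(n), 4L + n + seq_len(n))
  max_iter <- 100L * n + 500L
  bland_after <- 20L * n + 100L
  for (it in seq_len(max_iter)) {
    red <- cvec - as.vector(cvec[basis] %*% Tb)
    neg <- which(red < -tol)
    if (!length(neg)) {
      z <- numeric(m); z[basis] <- xb
      return(list(a = z[1L] - z[2L], b = z[3L] - z[4L],
                  loss = sum(cvec[basis] * xb)))
    }
    j <- if (it > bland_after) neg[1L] else neg[which.min(red[neg])]
    col <- Tb[, j]
    cand <- which(col > tol)
    if (!length(cand)) stop("simplex_rq: unbounded LP (should not happen)")
    ratio <- xb[cand] / col[cand]
    rmin <- min(ratio)
    tiers <- cand[ratio <= rmin + tol]
    r <- tiers[which.min(basis[tiers])]   # Bland-style tie break
    piv <- col[r]
    Tb[r, ] <- Tb[r, ] / piv
    xb[r] <- xb[r] / piv
    other <- setdiff(seq_len(n), r)
    if (length(other)) {
      Tb[other, ] <- Tb[other, ] - outer(col[other], Tb[r, ])
      xb[other] <- xb[other] - col[other] * xb[r]
    }
    xb[xb < 0 & xb > -tol] <- 0
    basis[r] <- j
  }
  stop("simplex_rq: iteration limit reached")
}

#' Reference quantile-line fit by point-pair enumeration
#'
#' Exhaustively evaluates the pinball loss of every line through two data
#' points with distinct predictor values and returns the minimizer. Because
#' an optimal basic solution of the quantile-regression LP interpolates two
#' observations, this enumeration is exact; it serves as an independent
#' reference for [fit_quantile()] at small n (cost is O(n^3)).
#'
#' @inheritParams fit_quantile
#' @return List with `intercept`, `slope`, `loss`.
#' @export
fit_quantile_enum <- function(x, y, tau) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  pairs <- utils::combn(length(x), 2L)
  dx <- x[pairs[2L, ]] - x[pairs[1L, ]]
  ok <- abs(dx) > 0
  if (!any(ok)) stop("fit_quantile_enum: predictor is constant")
  b <- (y[pairs[2L, ok]] - y[pairs[1L, ok]]) / dx[ok]
  a <- y[pairs[1L, ok]] - b * x[pairs[1L, ok]]
  loss <- vapply(seq_along(b),
                 function(k) pinball_loss(y - a[k] - b[k] * x, tau),
                 numeric(1))
  k <- which.min(loss)
  list(intercept = a[k], slope = b[k], loss = loss[k])
}
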