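default_taus <- function() c(0.05, 0.10, 0.50, 0.55, 0.90, 0.95)

#' Double quantile regression of climate on a trait
#'
#' Fits the conditional-quantile lines of a climate variable on a site-mean
#' trait at the lower (0.05, 0.10), central (0.50, 0.55) and upper (0.90,
#' 0.95) quantiles — the "double" refers to modelling both climate extremes
#' around the median niche. Each line minimizes the pinball loss exactly
#' ([fit_quantile()]); the slope of each line gets a rank-score test and
#' rank-inversion confidence interval ([slope_inference()]). Crossing of
#' fitted lines inside the observed trait range is detected and flagged,
#' never corrected.
#'
#' @param formula model formula `climate ~ trait` (one predictor).
#' @param data data.frame of site means (see [site_means()]).
#' @param taus quantile levels; default `c(0.05, 0.10, 0.50, 0.55, 0.90,
#'   0.95)`.
#' @param alpha significance level for slope inference.
#' @param method inference method, `"rank"` or `"xy-bootstrap"`.
#' @param standardize z-score both variables before fitting (coefficients
#'   are then in SD units); raw-unit coefficients can always be recovered by
#'   the usual back-transformation `b_raw = b_std * sd(y) / sd(x)`.
#' @param n_boot,seed bootstrap controls (bootstrap method only).
#' @param ci compute rank-inversion confidence intervals (default TRUE;
#'   setting FALSE keeps the significance flag and p-value but skips the
#'   interval, which is the expensive part in large simulation studies).
#' @return Object of class `"dqr"`: list with `fits` (data.frame, one row
#'   per tau: `tau`, `intercept`, `slope`, `p_value`, `ci_lower`,
#'   `ci_upper`, `significant`, `loss`), `trait`, `climate`, `n`,
#'   `standardize`, `crossing`, the model data `x`/`y` and scaling info.
#' @examples
#' set.seed(1)
#' d <- data.frame(trait = rnorm(48))
#' d$clim <- d$trait + rnorm(48, sd = 0.5)
#' m <- dqr(clim ~ trait, d)
#' coef(m)
#' @export
dqr <- function(formula, data, taus = default_taus(), alpha = 0.05,
                method = c("rank", "xy-bootstrap"), standardize = FALSE,
                n_boot = 500L, seed = NULL, ci = TRUE) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  if (ncol(mf) != 2L)
    stop("dqr: formula must be 'climate ~ trait' with a single predictor")
  yname <- names(mf)[1L]; xname <- names(mf)[2L]
  y <- mf[[1L]]; x <- mf[[2L]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 10L) stop("dqr: need at least 10 pairwise-complete observations")
  scale_info <- list(mx = mean(x), sx = stats::sd(x),
                     my = mean(y), sy = stats::sd(y))
  if (standardize) { x <- zscore(x); y <- zscore(y) }
  rows <- lapply(taus, function(tt) {
    f <- fit_quantile(x, y, tt)
    inf <- slope_inference(x, y, tt, method = method, alpha = alpha,
                           n_boot = n_boot, seed = seed, ci = ci)
    data.frame(tau = tt, intercept = f$intercept, slope = f$slope,
               p_value = inf$p_value, ci_lower = inf$ci[1],
               ci_upper = inf$ci[2], significant = inf$significant,
               loss = f$loss)
  })
  fits <- do.call(rbind, rows)
  structure(list(fits = fits, trait = xname, climate = yname, n = n,
                 taus = taus, alpha = alpha, method = method,
                 standardize = standardize, x = x, y = y,
                 scale_info = scale_info,
                 crossing = detect_crossing(fits, range(x)),
                 call = match.call()),
            class = "dqr")
}

# The outer fitted lines (lowest vs highest tau) cross inside [lo, hi] iff
# the upper-quantile line dips below the lower one at either end of the
# observed trait range (lines are straight, so endpoint checks suffice).
detect_crossing <- function(fits, xr, tol = 1e-9) {
  i <- which.min(fits$tau); j <- which.max(fits$tau)
  if (i == j) return(FALSE)
  d_lo <- (fits$intercept[j] + fits$slope[j] * xr[1]) -
    (fits$intercept[i] + fits$slope[i] * xr[1])
  d_hi <- (fits$intercept[j] + fits$slope[j] * xr[2]) -
    (fits$intercept[i] + fits$slope[i] * xr[2])
  min(d_lo, d_hi) < -tol
}

#' Fit one trait-climate double quantile set from a site-mean table
#'
#' Convenience wrapper around [dqr()] taking column names instead of a
#' formula.
#'
#' @param data site-mean table (see [site_means()]).
#' @param trait,climate column names.
#' @inheritParams dqr
#' @return A `"dqr"` object.
#' @export
fit_double <- function(data, trait, climate, taus = default_taus(),
                       alpha = 0.05, method = "rank", standardize = FALSE,
                       ci = TRUE) {
  if (!trait %in% names(data)) stop("fit_double: no trait column '", trait, "'")
  if (!climate %in% names(data))
    stop("fit_double: no climate column '", climate, "'")
  m <- dqr(stats::as.formula(paste(climate, "~", trait)), data, taus = taus,
           alpha = alpha, method = method, standardize = standardize, ci = ci)
  m$trait <- trait; m$climate <- climate
  m
}

#' @export
print.dqr <- function(x, ...) {
  cat(sprintf("Double quantile regression: %s ~ %s (n = %d%s)\n",
              x$climate, x$trait, x$n,
              if (x$standardize) ", z-scored" else ""))
  tab <- x$fits
  tab$sig <- ifelse(tab$significant, "*", "")
  print(format(tab[, c("tau", "intercept", "slope", "p_value", "sig")],
               digits = 4), row.names = FALSE)
  if (x$crossing)
    cat("Note: fitted quantile lines cross inside the observed trait range\n")
  invisible(x)
}

#' @export
summary.dqr <- function(object, ...) {
  structure(list(dqr = object), class = "summary.dqr")
}

#' @export
print.summary.dqr <- function(x, ...) {
  m <- x$dqr
  print(m)
  cat(sprintf("Inference: %s, alpha = %g; CIs:\n", m$method, m$alpha))
  print(format(m$fits[, c("tau", "slope", "ci_lower", "ci_upper")],
               digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.dqr <- function(object, ...) {
  m <- as.matrix(object$fits[, c("intercept", "slope")])
  rownames(m) <- sprintf("tau=%.2f", object$fits$tau)
  m
}

#' Predicted conditional quantiles from a dqr fit
#'
#' @param object a `"dqr"` object.
#' @param newdata data.frame containing the trait column (or a numeric
#'   vector of trait values); defaults to the fitted data.
#' @param tau quantile level(s) to predict; must be among the fitted taus.
#' @param ... unused.
#' @return Matrix of predicted climate values, one column per tau.
#' @export
predict.dqr <- function(object, newdata = NULL, tau = object$taus, ...) {
  xv <- if (is.null(newdata)) object$x
  else if (is.numeric(newdata)) newdata
  else newdata[[object$trait]]
  if (is.null(xv)) stop("predict.dqr: newdata lacks column '", object$trait, "'")
  miss <- setdiff(tau, object$fits$tau)
  if (length(miss))
    stop("predict.dqr: tau not fitted: ", paste(miss, collapse = ", "))
  out <- sapply(tau, function(tt) {
    r <- object$fits[object$fits$tau == tt, ]
    r$intercept + r$slope * xv
  })
  out <- matrix(out, nrow = length(xv),
                dimnames = list(NULL, sprintf("tau=%.2f", tau)))
  out
}

#' @export
residuals.dqr <- function(object, tau = 0.50, ...) {
  r <- object$fits[abs(object$fits$tau - tau) < 1e-9, ]
  if (!nrow(r)) stop("residuals.dqr: tau not fitted: ", tau)
  object$y - (r$intercept + r$slope * object$x)
}

#' Plot a double quantile regression
#'
#' Scatter of climate against trait with the fitted quantile lines; solid
#' lines mark slopes whose confidence interval excludes zero, dashed lines
#' nonsignificant ones.
#'
#' @param x a `"dqr"` object.
#' @param taus which fitted lines to draw (default: outer pair and median).
#' @param ... passed to [graphics::plot()].
#' @export
plot.dqr <- function(x, taus = c(0.05, 0.50, 0.95), ...) {
  graphics::plot(x$x, x$y, xlab = x$trait, ylab = x$climate,
                 pch = 19, col = "grey40", ...)
  cols <- c("steelblue", "grey30", "firebrick")
  taus <- intersect(taus, x$fits$tau)
  for (i in seq_along(taus)) {
    r <- x$fits[x$fits$tau == taus[i], ]
    graphics::abline(r$intercept, r$slope,
                     col = cols[(i - 1L) %% length(cols) + 1L],
                     lwd = 2, lty = if (r$significant) 1 else 2)
  }
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("tau=%.2f", taus), lwd = 2,
                   col = cols[seq_along(taus)])
  invisible(x)
}

#' Fit all trait-climate double quantile regressions of a site-mean table
#'
#' @param data site-mean table.
#' @param traits trait column names (default: the four field traits or the
#'   `garden_`-prefixed set when `garden = TRUE`).
#' @param climates climate column names (default: all ENVIREM columns found).
#' @param garden fit the garden trait columns instead of the field ones.
#' @inheritParams dqr
#' @return List of `"dqr"` objects named `"trait:climate"`, with a tidy
#'   summary data.frame attached as attribute `"table"` (one row per
#'   trait x climate x tau; see [dqr_tidy()]).
#' @export
dqr_table <- function(data, traits = NULL, climates = NULL, garden = FALSE,
                      taus = default_taus(), alpha = 0.05, method = "rank",
                      standardize = TRUE, ci = TRUE) {
  if (is.null(traits))
    traits <- if (garden)
      intersect(paste0("garden_", c("growth_diameter", "leaf_area",
                                    "leaf_mass", "SLA")), names(data))
    else intersect(field_traits(), names(data))
  if (is.null(climates)) climates <- intersect(envirem_variables(),
                                               names(data))
  if (!length(traits)) stop("dqr_table: no trait columns found")
  if (!length(climates)) stop("dqr_table: no climate columns found")
  fits <- list()
  for (tr in traits) for (cl in climates) {
    fits[[paste(tr, cl, sep = ":")]] <-
      fit_double(data, tr, cl, taus = taus, alpha = alpha, method = method,
                 standardize = standardize, ci = ci)
  }
  attr(fits, "table") <- dqr_tidy(fits)
  fits
}

#' Tidy table of fitted quantile lines
#'
#' @param fits list of `"dqr"` objects (e.g. from [dqr_table()]).
#' @return data.frame, one row per trait x climate x tau.
#' @export
dqr_tidy <- function(fits) {
  do.call(rbind, lapply(fits, function(m) {
    cbind(data.frame(trait = m$trait, climate = m$climate, n = m$n,
                     standardized = m$standardize, crossing = m$crossing),
          m$fits)
  })) -> out
  rownames(out) <- NULL
  out
}
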