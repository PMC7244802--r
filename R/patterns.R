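pattern_labels <- function() c("aligned", "one_sided_upper",
                               "one_sided_lower", "reverse", "none")

label_from_flags <- function(sL, sU, gL, gU) {
  if (sL && sU) { if (gL == gU) "aligned" else "reverse" }
  else if (sU) "one_sided_upper"
  else if (sL) "one_sided_lower"
  else "none"
}

#' Classify a trait-climate response shape
#'
#' Maps the outer-quantile significance pattern of a fitted [dqr()] to the
#' response-shape taxonomy: *aligned* (rhombus; both outer slopes
#' significant, same sign — trait shifts the whole climate niche), *one-
#' sided* (wedge; exactly one outer slope significant — constraint at one
#' climate extreme), *reverse* (acute triangle; both significant, opposite
#' signs — double-sided constraint), *none*. The primary label uses the
#' outermost pair (tau = 0.05/0.95); repeating the rule on the 0.10/0.90
#' pair yields a robustness flag. Median (tau = 0.50) significance is
#' reported alongside but never enters the label.
#'
#' @param dq a `"dqr"` object containing fits at taus 0.05, 0.95 (and
#'   0.10/0.90 for the robustness flag, 0.50 for the median report).
#' @param alpha unused when the fits already carry significance at their
#'   own alpha; kept for explicitness.
#' @return Object of class `"response_pattern"`: list with `trait`,
#'   `climate`, `label`, `sign_lower`, `sign_upper` (signs of significant
#'   outer slopes, 0 otherwise), `median_significant`, `robust` (same label
#'   under the 0.10/0.90 pair), `crossing`.
#' @export
classify_pattern <- function(dq, alpha = dq$alpha) {
  stopifnot(inherits(dq, "dqr"))
  get_fit <- function(tt) {
    r <- dq$fits[abs(dq$fits$tau - tt) < 1e-9, ]
    if (!nrow(r)) stop("classify_pattern: fit at tau = ", tt, " missing")
    r
  }
  fL <- get_fit(0.05); fU <- get_fit(0.95)
  lab <- label_from_flags(fL$significant, fU$significant,
                          sign(fL$slope), sign(fU$slope))
  robust <- NA
  if (all(c(0.10, 0.90) %in% dq$fits$tau)) {
    rL <- get_fit(0.10); rU <- get_fit(0.90)
    robust <- label_from_flags(rL$significant, rU$significant,
                               sign(rL$slope), sign(rU$slope)) == lab
  }
  med <- if (0.50 %in% dq$fits$tau) get_fit(0.50)$significant else NA
  structure(list(trait = dq$trait, climate = dq$climate, label = lab,
                 sign_lower = if (fL$significant) sign(fL$slope) else 0,
                 sign_upper = if (fU$significant) sign(fU$slope) else 0,
                 median_significant = med, robust = robust,
                 crossing = dq$crossing),
            class = "response_pattern")
}

#' @export
print.response_pattern <- function(x, ...) {
  cat(sprintf("%s ~ %s: %s (lower sign %+d, upper sign %+d%s)\n",
              x$climate, x$trait, x$label, x$sign_lower, x$sign_upper,
              if (isTRUE(x$robust)) ", robust at 0.10/0.90" else ""))
  invisible(x)
}

#' Pattern table for a list of fits
#'
#' @param fits list of `"dqr"` objects (e.g. one trait against all climate
#'   variables, from [dqr_table()]).
#' @return data.frame with one row per fit: trait, climate, label, outer
#'   slope signs, median significance, robustness and crossing flags.
#' @export
pattern_table <- function(fits) {
  do.call(rbind, lapply(fits, function(m) {
    p <- classify_pattern(m)
    data.frame(trait = p$trait, climate = p$climate, label = p$label,
               sign_lower = p$sign_lower, sign_upper = p$sign_upper,
               median_significant = p$median_significant,
               robust = p$robust, crossing = p$crossing)
  })) -> out
  rownames(out) <- NULL
  out
}

#' Tally response patterns for one trait
#'
#' Counts shape labels across climate variables for a single trait; the
#' combined `one_sided` count (upper + lower wedges) is reported alongside
#' the full breakdown, matching how wedge tallies are usually quoted.
#'
#' @param patterns data.frame from [pattern_table()] (one trait, one row
#'   per climate variable) or a list of `"response_pattern"` objects.
#' @return data.frame with columns `label` and `count` over all five
#'   labels plus the `one_sided` sum; counts over the five primitive labels
#'   sum to the number of climate variables.
#' @export
summarize_patterns <- function(patterns) {
  if (is.list(patterns) && !is.data.frame(patterns))
    patterns <- do.call(rbind, lapply(patterns, function(p)
      data.frame(trait = p$trait, climate = p$climate, label = p$label)))
  if (!nrow(patterns))
    return(data.frame(label = character(0), count = integer(0)))
  if (length(unique(patterns$trait)) > 1L)
    stop("summarize_patterns: tally one trait at a time")
  if (anyDuplicated(patterns[, c("trait", "climate")]))
    stop("summarize_patterns: duplicate (trait, climate) entries")
  counts <- table(factor(patterns$label, levels = pattern_labels()))
  out <- data.frame(label = c(pattern_labels(), "one_sided"),
                    count = c(as.integer(counts),
                              as.integer(counts["one_sided_upper"] +
                                           counts["one_sided_lower"])))
  out
}

#' Classification accuracy against planted shapes
#'
#' Monte-Carlo recovery study: for each effect size, simulate `n_reps`
#' datasets of `n_sites` sites from a [shape_spec()] of the given target
#' shape, run the double quantile regression and classification, and record
#' how often the planted label is recovered. Within Monte-Carlo error the
#' recovery rate is non-decreasing in effect size.
#'
#' @param target_shape shape to plant (see [shape_spec()]).
#' @param n_sites sites per simulated dataset (default 48).
#' @param effect_grid effect sizes to scan.
#' @param n_reps simulated datasets per effect size (minimum 50).
#' @param seed integer seed.
#' @param alpha significance level used in classification.
#' @param method,n_boot inference method passed to [dqr()].
#' @param scale_ratio baseline-to-slope noise ratio `c/|d|` for shapes with
#'   a scale slope (wedges, triangles); the effective effect size of those
#'   shapes, since their recovery is invariant to joint rescaling of the
#'   planted slopes and noise.
#' @param family noise family of the planted shapes.
#' @param support trait support of the planted shapes (sites are truncated
#'   to it); must satisfy `scale_ratio > max(abs(support))` for shapes with
#'   a scale slope, or the implied quantile lines would cross.
#' @return data.frame with columns `effect`, `recovery` (rate in \[0, 1\]),
#'   `n_reps`.
#' @export
pattern_recovery_power <- function(target_shape, n_sites = 48L,
                                   effect_grid = c(0.25, 0.5, 1),
                                   n_reps = 100L, seed = 1L, alpha = 0.05,
                                   method = "rank", n_boot = 300L,
                                   scale_ratio = 3, family = "normal",
                                   support = c(-2.8, 2.8)) {
  if (n_reps < 50L) stop("pattern_recovery_power: n_reps must be >= 50")
  with_seed(seed, {
    rates <- vapply(effect_grid, function(eff) {
      spec <- study_shape(target_shape, eff, scale_ratio, family, support)
      hits <- vapply(seq_len(n_reps), function(i) {
        d <- simulate_shape_sites(spec, n_sites)
        m <- dqr(y ~ x, d, taus = c(0.05, 0.95), alpha = alpha,
                 method = method, n_boot = n_boot, ci = FALSE)
        classify_pattern(m)$label == target_shape
      }, logical(1))
      mean(hits)
    }, numeric(1))
    data.frame(effect = effect_grid, recovery = rates, n_reps = n_reps)
  })
}

# Shape spec for recovery studies: noise scale tied to the scale slope so
# the wedge/triangle stays valid (non-crossing) at any effect size.
study_shape <- function(target_shape, effect, scale_ratio, family,
                        support = c(-2.8, 2.8)) {
  if (target_shape == "none" || effect == 0)
    return(shape_spec("none", family = family, support = support))
  sp <- shape_spec(target_shape, effect = effect, scale = 1e6,
                   family = family, support = support)
  scale <- if (abs(sp$d) > 1e-12) scale_ratio * abs(sp$d) else 1 / effect
  shape_spec(target_shape, effect = effect, scale = scale, family = family,
             support = support)
}

# One dataset of site-level (trait, climate) pairs under a shape spec:
# x standard normal (truncated to the shape's support), y conditional on x.
simulate_shape_sites <- function(spec, n_sites) {
  x <- stats::rnorm(n_sites)
  x <- pmin(pmax(x, spec$support[1]), spec$support[2])
  u <- draw_u(n_sites, spec$family)
  data.frame(x = x, y = spec$a + spec$b * x + (spec$c + spec$d * x) * u)
}
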