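#' Genetic cline versus plasticity call for one climate limit
#'
#' Compares the field and common-garden quantile fits of the same climate
#' variable at the same limit (upper = tau 0.95, lower = tau 0.05), with the
#' field trait paired to its garden analog (DBH to annual growth diameter;
#' leaf traits to themselves). Both significant with the same slope sign is
#' evidence for a genetic cline; field-only significance is consistent with
#' phenotypic plasticity at that limit; garden-only and neither are reported
#' as such.
#'
#' @param field_fit,garden_fit `"dqr"` objects for the same climate variable
#'   (field and garden trait pairing).
#' @param limit `"upper"` (tau = 0.95) or `"lower"` (tau = 0.05).
#' @param alpha unused (fits carry their own significance); kept explicit.
#' @return Object of class `"cline_call"`: list with `trait` (field),
#'   `garden_trait`, `climate`, `limit`, `call` in
#'   `{genetic_cline, plasticity, garden_only, neither}`, and the two slope
#'   rows used.
#' @export
call_cline <- function(field_fit, garden_fit, limit = c("upper", "lower"),
                       alpha = field_fit$alpha) {
  limit <- match.arg(limit)
  stopifnot(inherits(field_fit, "dqr"), inherits(garden_fit, "dqr"))
  if (field_fit$climate != garden_fit$climate)
    stop("call_cline: fits are for different climate variables (",
         field_fit$climate, " vs ", garden_fit$climate, ")")
  tt <- if (limit == "upper") 0.95 else 0.05
  pick <- function(m) {
    r <- m$fits[abs(m$fits$tau - tt) < 1e-9, ]
    if (!nrow(r)) stop("call_cline: fit at tau = ", tt, " missing")
    r
  }
  fr <- pick(field_fit); gr <- pick(garden_fit)
  call <- if (fr$significant && gr$significant) {
    if (sign(fr$slope) == sign(gr$slope)) "genetic_cline" else "neither"
  } else if (fr$significant) "plasticity"
  else if (gr$significant) "garden_only"
  else "neither"
  structure(list(trait = field_fit$trait, garden_trait = garden_fit$trait,
                 climate = field_fit$climate, limit = limit, call = call,
                 field = fr, garden = gr),
            class = "cline_call")
}

#' @export
print.cline_call <- function(x, ...) {
  cat(sprintf("%s / %s ~ %s, %s limit: %s\n", x$trait, x$garden_trait,
              x$climate, x$limit, x$call))
  invisible(x)
}

#' Cline-call table over paired field/garden fits
#'
#' Runs [call_cline()] at both limits for every field trait with a garden
#' analog, across all climate variables present in both fit lists.
#'
#' @param field_fits,garden_fits lists of `"dqr"` objects named
#'   `"trait:climate"` (see [dqr_table()]).
#' @param pairing named character vector mapping field trait to garden trait
#'   column.
#' @return data.frame with one row per (trait, climate, limit).
#' @export
cline_table <- function(field_fits, garden_fits,
                        pairing = c(DBH = "garden_growth_diameter",
                                    leaf_area = "garden_leaf_area",
                                    leaf_mass = "garden_leaf_mass",
                                    SLA = "garden_SLA")) {
  rows <- list()
  for (tr in names(pairing)) {
    for (key in names(field_fits)) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
      if (parts[1L] != tr) next
      gkey <- paste(pairing[[tr]], parts[2L], sep = ":")
      if (!gkey %in% names(garden_fits)) next
      for (lim in c("upper", "lower")) {
        cc <- call_cline(field_fits[[key]], garden_fits[[gkey]], lim)
        rows[[length(rows) + 1L]] <-
          data.frame(trait = cc$trait, garden_trait = cc$garden_trait,
                     climate = cc$climate, limit = cc$limit, call = cc$call,
                     field_slope = cc$field$slope,
                     garden_slope = cc$garden$slope)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Consistent field/garden pairs (genetic clines)
#'
#' The subset of cline calls where field and garden quantile regressions
#' are significant in the same direction; exactly these (trait, climate,
#' limit) triples feed the constraint-mapping stage.
#'
#' @param calls data.frame from [cline_table()].
#' @return data.frame subset with `call == "genetic_cline"`.
#' @export
consistent_pairs <- function(calls) {
  out <- calls[calls$call == "genetic_cline", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Broad-sense heritability from clonal replicates
#'
#' One-way random-effects variance components by the method of moments:
#' between/within genotype mean squares with the unbalanced-design
#' correction `n0 = (N - sum(n_i^2)/N) / (k - 1)` for the effective
#' replicate number. `H2 = V_G / (V_G + V_E)` is the share of phenotypic
#' variance explained by genotype; a negative moment estimate of `V_G` is
#' clamped to zero and flagged.
#'
#' @param garden garden records (see [read_garden_table()]).
#' @param trait trait column name.
#' @return Object of class `"heritability"`: list with `trait`, `H2`,
#'   `V_G`, `V_E`, `n_genotypes`, `n_total`, `clamped`.
#' @export
heritability <- function(garden, trait) {
  if (!trait %in% names(garden))
    stop("heritability: no trait column '", trait, "'")
  v <- garden[[trait]]
  g <- garden$genotype_id[!is.na(v)]
  v <- v[!is.na(v)]
  ni <- table(g)
  if (sum(ni >= 2L) < 2L)
    stop("heritability: need at least 2 genotypes with >= 2 replicates")
  k <- length(ni); N <- length(v)
  gm <- tapply(v, g, mean)
  grand <- mean(v)
  msb <- sum(ni * (gm - grand)^2) / (k - 1)
  msw <- sum((v - gm[g])^2) / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  vg <- (msb - msw) / n0
  clamped <- vg < 0
  vg <- max(vg, 0)
  structure(list(trait = trait, H2 = vg / (vg + msw), V_G = vg, V_E = msw,
                 n_genotypes = k, n_total = N, clamped = clamped),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("Broad-sense heritability of %s: H2 = %.3f (V_G = %.4g, V_E = %.4g; %d genotypes, %d plants%s)\n",
              x$trait, x$H2, x$V_G, x$V_E, x$n_genotypes, x$n_total,
              if (x$clamped) "; V_G clamped at 0" else ""))
  invisible(x)
}

#' Heritability table for all garden traits
#'
#' @param garden garden records.
#' @param traits trait columns (default: the four garden traits present).
#' @return data.frame with one row per trait.
#' @export
heritability_table <- function(garden, traits = NULL) {
  if (is.null(traits))
    traits <- intersect(c("growth_diameter", "leaf_area", "leaf_mass",
                          "SLA"), names(garden))
  do.call(rbind, lapply(traits, function(tr) {
    h <- heritability(garden, tr)
    data.frame(trait = tr, H2 = h$H2, V_G = h$V_G, V_E = h$V_E,
               n_genotypes = h$n_genotypes, n_total = h$n_total,
               clamped = h$clamped)
  }))
}
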