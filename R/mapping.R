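mask_codes <- function() c(unconstrained = 0L, constrained = 1L,
                           no_go = 2L, out_of_range = 3L)

#' Invert a significant quantile line over gridded climate
#'
#' Solves the upper-limit constraint `y <= a + b x` (or the lower-limit
#' constraint `y >= a + b x`) for the trait x at every grid cell, turning a
#' fitted climate-on-trait quantile line into a per-cell trait bound. Slope
#' signs decide the bound direction; for the upper limit, `b < 0` yields a
#' trait *maximum* `(y - a)/b`, `b > 0` a trait *minimum* (cells demanding a
#' larger trait than ever observed are no-go), and `b = 0` a pure threshold
#' on the climate value. The lower limit mirrors this. Only significant fits
#' may be inverted — the consistency filter ([consistent_pairs()]) is the
#' caller's gate.
#'
#' @param fit one row of a `"dqr"` fit table (needs `intercept`, `slope`,
#'   `significant`) or a `"quantile_fit"`; coefficients must be in raw trait
#'   and climate units.
#' @param grid [climate_grid()] of the fitted climate variable.
#' @return Object of class `"trait_bound"`: list with `kind` per cell
#'   semantics (`"upper"` bound grid, `"lower"` bound grid, or
#'   `"threshold"`), matrices `upper`/`lower` (NA where no bound), logical
#'   matrix `feasible` for threshold constraints, and provenance fields.
#' @export
invert_upper <- function(fit, grid) {
  invert_limit(fit, grid, limit = "upper")
}

#' @rdname invert_upper
#' @export
invert_lower <- function(fit, grid) {
  invert_limit(fit, grid, limit = "lower")
}

invert_limit <- function(fit, grid, limit, tol = 1e-9) {
  stopifnot(inherits(grid, "climate_grid"))
  a <- fit$intercept; b <- fit$slope
  sig <- fit$significant %||% TRUE
  if (!isTRUE(sig))
    stop("invert_", limit, ": refusing to invert a non-significant fit; ",
         "filter with consistent_pairs() first")
  y <- grid$values
  up <- matrix(NA_real_, nrow(y), ncol(y))
  lo <- matrix(NA_real_, nrow(y), ncol(y))
  feas <- matrix(TRUE, nrow(y), ncol(y))
  if (abs(b) <= tol) {
    # threshold case: constraint is on the climate value alone
    feas <- if (limit == "upper") y <= a + tol else y >= a - tol
  } else {
    xstar <- (y - a) / b
    if (limit == "upper") {
      if (b < 0) up <- xstar else lo <- xstar
    } else {
      if (b > 0) up <- xstar else lo <- xstar
    }
  }
  structure(list(kind = if (abs(b) <= tol) "threshold"
                 else if (!all(is.na(up))) "upper" else "lower",
                 upper = up, lower = lo, feasible = feas,
                 climate = grid$varname, limit = limit,
                 intercept = a, slope = b, geometry = grid[c("xll", "yll",
                                                             "cellsize")]),
            class = "trait_bound")
}

#' Combine per-variable trait bounds into a constraint grid
#'
#' Per-cell minimum over all upper trait bounds, clamped to the observed
#' trait range — "the lowest trait value per cell identifies the strongest
#' climatic constraint". Cells whose combined maximum falls below the
#' observed trait minimum, whose required minimum exceeds the combined
#' maximum, or which violate any zero-slope threshold are no-go; cells
#' where no constraint bites carry the observed maximum and are flagged
#' unconstrained.
#'
#' @param bounds list of `"trait_bound"` objects (same grid geometry).
#' @param trait_range observed trait range `c(min, max)` in raw units.
#' @param trait trait name (provenance).
#' @return Object of class `"constraint_grid"`: list with `trait_max`
#'   (numeric matrix; NA on no-go / out-of-range cells), `mask` (integer
#'   matrix coded by [mask_codes()]: 0 unconstrained, 1 constrained, 2
#'   no-go, 3 out-of-range), `trait_range`, `geometry` and `provenance`.
#' @export
combine_constraints <- function(bounds, trait_range, trait = "trait") {
  if (!length(bounds)) stop("combine_constraints: need at least one bound")
  stopifnot(length(trait_range) == 2L, trait_range[1] <= trait_range[2])
  geo <- bounds[[1L]]$geometry
  dims <- dim(bounds[[1L]]$feasible)
  for (b in bounds) {
    if (!identical(dim(b$feasible), dims) ||
        abs(b$geometry$xll - geo$xll) > 1e-9 ||
        abs(b$geometry$yll - geo$yll) > 1e-9 ||
        abs(b$geometry$cellsize - geo$cellsize) > 1e-9)
      stop("combine_constraints: grid geometry mismatch")
  }
  tmax <- matrix(trait_range[2], dims[1L], dims[2L])
  tmin <- matrix(trait_range[1], dims[1L], dims[2L])
  ok <- matrix(TRUE, dims[1L], dims[2L])
  for (b in bounds) {
    ok <- ok & b$feasible
    up <- b$upper
    if (!all(is.na(up))) tmax <- pmin(tmax, up)
    lo <- b$lower
    if (!all(is.na(lo))) tmin <- pmax(tmin, lo)
  }
  no_go <- !ok | tmax < trait_range[1] - 1e-12 | tmin > tmax + 1e-12
  mask <- matrix(mask_codes()[["constrained"]], dims[1L], dims[2L])
  mask[tmax >= trait_range[2] - 1e-12] <- mask_codes()[["unconstrained"]]
  mask[no_go] <- mask_codes()[["no_go"]]
  tmax[no_go] <- NA_real_
  provenance <- lapply(bounds, function(b)
    list(climate = b$climate, limit = b$limit, intercept = b$intercept,
         slope = b$slope))
  structure(list(trait = trait, trait_max = tmax, mask = mask,
                 trait_range = trait_range, geometry = geo,
                 provenance = provenance),
            class = "constraint_grid")
}

#' @export
print.constraint_grid <- function(x, ...) {
  tab <- table(factor(names(mask_codes())[x$mask + 1L],
                      levels = names(mask_codes())))
  cat(sprintf("Constraint grid for %s (%d x %d cells):\n", x$trait,
              nrow(x$mask), ncol(x$mask)))
  print(tab)
  cat(sprintf("  trait_max range: [%g, %g] (observed range [%g, %g])\n",
              suppressWarnings(min(x$trait_max, na.rm = TRUE)),
              suppressWarnings(max(x$trait_max, na.rm = TRUE)),
              x$trait_range[1], x$trait_range[2]))
  cat("  constraints:", paste(vapply(x$provenance, function(p)
    paste0(p$climate, "/", p$limit), ""), collapse = ", "), "\n")
  invisible(x)
}

#' Mask cells outside the observed climate envelope
#'
#' Cells whose climate values fall outside the per-variable min--max
#' rectangle of the observed sites are outside the species' sampled climate
#' range and are removed from the prediction (out-of-range). Idempotent.
#'
#' @param cgrid a [combine_constraints()] result.
#' @param climate_grids named list of [climate_grid()]s covering at least
#'   the mapped variables.
#' @param site_climate site climate table (one row per site, columns for
#'   the mapped variables).
#' @param vars variables defining the envelope (default: those in the
#'   grid's provenance).
#' @return The `constraint_grid` with out-of-range cells masked and their
#'   `trait_max` removed.
#' @export
apply_envelope_mask <- function(cgrid, climate_grids, site_climate,
                                vars = NULL) {
  stopifnot(inherits(cgrid, "constraint_grid"))
  vars <- vars %||% unique(vapply(cgrid$provenance, `[[`, "", "climate"))
  out <- matrix(FALSE, nrow(cgrid$mask), ncol(cgrid$mask))
  for (v in vars) {
    if (!v %in% names(climate_grids))
      stop("apply_envelope_mask: no climate grid for '", v, "'")
    if (!v %in% names(site_climate))
      stop("apply_envelope_mask: no site climate column '", v, "'")
    rng <- range(site_climate[[v]], na.rm = TRUE)
    y <- climate_grids[[v]]$values
    out <- out | y < rng[1] - 1e-12 | y > rng[2] + 1e-12
  }
  cgrid$mask[out] <- mask_codes()[["out_of_range"]]
  cgrid$trait_max[out] <- NA_real_
  cgrid
}

#' Write and read a constraint map
#'
#' Serializes a [combine_constraints()] grid as a pair of ESRI ASCII grids
#' (`<path>_traitmax.asc`, float; `<path>_mask.asc`, integer codes per
#' [mask_codes()]) plus a JSON sidecar (`<path>_provenance.json`) carrying
#' the trait, observed range and the quantile-line provenance. No-go cells
#' are distinguishable from missing data by their mask code (2), while the
#' trait_max band stores them as nodata. The pair round-trips bit-exactly
#' through [read_map()].
#'
#' @param cgrid a `"constraint_grid"`.
#' @param path output path stem (no extension).
#' @return `path`, invisibly.
#' @export
write_map <- function(cgrid, path) {
  stopifnot(inherits(cgrid, "constraint_grid"))
  geo <- cgrid$geometry
  write_asc(climate_grid(cgrid$trait_max, geo$xll, geo$yll, geo$cellsize,
                         varname = "trait_max"),
            paste0(path, "_traitmax.asc"))
  write_asc(climate_grid(cgrid$mask + 0, geo$xll, geo$yll, geo$cellsize,
                         varname = "mask", nodata = -1),
            paste0(path, "_mask.asc"))
  jsonlite::write_json(list(trait = cgrid$trait,
                            trait_range = cgrid$trait_range,
                            provenance = cgrid$provenance),
                       paste0(path, "_provenance.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  tm <- read_asc(paste0(path, "_traitmax.asc"))
  mk <- read_asc(paste0(path, "_mask.asc"))
  meta <- jsonlite::read_json(paste0(path, "_provenance.json"),
                              simplifyVector = TRUE)
  structure(list(trait = meta$trait, trait_max = tm$values,
                 mask = matrix(as.integer(mk$values), nrow(mk$values)),
                 trait_range = meta$trait_range,
                 geometry = list(xll = tm$xll, yll = tm$yll,
                                 cellsize = tm$cellsize),
                 provenance = apply(meta$provenance, 1L, as.list)),
            class = "constraint_grid")
}

#' Map trait constraints from fitted quantile lines
#'
#' High-level wrapper: takes the tidy fit table (raw units), the consistent
#' (trait, climate, limit) triples, the climate grids and the observed
#' trait values, and produces the constraint grid for one trait, envelope-
#' masked.
#'
#' @param fit_table tidy fit table ([dqr_tidy()]) in raw units.
#' @param consistent data.frame of (trait, climate, limit) triples (see
#'   [consistent_pairs()]).
#' @param trait trait to map.
#' @param climate_grids named list of [climate_grid()]s.
#' @param site_climate site climate table for the envelope.
#' @param trait_values observed raw trait values (range defines clamping).
#' @return A `"constraint_grid"`, or `NULL` when no consistent pair exists
#'   for the trait.
#' @export
map_trait_constraints <- function(fit_table, consistent, trait,
                                  climate_grids, site_climate,
                                  trait_values) {
  use <- consistent[consistent$trait == trait, , drop = FALSE]
  if (!nrow(use)) return(NULL)
  bounds <- list()
  for (i in seq_len(nrow(use))) {
    cl <- use$climate[i]; lim <- use$limit[i]
    tt <- if (lim == "upper") 0.95 else 0.05
    row <- fit_table[fit_table$trait == trait & fit_table$climate == cl &
                       abs(fit_table$tau - tt) < 1e-9, ]
    if (!nrow(row))
      stop("map_trait_constraints: no fit row for ", trait, " ~ ", cl,
           " at tau ", tt)
    if (!cl %in% names(climate_grids))
      stop("map_trait_constraints: no climate grid for '", cl, "'")
    fn <- if (lim == "upper") invert_upper else invert_lower
    bounds[[length(bounds) + 1L]] <- fn(row[1L, ], climate_grids[[cl]])
  }
  cg <- combine_constraints(bounds, range(trait_values, na.rm = TRUE),
                            trait = trait)
  apply_envelope_mask(cg, climate_grids, site_climate)
}
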