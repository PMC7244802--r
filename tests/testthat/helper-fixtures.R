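# Shared fixtures and independent oracles, built in code at test time.

# Small random regression dataset.
rand_xy <- function(n, slope = 0, noise = 1) {
  x <- rnorm(n)
  list(x = x, y = slope * x + rnorm(n, sd = noise))
}

# Independent least-absolute-deviations oracle: golden-section over the
# slope of the profiled L1 objective (optimal intercept for fixed slope is
# the weighted median of y - b x), refined by a fine local grid. Used to
# cross-check the tau = 0.5 quantile fit without touching the LP path.
lad_oracle <- function(x, y) {
  prof <- function(b) sum(abs(y - b * x - median(y - b * x)))
  bs <- seq(-10, 10, length.out = 4001)
  b0 <- bs[which.min(vapply(bs, prof, numeric(1)))]
  bs2 <- seq(b0 - 0.02, b0 + 0.02, length.out = 2001)
  b <- bs2[which.min(vapply(bs2, prof, numeric(1)))]
  list(slope = b, loss = 0.5 * prof(b))
}

# Brute-force feasibility oracle for the mapping module: scan a dense trait
# grid per cell against all quantile-line constraints and report the
# maximum feasible trait (or no-go).
feasibility_oracle <- function(constraints, y_cells, trait_range,
                               n_grid = 10000L) {
  tgrid <- seq(trait_range[1], trait_range[2], length.out = n_grid)
  vapply(seq_len(nrow(y_cells)), function(ci) {
    ok <- rep(TRUE, n_grid)
    for (k in seq_along(constraints)) {
      cn <- constraints[[k]]
      yv <- y_cells[ci, k]
      line <- cn$intercept + cn$slope * tgrid
      ok <- ok & if (cn$limit == "upper") yv <= line + 1e-12
                 else yv >= line - 1e-12
    }
    if (!any(ok)) NA_real_ else max(tgrid[ok])
  }, numeric(1))
}

# Default synthetic field + garden + climate bundle at a given seed.
synth_bundle <- function(seed = 1L, n_watersheds = 16L,
                         genetics = genetic_model(), shapes = list()) {
  design <- transect_design(n_watersheds = n_watersheds, seed = seed)
  sites <- gen_transects(design)
  ft <- gen_field_traits(sites, shapes, genetics, seed = seed + 1L)
  climate <- gen_climate(sites, climate_model(), seed = seed + 2L)
  for (cl in setdiff(names(ft$site_climate), c("watershed", "band")))
    climate[[cl]] <- ft$site_climate[[cl]]
  garden <- gen_garden(ft$field, genetics, seed = seed + 3L)
  list(sites = sites, field = ft$field, truth = ft$truth,
       garden = garden, climate = climate)
}
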