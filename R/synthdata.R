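#' Names of the 15 ENVIREM-style climate variables
#'
#' The bioclimatic variables the data model carries: moisture (climatic
#' moisture index, Thornthwaite aridity), potential evapotranspiration
#' (annual, quarterly extremes, seasonality), thermal sums (growing degree
#' days), temperature extremes of the coldest/warmest month, thermicity and
#' continentality.
#'
#' @return Character vector of length 15.
#' @export
envirem_variables <- function() {
  c("climatic_moisture_index", "aridity_index_thornthwaite", "annual_PET",
    "continentality", "growing_degree_days0", "growing_degree_days5",
    "max_temp_coldest_month", "min_temp_warmest_month",
    "month_count_by_temp10", "PET_driest_quarter", "PET_wettest_quarter",
    "PET_coldest_quarter", "PET_warmest_quarter", "PET_seasonality",
    "thermicity_index")
}

#' Transect sampling design
#'
#' Describes an elevational-transect survey: watersheds scattered over a
#' latitude/longitude window, each holding `sites_per_watershed` sites at
#' strictly increasing elevation (low/mid/high for the default 3), with a
#' uniform-random number of genotypes per site. Defaults reproduce the
#' survey geometry of a 16-watershed Rocky Mountain transect study:
#' latitudes 33.7--45.4, longitudes -114.2 to -105.5, elevations
#' 1373--2808 m, 5--10 genotypes per site.
#'
#' @param n_watersheds number of watersheds (>= 1).
#' @param sites_per_watershed sites per transect (default 3).
#' @param genotypes_per_site integer range `c(min, max)` sampled uniformly.
#' @param lat_range,lon_range,elev_range numeric `c(min, max)` windows.
#' @param seed integer seed making the whole design reproducible.
#' @return Object of class `"transect_design"`.
#' @export
transect_design <- function(n_watersheds = 16L, sites_per_watershed = 3L,
                            genotypes_per_site = c(5L, 10L),
                            lat_range = c(33.7, 45.4),
                            lon_range = c(-114.2, -105.5),
                            elev_range = c(1373, 2808),
                            seed = 1L) {
  chk <- function(r, nm) {
    if (length(r) != 2L || !is.numeric(r) || r[1] > r[2])
      stop("transect_design: invalid ", nm, " (need c(min, max), min <= max)")
  }
  if (n_watersheds < 1L) stop("transect_design: n_watersheds must be >= 1")
  if (sites_per_watershed < 1L)
    stop("transect_design: sites_per_watershed must be >= 1")
  chk(lat_range, "lat_range"); chk(lon_range, "lon_range")
  chk(elev_range, "elev_range"); chk(genotypes_per_site, "genotypes_per_site")
  structure(list(n_watersheds = as.integer(n_watersheds),
                 sites_per_watershed = as.integer(sites_per_watershed),
                 genotypes_per_site = as.integer(genotypes_per_site),
                 lat_range = lat_range, lon_range = lon_range,
                 elev_range = elev_range, seed = as.integer(seed)),
            class = "transect_design")
}

#' Generate transect sites
#'
#' Draws one row per site: watershed id, elevation band, coordinates and
#' elevation. Within a watershed the elevation window is subdivided into
#' equal bands and one site drawn uniformly inside each, so elevations are
#' strictly increasing from low to high and always inside `elev_range`.
#'
#' @param design a [transect_design()].
#' @return data.frame with columns `watershed`, `band`, `lat`, `lon`,
#'   `elevation`, `n_genotypes` (one row per site).
#' @export
gen_transects <- function(design) {
  stopifnot(inherits(design, "transect_design"))
  k <- design$sites_per_watershed
  bands <- if (k == 3L) c("low", "mid", "high") else sprintf("band%02d", 1:k)
  with_seed(design$seed, {
    rows <- lapply(seq_len(design$n_watersheds), function(w) {
      lat <- stats::runif(1, design$lat_range[1], design$lat_range[2])
      lon <- stats::runif(1, design$lon_range[1], design$lon_range[2])
      # watershed-specific elevation window, then one site per equal band
      win <- sort(stats::runif(2, design$elev_range[1], design$elev_range[2]))
      if (diff(win) < 200) win <- pmin(pmax(mean(win) + c(-150, 150),
                                            design$elev_range[1]),
                                       design$elev_range[2])
      edges <- seq(win[1], win[2], length.out = k + 1L)
      elev <- stats::runif(k, edges[-(k + 1L)] + 1e-6, edges[-1L])
      data.frame(watershed = sprintf("W%02d", w), band = bands,
                 lat = lat + stats::runif(k, -0.02, 0.02),
                 lon = lon + stats::runif(k, -0.02, 0.02),
                 elevation = elev,
                 n_genotypes = {
                   g <- design$genotypes_per_site
                   if (g[1] == g[2]) rep(g[1], k)
                   else sample(seq.int(g[1], g[2]), k, replace = TRUE)
                 })
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Site-level climate model
#'
#' Each climate variable responds linearly to elevation and latitude plus
#' independent Gaussian noise: `value = intercept + b_elev * elevation +
#' b_lat * lat + N(0, sigma)`. Because all variables share the elevation and
#' latitude drivers, they are mutually correlated, as bioclimatic variables
#' are in real rasters. The default coefficients give temperature-type
#' variables a negative lapse (e.g. -0.006 degC/m for monthly temperature
#' extremes) and realistic magnitudes for PET, degree days and moisture
#' indices over 1300--2800 m and 33--46 degrees N.
#'
#' @param coefficients data.frame with columns `variable`, `intercept`,
#'   `b_elev`, `b_lat`, `sigma`; variables must be a subset of
#'   [envirem_variables()].
#' @return Object of class `"climate_model"`.
#' @export
climate_model <- function(coefficients = default_climate_coefficients()) {
  need <- c("variable", "intercept", "b_elev", "b_lat", "sigma")
  if (!all(need %in% names(coefficients)))
    stop("climate_model: coefficients need columns ",
         paste(need, collapse = ", "))
  bad <- setdiff(coefficients$variable, envirem_variables())
  if (length(bad))
    stop("climate_model: unknown climate variable(s): ",
         paste(bad, collapse = ", "))
  if (any(coefficients$sigma < 0)) stop("climate_model: sigma must be >= 0")
  structure(list(coefficients = coefficients), class = "climate_model")
}

#' @rdname climate_model
#' @export
default_climate_coefficients <- function() {
  data.frame(
    variable = envirem_variables(),
    intercept = c(-0.2, 40, 1700, 18, 7000, 5500, 22, 24, 12, 520, 470,
                  180, 800, 52, 700),
    b_elev = c(4e-4, 0.02, -0.25, 0.004, -1.2, -1.0, -0.006, -0.006,
               -0.002, -0.08, -0.07, -0.03, -0.12, -0.004, -0.12),
    b_lat = c(0.01, 0.5, -15, 0.3, -80, -70, -0.10, -0.08, -0.06, -5, -4,
              -1.5, -6, 0.2, -6),
    sigma = c(0.05, 2, 25, 1, 100, 90, 0.5, 0.5, 0.3, 10, 10, 5, 12, 1.5,
              10))
}

#' Generate site climate values
#'
#' Evaluates a [climate_model()] at each site's elevation and latitude and
#' adds independent Gaussian noise, one column per climate variable.
#'
#' @param sites site table from [gen_transects()] (needs `elevation`, `lat`).
#' @param model a [climate_model()].
#' @param seed integer seed.
#' @return `sites` with one numeric column appended per climate variable.
#' @export
gen_climate <- function(sites, model, seed = 1L) {
  stopifnot(inherits(model, "climate_model"))
  if (!nrow(sites)) stop("gen_climate: empty site table")
  co <- model$coefficients
  with_seed(seed, {
    for (k in seq_len(nrow(co))) {
      sites[[co$variable[k]]] <- co$intercept[k] +
        co$b_elev[k] * sites$elevation + co$b_lat[k] * sites$lat +
        stats::rnorm(nrow(sites), 0, co$sigma[k])
    }
    sites
  })
}

quantile_of_u <- function(tau, family) {
  switch(family,
         normal = stats::qnorm(tau),
         uniform = 2 * tau - 1,
         stop("unknown noise family: ", family))
}

draw_u <- function(n, family) {
  switch(family,
         normal = stats::rnorm(n),
         uniform = stats::runif(n, -1, 1),
         stop("unknown noise family: ", family))
}

#' Plantable trait--climate response shape
#'
#' Specifies the joint structure of one climate variable conditional on a
#' standardized site-mean trait x: `y = a + b*x + (c + d*x) * u`, with `u` a
#' standard symmetric variate (normal, or uniform on \[-1, 1\] for exact
#' bounded-support truth). The implied conditional-quantile line at level
#' tau has slope `b + d * q_u(tau)`, so `d != 0` opens or closes the quantile
#' fan (wedges/triangles) while `b` shifts it bodily (alignment).
#'
#' Canonical parameterizations by target shape (effect = outer-slope
#' magnitude): aligned `b = effect, d = 0`; reverse `b = 0,
#' d = effect/q_u(0.95)`; one-sided upper/lower put all of `effect` on one
#' outer quantile and exactly zero on the other; none `b = d = 0`.
#' Custom `b`/`d` are accepted but must reproduce the declared shape, and
#' the scale `c + d*x` must stay positive over `support` (otherwise the
#' implied quantile lines would cross).
#'
#' @param target_shape one of `"aligned"`, `"one_sided_upper"`,
#'   `"one_sided_lower"`, `"reverse"`, `"none"`.
#' @param effect magnitude of the planted outer-quantile slope (standardized
#'   trait units; default 1).
#' @param intercept location `a` of the climate variable.
#' @param scale baseline noise scale `c` (> 0).
#' @param b,d optional explicit location slope and scale slope, overriding
#'   the canonical parameterization.
#' @param family noise family of `u`: `"normal"` or `"uniform"`.
#' @param support trait range over which non-crossing is enforced.
#' @return Object of class `"shape_spec"`.
#' @export
shape_spec <- function(target_shape = c("aligned", "one_sided_upper",
                                        "one_sided_lower", "reverse", "none"),
                       effect = 1, intercept = 0, scale = 1,
                       b = NULL, d = NULL,
                       family = c("normal", "uniform"),
                       support = c(-3, 3)) {
  target_shape <- match.arg(target_shape)
  family <- match.arg(family)
  q95 <- quantile_of_u(0.95, family)
  if (is.null(b) || is.null(d)) {
    par <- switch(target_shape,
                  aligned = c(b = effect, d = 0),
                  none = c(b = 0, d = 0),
                  reverse = c(b = 0, d = effect / q95),
                  one_sided_upper = c(b = effect / 2, d = effect / (2 * q95)),
                  one_sided_lower = c(b = effect / 2, d = -effect / (2 * q95)))
    b <- b %||% unname(par["b"]); d <- d %||% unname(par["d"])
  }
  if (scale <= 0) stop("shape_spec: scale must be > 0")
  if (min(scale + d * support) <= 0)
    stop("shape_spec: implied quantile lines cross on the trait support ",
         "(scale + d * x must stay positive)")
  got <- implied_shape(b, d, family)
  if (got != target_shape)
    stop("shape_spec: parameters b = ", b, ", d = ", d, " imply shape '",
         got, "', not the declared '", target_shape, "'")
  structure(list(target_shape = target_shape, a = intercept, b = b,
                 c = scale, d = d, family = family, support = support),
            class = "shape_spec")
}

# Shape implied analytically by the outer-quantile slopes b + d q_u(tau).
implied_shape <- function(b, d, family, tol = 1e-12) {
  s05 <- b + d * quantile_of_u(0.05, family)
  s95 <- b + d * quantile_of_u(0.95, family)
  z05 <- abs(s05) <= tol; z95 <- abs(s95) <= tol
  if (z05 && z95) "none"
  else if (z05) "one_sided_upper"
  else if (z95) "one_sided_lower"
  else if (sign(s05) == sign(s95)) "aligned"
  else "reverse"
}

#' Planted conditional-quantile slope of a shape specification
#'
#' @param spec a [shape_spec()].
#' @param tau quantile level(s) in (0, 1).
#' @return Numeric vector `b + d * q_u(tau)`.
#' @export
planted_slope <- function(spec, tau) {
  stopifnot(inherits(spec, "shape_spec"))
  spec$b + spec$d * quantile_of_u(tau, spec$family)
}

#' Genetic architecture of the simulated traits
#'
#' Decomposes trait variation into a genetic site-level cline, a plastic
#' site-level response, genotype-level genetic deviations and residual
#' noise. In the field, a genotype's value is `site mean + g_i + e_i`; in
#' the common garden the plastic site term disappears and replicates of a
#' genotype share its genetic value: `garden = mu + cline term + g_i +
#' rep noise`. Broad-sense heritability `H2` fixes the genotype share of
#' within-site variance: `Var(g) = H2 * sigma_within^2`,
#' `Var(e) = (1 - H2) * sigma_within^2` (both field and garden), so with no
#' cline the expected genotype variance share in the garden equals `H2`.
#'
#' @param H2 broad-sense heritability in \[0, 1\] (recycled across traits).
#' @param cline genetic cline slope on the standardized site driver
#'   (elevation), in site-SD units of the trait.
#' @param plasticity plastic slope on the same driver, same units.
#' @param replicates_per_genotype clonal replicates grown per genotype
#'   (default 3, matching a garden of ~2.7 cuttings per genotype).
#' @return Object of class `"genetic_model"`.
#' @export
genetic_model <- function(H2 = 0.5, cline = 0, plasticity = 0.8,
                          replicates_per_genotype = 3L) {
  if (any(H2 < 0 | H2 > 1)) stop("genetic_model: H2 must be in [0, 1]")
  if (replicates_per_genotype < 1L)
    stop("genetic_model: replicates_per_genotype must be >= 1")
  structure(list(H2 = H2, cline = cline, plasticity = plasticity,
                 replicates_per_genotype = as.integer(replicates_per_genotype)),
            class = "genetic_model")
}

# Trait scales of the simulated species: site-to-site SD, within-site SD and
# the garden analog scale (growth diameter in mm for field DBH in cm).
trait_defaults <- function() {
  data.frame(trait = c("DBH", "leaf_area", "leaf_mass"),
             mean = c(30, 25, 0.10),
             sd_site = c(8, 5, 0.025),
             sd_within = c(4, 2.5, 0.012),
             garden_mean = c(8, 18, 0.08),
             garden_scale = c(0.3, 0.7, 0.7))
}

field_traits <- function() c("DBH", "leaf_area", "leaf_mass", "SLA")

#' Generate field trait data with plantable quantile-shape structure
#'
#' Simulates per-genotype field measurements of DBH, leaf area, leaf mass
#' (SLA derived as area/mass) on a transect site table, together with
#' climate columns whose conditional-quantile structure given the site-mean
#' trait follows the supplied [shape_spec()]s. Site-mean traits combine a
#' genetic cline and a plastic response to the standardized elevation driver
#' plus independent site deviations; genotypes deviate from their site mean
#' by genetic (`g_i`) and residual noise split by `H2`.
#'
#' For every `"trait:climate"` entry of `shapes`, the site value of that
#' climate variable is drawn as `y = a + b*x + (c + d*x) u` with `x` the
#' standardized latent site-mean trait — the ground truth lives in exactly
#' the conditional quantiles the analysis estimates.
#'
#' @param sites site table from [gen_transects()].
#' @param shapes named list of [shape_spec()]s; names are
#'   `"trait:climate_variable"` (e.g. `"leaf_mass:aridity_index_thornthwaite"`).
#'   A climate variable may be driven by at most one trait.
#' @param genetics a [genetic_model()].
#' @param seed integer seed.
#' @return List with `field` (one row per genotype: ids, site info, traits;
#'   carries a `"genetic_values"` attribute used by [gen_garden()]),
#'   `site_climate` (per-site planted climate columns for the shaped
#'   variables) and `truth` (latent standardized site-mean traits).
#' @export
gen_field_traits <- function(sites, shapes = list(),
                             genetics = genetic_model(), seed = 1L) {
  stopifnot(inherits(genetics, "genetic_model"))
  if (length(shapes)) {
    keys <- strsplit(names(shapes), ":", fixed = TRUE)
    if (any(lengths(keys) != 2L))
      stop("gen_field_traits: shape names must be 'trait:climate_variable'")
    tr <- vapply(keys, `[`, "", 1L); cl <- vapply(keys, `[`, "", 2L)
    if (!all(tr %in% field_traits()))
      stop("gen_field_traits: unknown trait in shapes: ",
           paste(setdiff(tr, field_traits()), collapse = ", "))
    if (!all(cl %in% envirem_variables()))
      stop("gen_field_traits: unknown climate variable in shapes: ",
           paste(setdiff(cl, envirem_variables()), collapse = ", "))
    if (anyDuplicated(cl))
      stop("gen_field_traits: a climate variable can be driven by one trait only")
  }
  td <- trait_defaults()
  H2 <- rep_len(genetics$H2, nrow(td))
  z <- as.vector(scale(sites$elevation))
  n_sites <- nrow(sites)
  with_seed(seed, {
    # latent site means per base trait
    site_mean <- list()
    for (k in seq_len(nrow(td))) {
      dev <- stats::rnorm(n_sites)
      site_mean[[td$trait[k]]] <- td$mean[k] + td$sd_site[k] *
        ((genetics$cline + genetics$plasticity) * z + dev)
    }
    # genotype rows
    reps <- sites$n_genotypes
    idx <- rep(seq_len(n_sites), reps)
    field <- data.frame(
      genotype_id = sprintf("%s_%s_g%02d", sites$watershed[idx],
                            sites$band[idx],
                            unlist(lapply(reps, seq_len))),
      watershed = sites$watershed[idx], band = sites$band[idx],
      lat = sites$lat[idx], lon = sites$lon[idx],
      elevation = sites$elevation[idx])
    gvals <- data.frame(genotype_id = field$genotype_id,
                        site = idx)
    for (k in seq_len(nrow(td))) {
      nm <- td$trait[k]
      g <- stats::rnorm(nrow(field), 0, sqrt(H2[k]) * td$sd_within[k])
      e <- stats::rnorm(nrow(field), 0, sqrt(1 - H2[k]) * td$sd_within[k])
      val <- site_mean[[nm]][idx] + g + e
      field[[nm]] <- pmax(val, 0.01 * td$mean[k])   # traits are nonnegative
      # genetic value = cline component + genotype deviation (site-plastic
      # and residual terms excluded); stored for the garden generator
      gvals[[nm]] <- td$mean[k] +
        td$sd_site[k] * genetics$cline * z[idx] + g
    }
    field$SLA <- field$leaf_area / field$leaf_mass
    # planted climate conditional on standardized latent site-mean trait
    truth <- data.frame(watershed = sites$watershed, band = sites$band)
    for (k in seq_len(nrow(td)))
      truth[[paste0("x_", td$trait[k])]] <-
        as.vector(scale(site_mean[[td$trait[k]]]))
    truth$x_SLA <- as.vector(scale(site_mean$leaf_area / site_mean$leaf_mass))
    site_climate <- data.frame(watershed = sites$watershed, band = sites$band)
    if (length(shapes)) {
      for (j in seq_along(shapes)) {
        sp <- shapes[[j]]
        stopifnot(inherits(sp, "shape_spec"))
        x <- truth[[paste0("x_", tr[j])]]
        if (min(sp$c + sp$d * x) <= 0)
          stop("gen_field_traits: shape for ", names(shapes)[j],
               " implies quantile crossing on the realized trait support")
        u <- draw_u(n_sites, sp$family)
        site_climate[[cl[j]]] <- sp$a + sp$b * x + (sp$c + sp$d * x) * u
      }
    }
    attr(field, "genetic_values") <- gvals
    list(field = field, site_climate = site_climate, truth = truth)
  })
}

#' Generate common-garden clonal replicate data
#'
#' Grows `replicates_per_genotype` clonal replicates of every field genotype
#' in a single common environment: each replicate equals the genotype's
#' genetic value (cline component + genotype deviation, rescaled to garden
#' units) plus independent garden noise sized so the expected genotype
#' variance share equals `H2`. The DBH analog is the diameter of annual
#' shoot growth (`growth_diameter`, mm); leaf traits keep their names and
#' SLA is derived per replicate.
#'
#' @param field field table from [gen_field_traits()] (its
#'   `"genetic_values"` attribute links garden genotypes to their field
#'   genetic values; if absent, fresh genetic values are drawn).
#' @param genetics the [genetic_model()] used for the field table.
#' @param seed integer seed.
#' @return data.frame with one row per replicate: `genotype_id`,
#'   `replicate_id`, `growth_diameter`, `leaf_area`, `leaf_mass`, `SLA`.
#' @export
gen_garden <- function(field, genetics = genetic_model(), seed = 1L) {
  stopifnot(inherits(genetics, "genetic_model"))
  if (!"genotype_id" %in% names(field))
    stop("gen_garden: field table lacks genotype_id")
  td <- trait_defaults()
  H2 <- rep_len(genetics$H2, nrow(td))
  gv <- attr(field, "genetic_values")
  R <- genetics$replicates_per_genotype
  n_g <- nrow(field)
  with_seed(seed, {
    if (is.null(gv)) {
      gv <- data.frame(genotype_id = field$genotype_id)
      for (k in seq_len(nrow(td)))
        gv[[td$trait[k]]] <- td$mean[k] +
          stats::rnorm(n_g, 0, sqrt(H2[k]) * td$sd_within[k])
    }
    idx <- rep(seq_len(n_g), each = R)
    out <- data.frame(genotype_id = gv$genotype_id[idx],
                      replicate_id = sprintf("r%02d", rep(seq_len(R), n_g)))
    garden_names <- c(DBH = "growth_diameter", leaf_area = "leaf_area",
                      leaf_mass = "leaf_mass")
    for (k in seq_len(nrow(td))) {
      nm <- td$trait[k]
      sc <- td$garden_scale[k]
      genetic_dev <- (gv[[nm]] - td$mean[k]) * sc
      noise_sd <- sqrt(1 - H2[k]) * td$sd_within[k] * sc
      val <- td$garden_mean[k] + genetic_dev[idx] +
        stats::rnorm(length(idx), 0, noise_sd)
      out[[garden_names[[nm]]]] <- pmax(val, 0.01 * td$garden_mean[k])
    }
    out$SLA <- out$leaf_area / out$leaf_mass
    out
  })
}

#' Deterministic synthetic elevation surface
#'
#' A smooth ridge-plus-gradient surface mapping coordinates to elevation
#' inside `elev_range`; pure function of its arguments, used by
#' [gen_climate_raster()] so that site tables and rasters can be generated
#' consistently.
#'
#' @param x,y coordinate vectors (equal length).
#' @param extent `c(xmin, xmax, ymin, ymax)` window normalizing coordinates.
#' @param elev_range `c(min, max)` output elevation range in meters.
#' @return Numeric vector of elevations.
#' @export
elevation_surface <- function(x, y, extent, elev_range = c(1373, 2808)) {
  tx <- (x - extent[1]) / max(extent[2] - extent[1], 1e-12)
  ty <- (y - extent[3]) / max(extent[4] - extent[3], 1e-12)
  s <- 0.35 + 0.3 * sin(2 * pi * tx) * sin(pi * ty) + 0.3 * ty
  elev_range[1] + (elev_range[2] - elev_range[1]) * pmin(pmax(s, 0), 1)
}

#' Generate gridded climate layers
#'
#' Evaluates a [climate_model()] over a rectangular grid on the synthetic
#' [elevation_surface()] (north-up, cell-center registered), one layer per
#' climate variable plus the elevation layer itself. With `noise = FALSE`
#' (or model sigmas of zero) a site placed at a cell center receives exactly
#' the cell's climate values from [gen_climate()].
#'
#' @param extent `c(xmin, xmax, ymin, ymax)`; must have positive area.
#' @param cellsize positive cell size in the same units.
#' @param model a [climate_model()].
#' @param seed integer seed (noise only).
#' @param elev_range elevation range passed to [elevation_surface()].
#' @param noise add the model's Gaussian noise per cell (default TRUE).
#' @return Named list of [climate_grid()]s (15 variables + `"elevation"`).
#' @export
gen_climate_raster <- function(extent, cellsize, model = climate_model(),
                               seed = 1L, elev_range = c(1373, 2808),
                               noise = TRUE) {
  stopifnot(inherits(model, "climate_model"))
  if (cellsize <= 0) stop("gen_climate_raster: cellsize must be positive")
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("gen_climate_raster: empty extent")
  nc <- max(1L, floor((extent[2] - extent[1]) / cellsize))
  nr <- max(1L, floor((extent[4] - extent[3]) / cellsize))
  xs <- extent[1] + (seq_len(nc) - 0.5) * cellsize
  ys <- extent[3] + (nr - seq_len(nr) + 0.5) * cellsize   # row 1 = north
  X <- matrix(rep(xs, each = nr), nrow = nr)
  Y <- matrix(rep(ys, nc), nrow = nr)
  E <- matrix(elevation_surface(as.vector(X), as.vector(Y), extent,
                                elev_range), nrow = nr)
  co <- model$coefficients
  with_seed(seed, {
    out <- list(elevation = climate_grid(E, extent[1], extent[3], cellsize,
                                         varname = "elevation"))
    for (k in seq_len(nrow(co))) {
      v <- co$intercept[k] + co$b_elev[k] * E + co$b_lat[k] * Y
      if (noise && co$sigma[k] > 0)
        v <- v + matrix(stats::rnorm(length(v), 0, co$sigma[k]), nrow = nr)
      out[[co$variable[k]]] <- climate_grid(v, extent[1], extent[3],
                                            cellsize,
                                            varname = co$variable[k])
    }
    out
  })
}
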