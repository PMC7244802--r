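test_that("transect generation honors the design invariants", {
  design <- transect_design(seed = 3)
  sites <- gen_transects(design)
  expect_equal(nrow(sites), 48L)
  expect_equal(sort(unique(sites$band)), sort(c("low", "mid", "high")))
  for (w in unique(sites$watershed)) {
    s <- sites[sites$watershed == w, ]
    expect_true(all(diff(s$elevation[match(c("low", "mid", "high"),
                                           s$band)]) > 0))
  }
  expect_true(all(sites$lat >= design$lat_range[1] &
                    sites$lat <= design$lat_range[2] + 0.02))
  expect_true(all(sites$elevation >= design$elev_range[1] &
                    sites$elevation <= design$elev_range[2]))
  expect_true(all(sites$n_genotypes >= 5 & sites$n_genotypes <= 10))
  # determinism and the minimal design
  expect_identical(sites, gen_transects(design))
  tiny <- gen_transects(transect_design(n_watersheds = 1,
                                        sites_per_watershed = 1))
  expect_equal(nrow(tiny), 1L)
  expect_error(transect_design(lat_range = c(50, 40)), "invalid lat_range")
})

test_that("climate generation follows the linear model exactly without noise", {
  sites <- data.frame(watershed = c("W01", "W01"), band = c("low", "high"),
                      lat = c(40, 40), lon = c(-110, -110),
                      elevation = c(1500, 2500))
  co <- default_climate_coefficients()
  co$sigma[] <- 0
  cm <- climate_model(co)
  clim <- gen_climate(sites, cm, seed = 1)
  # lapse of -0.006 degC/m over 1000 m is exactly -6 degrees
  expect_equal(diff(clim$max_temp_coldest_month), -6, tolerance = 1e-12)
  # zero coefficients, zero noise: constant column
  co2 <- co; co2$b_elev[] <- 0; co2$b_lat[] <- 0
  clim2 <- gen_climate(sites, climate_model(co2), seed = 1)
  expect_equal(clim2$annual_PET[1], clim2$annual_PET[2])
  expect_error(climate_model(data.frame(variable = "not_a_var",
                                        intercept = 0, b_elev = 0,
                                        b_lat = 0, sigma = 0)),
               "unknown climate variable")
})

test_that("shared elevation drivers induce strong inter-variable correlation", {
  sites <- gen_transects(transect_design(seed = 5))
  clim <- gen_climate(sites, climate_model(), seed = 5)
  r <- cor(clim$growing_degree_days0, clim$annual_PET)
  expect_gt(abs(r), 0.5)
})

test_that("shape specs validate their declared geometry at construction", {
  sp <- shape_spec("one_sided_upper", effect = 1)
  expect_gt(planted_slope(sp, 0.95), 0)
  expect_equal(planted_slope(sp, 0.05), 0, tolerance = 1e-12)
  sp0 <- shape_spec("none")
  expect_equal(planted_slope(sp0, 0.95), 0)
  spa <- shape_spec("aligned", effect = 1)
  for (tt in c(0.05, 0.5, 0.95))
    expect_equal(planted_slope(spa, tt), 1)
  # mismatched explicit parameters are rejected
  expect_error(shape_spec("one_sided_upper", b = 0, d = 0.2),
               "imply shape")
  # crossing on the support is rejected
  expect_error(shape_spec("reverse", effect = 2, scale = 1),
               "cross")
})

test_that("planted quantile slopes are recovered from large simulated data", {
  # estimate conditional quantile slopes by binning x and regressing the
  # within-bin empirical quantiles on bin centers -- independent of the
  # package's LP fitter
  binned_slope <- function(x, y, tau, nbins = 25) {
    br <- quantile(x, seq(0, 1, length.out = nbins + 1))
    bin <- cut(x, unique(br), include.lowest = TRUE)
    qs <- tapply(y, bin, quantile, probs = tau, type = 6)
    ctr <- tapply(x, bin, mean)
    unname(coef(lm(qs ~ ctr))[2])
  }
  set.seed(71)
  n <- 10000
  for (shape in c("aligned", "one_sided_upper", "reverse")) {
    sp <- if (shape == "reverse") shape_spec(shape, effect = 1, scale = 2)
          else shape_spec(shape, effect = 1)
    x <- pmin(pmax(rnorm(n), -3), 3)
    u <- rnorm(n)
    y <- sp$a + sp$b * x + (sp$c + sp$d * x) * u
    for (tau in c(0.05, 0.95)) {
      planted <- planted_slope(sp, tau)
      est <- binned_slope(x, y, tau)
      expect_equal(est, planted,
                   tolerance = max(0.05, 0.05 * max(abs(planted), 1)))
    }
  }
})

test_that("field generator output is deterministic, positive and complete", {
  b <- synth_bundle(seed = 9)
  expect_true(all(c("DBH", "leaf_area", "leaf_mass", "SLA") %in%
                    names(b$field)))
  expect_true(all(b$field$DBH > 0))
  expect_equal(b$field$SLA, b$field$leaf_area / b$field$leaf_mass)
  expect_false(anyDuplicated(b$field$genotype_id) > 0)
  b2 <- synth_bundle(seed = 9)
  expect_identical(b$field, b2$field)
  expect_identical(b$garden, b2$garden)
})

test_that("shaped climate variables carry the planted conditional structure", {
  shapes <- list("leaf_mass:aridity_index_thornthwaite" =
                   shape_spec("aligned", effect = 1.2))
  sites <- gen_transects(transect_design(n_watersheds = 200, seed = 11))
  ft <- gen_field_traits(sites, shapes, genetic_model(), seed = 11)
  x <- ft$truth$x_leaf_mass
  y <- ft$site_climate$aridity_index_thornthwaite
  # median regression slope close to the planted location slope
  f <- fit_quantile(x, y, 0.5)
  expect_equal(f$slope, 1.2, tolerance = 0.15)
  # unknown names rejected
  expect_error(gen_field_traits(sites, list("DBH:bogus" = shapes[[1]]),
                                genetic_model(), 1),
               "unknown climate variable")
  expect_error(
    gen_field_traits(sites,
                     list("DBH:annual_PET" = shapes[[1]],
                          "SLA:annual_PET" = shapes[[1]]),
                     genetic_model(), 1),
    "one trait only")
})

test_that("garden replicates express the requested heritability structure", {
  # H2 = 1, no garden noise: replicates within genotype identical
  b1 <- synth_bundle(seed = 13, genetics = genetic_model(H2 = 1))
  sp <- split(b1$garden$growth_diameter, b1$garden$genotype_id)
  expect_true(all(vapply(sp, function(v) diff(range(v)) < 1e-12,
                         logical(1))))
  # H2 = 0: genotype variance component vanishes in expectation
  b0 <- synth_bundle(seed = 13, genetics = genetic_model(H2 = 0))
  h <- heritability(b0$garden, "growth_diameter")
  expect_lt(h$H2, 0.15)
  expect_error(genetic_model(H2 = 1.2), "H2")
})

test_that("heritability calibration converges at large genotype counts", {
  # method-of-moments recovery across many genotypes, few replicates
  set.seed(77)
  n_g <- 1000; R <- 3; H2 <- 0.5
  g <- rep(rnorm(n_g, sd = sqrt(H2)), each = R)
  y <- g + rnorm(n_g * R, sd = sqrt(1 - H2))
  garden <- data.frame(genotype_id = rep(sprintf("g%04d", 1:n_g), each = R),
                       trait = y)
  h <- heritability(garden, "trait")
  expect_equal(h$H2, H2, tolerance = 0.02)
})

test_that("raster layers agree with the site model and are reproducible", {
  ext <- c(-114, -106, 34, 45)
  g <- gen_climate_raster(ext, 0.5, climate_model(), seed = 15,
                          noise = FALSE)
  expect_length(g, 16L)   # 15 variables + elevation
  # constant elevation surface, zero noise: constant layers
  flat <- gen_climate_raster(ext, 0.5, climate_model(), seed = 1,
                             elev_range = c(2000, 2000), noise = FALSE)
  v <- flat$annual_PET$values
  ys <- grid_coords(flat$annual_PET)$y
  co <- default_climate_coefficients()
  k <- which(co$variable == "annual_PET")
  expect_equal(v, matrix(co$intercept[k] + co$b_elev[k] * 2000 +
                           co$b_lat[k] * rep(ys, ncol(v)), nrow(v)),
               tolerance = 1e-9)
  # determinism with noise
  g1 <- gen_climate_raster(ext, 0.5, climate_model(), seed = 15)
  g2 <- gen_climate_raster(ext, 0.5, climate_model(), seed = 15)
  expect_identical(g1$annual_PET$values, g2$annual_PET$values)
  # site placed at a cell center matches the cell value when noise is off
  cc <- grid_coords(g$annual_PET)
  site <- data.frame(watershed = "W01", band = "low",
                     lat = cc$y[3], lon = cc$x[4],
                     elevation = g$elevation$values[3, 4])
  co0 <- co; co0$sigma[] <- 0
  clim <- gen_climate(site, climate_model(co0), seed = 1)
  expect_equal(clim$annual_PET, g$annual_PET$values[3, 4], tolerance = 1e-9)
  expect_error(gen_climate_raster(c(0, 0, 0, 1), 0.5, climate_model()),
               "empty extent")
})
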