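grid_of <- function(vals, cellsize = 1, varname = "v") {
  climate_grid(vals, 0, 0, cellsize, varname = varname)
}

sig_fit <- function(a, b) list(intercept = a, slope = b, significant = TRUE)

test_that("upper-limit inversion solves the constraint algebra", {
  g <- grid_of(matrix(c(5, 12), 1))
  bnd <- invert_upper(sig_fit(10, -1), g)
  # y = 5: trait_max = (5 - 10)/(-1) = 5; y = 12: trait_max = -2 (no-go
  # once clamped against an observed minimum of 0)
  expect_equal(bnd$upper[1, 1], 5)
  expect_equal(bnd$upper[1, 2], -2)
  cg <- combine_constraints(list(bnd), trait_range = c(0, 60))
  expect_equal(cg$trait_max[1, 1], 5)
  expect_true(is.na(cg$trait_max[1, 2]))
  expect_equal(cg$mask[1, 2], 2L)  # no_go
  # b = 0 threshold: y <= a decides feasibility outright
  bt <- invert_upper(sig_fit(10, 0), grid_of(matrix(c(9, 11), 1)))
  expect_identical(bt$kind, "threshold")
  ct <- combine_constraints(list(bt), c(0, 60))
  expect_equal(ct$mask[1, ], c(0L, 2L))
  # non-significant fits are refused
  expect_error(invert_upper(list(intercept = 1, slope = -1,
                                 significant = FALSE), g),
               "non-significant")
})

test_that("lower-limit inversion mirrors the upper case", {
  g <- grid_of(matrix(c(6, -5, 100), 1))
  bnd <- invert_lower(sig_fit(0, 2), g)
  expect_equal(bnd$upper[1, 1], 3)      # y = 6: trait_max = 6/2 = 3
  cg <- combine_constraints(list(bnd), c(0, 10))
  expect_equal(cg$trait_max[1, 1], 3)
  # y = -5 allows only x <= -2.5, below every observed trait: no_go
  expect_equal(cg$mask[1, 2], 2L)
  # y far above the line for all observed traits: unconstrained
  expect_equal(cg$mask[1, 3], 0L)
  expect_equal(cg$trait_max[1, 3], 10)
  # b < 0 at a lower limit demands large traits: lower-bound case combined
  # with the observed maximum decides no_go
  g2 <- grid_of(matrix(c(-5, -30), 1))
  bnd2 <- invert_lower(sig_fit(0, -2), g2)
  cg2 <- combine_constraints(list(bnd2), c(0, 10))
  expect_equal(cg2$mask[1, 1], 0L)      # y = -5 needs x >= 2.5: feasible
  expect_equal(cg2$trait_max[1, 1], 10)
  expect_equal(cg2$mask[1, 2], 2L)      # y = -30 needs x >= 15 > max obs
})

test_that("min-combine takes the strongest constraint and clamps", {
  g1 <- grid_of(matrix(5, 2, 2))
  g2 <- grid_of(matrix(3, 2, 2))
  b1 <- invert_upper(sig_fit(10, -1), g1)   # trait_max 5
  b2 <- invert_upper(sig_fit(8, -1), g2)    # trait_max 5 -> combine
  cg <- combine_constraints(list(b1, b2), c(0, 4), trait = "DBH")
  # both upper bounds are 5, above observed max 4: unconstrained clamp
  expect_true(all(cg$trait_max == 4))
  expect_true(all(cg$mask == 0L))
  b3 <- invert_upper(sig_fit(6, -1), g2)    # trait_max 3
  cg2 <- combine_constraints(list(b1, b3), c(0, 4))
  expect_true(all(cg2$trait_max == 3))
  expect_true(all(cg2$mask == 1L))
  # geometry mismatch rejected
  gX <- climate_grid(matrix(1, 2, 2), 10, 0, 1)
  expect_error(combine_constraints(list(b1, invert_upper(sig_fit(6, -1),
                                                         gX)), c(0, 4)),
               "geometry mismatch")
  # monotonicity: adding a constraint never raises any cell
  expect_true(all(cg2$trait_max <= cg$trait_max + 1e-12, na.rm = TRUE))
})

test_that("combined constraint grid matches a brute-force feasibility scan", {
  set.seed(103)
  constraints <- list(
    list(intercept = 40, slope = -2, significant = TRUE, limit = "upper"),
    list(intercept = -5, slope = 1.5, significant = TRUE, limit = "lower"),
    list(intercept = 25, slope = -0.8, significant = TRUE, limit = "upper"))
  trait_range <- c(2, 18)
  grids <- lapply(constraints, function(cn) {
    grid_of(matrix(runif(100, -20, 45), 10, 10))
  })
  bounds <- Map(function(cn, g) {
    if (cn$limit == "upper") invert_upper(cn, g) else invert_lower(cn, g)
  }, constraints, grids)
  cg <- combine_constraints(bounds, trait_range)
  y_cells <- cbind(as.vector(grids[[1]]$values),
                   as.vector(grids[[2]]$values),
                   as.vector(grids[[3]]$values))
  oracle <- feasibility_oracle(constraints, y_cells, trait_range)
  got <- as.vector(cg$trait_max)
  step <- diff(trait_range) / 9999
  expect_identical(is.na(got), is.na(oracle))
  expect_true(all(abs(got - oracle) <= step + 1e-9, na.rm = TRUE))
  # inversion consistency: the binding line reproduces the climate value
  for (cell in which(cg$mask == 1L)) {
    xmax <- cg$trait_max[cell]
    preds <- vapply(seq_along(constraints), function(k) {
      cn <- constraints[[k]]
      cn$intercept + cn$slope * xmax
    }, numeric(1))
    ys <- y_cells[cell, ]
    expect_lt(min(abs(preds - ys)), 1e-6)
  }
})

test_that("the climate-envelope mask is correct and idempotent", {
  g <- grid_of(matrix(c(1, 5, 9, 20), 2, 2), varname = "annual_PET")
  bnd <- invert_upper(sig_fit(30, -1), g)
  cg <- combine_constraints(list(bnd), c(0, 50))
  site_climate <- data.frame(annual_PET = c(2, 10))
  m1 <- apply_envelope_mask(cg, list(annual_PET = g), site_climate)
  expect_equal(m1$mask[1, 1], 3L)     # 1 < min observed 2
  expect_equal(m1$mask[2, 2], 3L)     # 20 > max observed 10
  expect_true(all(m1$mask[cbind(c(2, 1), c(1, 2))] != 3L))
  m2 <- apply_envelope_mask(m1, list(annual_PET = g), site_climate)
  expect_identical(m1$mask, m2$mask)
  expect_identical(m1$trait_max, m2$trait_max)
})

test_that("ascii-grid maps round-trip bit-exactly with no-go preserved", {
  g <- grid_of(matrix(runif(12, 0, 30), 3, 4))
  bnd <- invert_upper(sig_fit(15, -1), g)
  cg <- combine_constraints(list(bnd), c(2, 9), trait = "DBH")
  stem <- file.path(tempdir(), "dbh_map")
  write_map(cg, stem)
  back <- read_map(stem)
  expect_identical(back$trait_max, cg$trait_max)
  expect_identical(back$mask, cg$mask)
  expect_equal(back$trait_range, cg$trait_range)
  expect_equal(back$geometry$cellsize, cg$geometry$cellsize)
  # no_go cells are NA in the trait band but coded 2 in the mask band,
  # distinguishable from out-of-range (3)
  if (any(cg$mask == 2L)) {
    expect_true(all(is.na(back$trait_max[back$mask == 2L])))
  }
})

test_that("climate_grid IO preserves headers and NA cells", {
  m <- matrix(c(1.5, NA, -2.25, 4), 2, 2)
  g <- climate_grid(m, -114.2, 33.7, 0.25, varname = "aridity")
  p <- tempfile(fileext = ".asc")
  write_asc(g, p)
  back <- read_asc(p)
  expect_identical(back$values, m)
  expect_equal(back$xll, -114.2)
  expect_equal(back$yll, 33.7)
  expect_equal(back$cellsize, 0.25)
  expect_error(read_asc(tempfile()), "no such file")
})
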