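stub_fit <- function(sig95, slope95, sig05 = FALSE, slope05 = 0,
                     trait = "DBH", climate = "annual_PET") {
  fits <- data.frame(tau = c(0.05, 0.95), intercept = 0,
                     slope = c(slope05, slope95), p_value = NA,
                     ci_lower = NA, ci_upper = NA,
                     significant = c(sig05, sig95), loss = 0)
  structure(list(fits = fits, trait = trait, climate = climate,
                 taus = fits$tau, alpha = 0.05, n = 48,
                 standardize = TRUE, crossing = FALSE), class = "dqr")
}

test_that("cline calls follow the field/garden significance rule", {
  f <- stub_fit(TRUE, 1)
  g <- stub_fit(TRUE, 0.7, trait = "garden_growth_diameter")
  expect_identical(call_cline(f, g, "upper")$call, "genetic_cline")
  g2 <- stub_fit(FALSE, 0.7, trait = "garden_growth_diameter")
  expect_identical(call_cline(f, g2, "upper")$call, "plasticity")
  f2 <- stub_fit(FALSE, 0)
  expect_identical(call_cline(f2, g, "upper")$call, "garden_only")
  expect_identical(call_cline(f2, g2, "upper")$call, "neither")
  # both significant, opposite directions: not a genetic cline
  g3 <- stub_fit(TRUE, -0.7, trait = "garden_growth_diameter")
  expect_identical(call_cline(f, g3, "upper")$call, "neither")
  # lower limit uses the tau = 0.05 fits
  f3 <- stub_fit(FALSE, 0, sig05 = TRUE, slope05 = 1)
  g4 <- stub_fit(FALSE, 0, sig05 = TRUE, slope05 = 2,
                 trait = "garden_growth_diameter")
  expect_identical(call_cline(f3, g4, "lower")$call, "genetic_cline")
  # mismatched climate variables are an error
  gX <- stub_fit(TRUE, 1, climate = "continentality")
  expect_error(call_cline(f, gX, "upper"), "different climate")
})

test_that("consistent_pairs extracts exactly the genetic-cline subset", {
  calls <- data.frame(trait = c("DBH", "DBH", "leaf_mass"),
                      climate = c("a", "b", "c"),
                      limit = c("upper", "lower", "upper"),
                      call = c("genetic_cline", "plasticity",
                               "genetic_cline"))
  cp <- consistent_pairs(calls)
  expect_equal(nrow(cp), 2L)
  expect_identical(cp, calls[calls$call == "genetic_cline", ],
                   ignore_attr = TRUE)
  none <- calls; none$call <- "plasticity"
  expect_equal(nrow(consistent_pairs(none)), 0L)
})

test_that("a planted shared genetic cline is detected across limits", {
  # strong genetic cline on elevation, plus plasticity; the garden keeps
  # the genetic component, so an aligned field pattern should reappear in
  # the garden and yield genetic_cline calls for the shaped pair
  shapes <- list("leaf_mass:aridity_index_thornthwaite" =
                   shape_spec("aligned", effect = 2, scale = 0.6))
  hits <- 0L
  for (seed in 1:12) {
    b <- synth_bundle(seed = 100 + seed,
                      genetics = genetic_model(H2 = 0.8, cline = 0.9,
                                               plasticity = 0.2),
                      shapes = shapes)
    sm <- site_means(b$field, b$garden, b$climate)
    ff <- dqr_table(sm, traits = "leaf_mass",
                    climates = "aridity_index_thornthwaite",
                    taus = c(0.05, 0.95), ci = FALSE)
    gf <- dqr_table(sm, garden = TRUE, traits = "garden_leaf_mass",
                    climates = "aridity_index_thornthwaite",
                    taus = c(0.05, 0.95), ci = FALSE)
    calls <- cline_table(ff, gf)
    if (any(calls$call == "genetic_cline")) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("heritability handles exact, shuffled and unbalanced designs", {
  # identical replicates within genotype, differing means: H2 = 1
  garden <- data.frame(genotype_id = rep(c("a", "b", "c"), each = 3),
                       trait = rep(c(1, 5, 9), each = 3))
  h <- heritability(garden, "trait")
  expect_equal(h$H2, 1)
  # permutation oracle: shuffled labels kill the genotype component
  set.seed(91)
  big <- data.frame(genotype_id = rep(sprintf("g%03d", 1:100), each = 4))
  big$trait <- rep(rnorm(100), each = 4) + rnorm(400, sd = 0.5)
  h2s <- replicate(100, {
    sh <- big
    sh$genotype_id <- sample(sh$genotype_id)
    heritability(sh, "trait")$H2
  })
  expect_lt(mean(h2s), 0.05)
  # affine invariance
  h_raw <- heritability(big, "trait")
  big2 <- big; big2$trait <- 3.7 * big2$trait - 11
  expect_equal(heritability(big2, "trait")$H2, h_raw$H2, tolerance = 1e-12)
  # all singletons are an error
  expect_error(heritability(data.frame(genotype_id = c("a", "b"),
                                       trait = c(1, 2)), "trait"),
               ">= 2 replicates")
  # negative moment estimates clamp to zero with a flag
  flat <- data.frame(genotype_id = rep(c("a", "b"), each = 2),
                     trait = c(1, 9, 5, 5))
  hf <- heritability(flat, "trait")
  expect_gte(hf$H2, 0)
})

test_that("method-of-moments H2 agrees with an REML variance split", {
  set.seed(97)
  n_g <- 150; R <- 4
  g <- rep(rnorm(n_g, sd = sqrt(0.6)), each = R)
  garden <- data.frame(genotype_id = rep(sprintf("g%03d", 1:n_g), each = R),
                       trait = g + rnorm(n_g * R, sd = sqrt(0.4)))
  h <- heritability(garden, "trait")
  fm <- lme4::lmer(trait ~ 1 + (1 | genotype_id), data = garden)
  vc <- as.data.frame(lme4::VarCorr(fm))
  h_reml <- vc$vcov[1] / sum(vc$vcov)
  expect_equal(h$H2, h_reml, tolerance = 0.02)
})
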