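# A dqr-shaped stub with prescribed outer significance/signs, letting the
# classification rule be tested as a pure function of its inputs.
stub_dqr <- function(sL, sU, gL = 1, gU = 1, s10 = sL, s90 = sU,
                     g10 = gL, g90 = gU, med = FALSE) {
  fits <- data.frame(tau = c(0.05, 0.10, 0.50, 0.90, 0.95),
                     intercept = 0,
                     slope = c(gL, g10, 0.1, g90, gU),
                     p_value = NA, ci_lower = NA, ci_upper = NA,
                     significant = c(sL, s10, med, s90, sU),
                     loss = 0)
  structure(list(fits = fits, trait = "DBH", climate = "annual_PET",
                 taus = fits$tau, alpha = 0.05, n = 48,
                 standardize = TRUE, crossing = FALSE),
            class = "dqr")
}

test_that("classification implements the response-shape rule exactly", {
  expect_identical(classify_pattern(stub_dqr(FALSE, TRUE, gU = -1))$label,
                   "one_sided_upper")
  expect_identical(classify_pattern(stub_dqr(TRUE, FALSE))$label,
                   "one_sided_lower")
  expect_identical(classify_pattern(stub_dqr(TRUE, TRUE, 1, 1))$label,
                   "aligned")
  expect_identical(classify_pattern(stub_dqr(TRUE, TRUE, -1, -1))$label,
                   "aligned")
  expect_identical(classify_pattern(stub_dqr(TRUE, TRUE, 1, gU = -1))$label,
                   "reverse")
  expect_identical(classify_pattern(stub_dqr(FALSE, FALSE))$label, "none")
})

test_that("every significance/sign combination maps to exactly one label", {
  for (sL in c(TRUE, FALSE)) for (sU in c(TRUE, FALSE))
    for (gL in c(-1, 1)) for (gU in c(-1, 1)) {
      p <- classify_pattern(stub_dqr(sL, sU, gL, gU))
      expect_true(p$label %in% c("aligned", "one_sided_upper",
                                 "one_sided_lower", "reverse", "none"))
      # signs are reported only for significant sides
      expect_identical(p$sign_lower, if (sL) gL else 0)
      expect_identical(p$sign_upper, if (sU) gU else 0)
    }
})

test_that("the robustness flag compares the 0.10/0.90 label to the primary", {
  same <- classify_pattern(stub_dqr(FALSE, TRUE))
  expect_true(same$robust)
  diff <- classify_pattern(stub_dqr(FALSE, TRUE, s90 = FALSE))
  expect_false(diff$robust)
  # robustness unavailable without the 0.10/0.90 pair
  m <- stub_dqr(FALSE, TRUE)
  m$fits <- m$fits[m$fits$tau %in% c(0.05, 0.5, 0.95), ]
  expect_true(is.na(classify_pattern(m)$robust))
})

test_that("tallies count labels and the combined one-sided category", {
  pat <- data.frame(trait = "DBH",
                    climate = sprintf("v%02d", 1:15),
                    label = c(rep("one_sided_upper", 6),
                              rep("one_sided_lower", 3),
                              rep("aligned", 3), rep("reverse", 1),
                              rep("none", 2)))
  tal <- summarize_patterns(pat)
  expect_equal(tal$count[tal$label == "one_sided"], 9L)
  expect_equal(tal$count[tal$label == "aligned"], 3L)
  expect_equal(sum(tal$count[tal$label != "one_sided"]), 15L)
  expect_equal(nrow(summarize_patterns(pat[0, ])), 0L)
  dup <- rbind(pat, pat[1, ])
  expect_error(summarize_patterns(dup), "duplicate")
  expect_error(summarize_patterns(
    data.frame(trait = c("DBH", "SLA"), climate = "v", label = "none")),
    "one trait")
})

test_that("label order never depends on climate-variable order", {
  set.seed(83)
  b <- synth_bundle(seed = 19, n_watersheds = 16)
  sm <- site_means(b$field, NULL, b$climate)
  cl <- c("annual_PET", "continentality", "thermicity_index")
  f1 <- dqr_table(sm, traits = "DBH", climates = cl,
                  taus = c(0.05, 0.5, 0.95), ci = FALSE)
  f2 <- dqr_table(sm, traits = "DBH", climates = rev(cl),
                  taus = c(0.05, 0.5, 0.95), ci = FALSE)
  p1 <- pattern_table(f1); p2 <- pattern_table(f2)
  p2 <- p2[match(p1$climate, p2$climate), ]
  expect_equal(p1$label, p2$label)
})

test_that("recovery power is high for planted shapes and honest for none", {
  pw <- pattern_recovery_power("none", n_reps = 60, seed = 23)
  # with no effect anywhere, 'none' is recovered at about (1 - alpha)^2
  expect_gte(min(pw$recovery), 1 - 2 * 0.05 - 0.08)
  pw2 <- pattern_recovery_power("aligned", n_sites = 48,
                                effect_grid = c(0.5, 2), n_reps = 60,
                                seed = 23)
  # recovery non-decreasing in effect within Monte-Carlo error
  expect_gte(pw2$recovery[2], pw2$recovery[1] - 0.1)
  expect_gte(pw2$recovery[2], 0.85)
  expect_error(pattern_recovery_power("aligned", n_reps = 10), ">= 50")
})
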