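Package: qniche
Title: Double Quantile Regression for Trait-Based Climate Niche Limits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a species' climate niche limits from intraspecific
    functional-trait variation using double quantile regression: conditional
    quantile lines of climate on site-mean traits are fit at lower (5th,
    10th), central (50th, 55th) and upper (90th, 95th) quantiles by exact
    linear programming on the pinball loss, with rank-score slope inference.
    Trait-climate pairs are classified into response shapes (aligned,
    one-sided, reverse), field and common-garden fits are compared to
    separate genetic clines from phenotypic plasticity, broad-sense
    heritability is estimated from clonal replicates, and significant
    quantile equations are inverted over gridded climate to map per-cell
    maximum attainable trait values and climatic no-go areas. Includes a
    transect-structured synthetic data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
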