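---
title: "Trait-based climate niche limits by double quantile regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based climate niche limits by double quantile regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qniche)
```

## The model

Classical niche models correlate climate with species occurrence; they say
little about *why* a range edge sits where it does. An alternative is to ask
how intraspecific variation in functional traits — tree diameter (DBH), leaf
area, leaf mass, specific leaf area (SLA) — bounds the climate a species can
occupy. `qniche` implements that analysis as *double quantile regression*:
for each trait–climate pair, conditional-quantile lines of **climate on the
site-mean trait** are fit at the lower limits ($\tau = 0.05, 0.10$), the
median niche ($\tau = 0.50, 0.55$) and the upper limits
($\tau = 0.90, 0.95$),

$$Q_y(\tau \mid x) = a_\tau + b_\tau x,$$

with $(a_\tau, b_\tau)$ minimizing the pinball loss
$\sum_i \rho_\tau(y_i - a - b x_i)$, $\rho_\tau(u) = u(\tau - \mathbf{1}[u<0])$.
The regression direction (climate as response, trait on the abscissa)
mirrors the way the fitted equations are later inverted: a significant outer
line delimits the climate a genotype with trait value $x$ can inhabit, and
the region beyond both outer lines is a *no-go area*.

The fit is exact: the problem is a small linear program solved by a dense
primal simplex (`fit_quantile()`). An optimal basic solution interpolates
two observations, which gives a free optimality certificate — the package
also ships `fit_quantile_enum()`, a brute-force scan over all point-pair
lines, used in the test suite as an independent oracle. The two routes agree
to machine precision for every dataset we generate.

The unit of analysis is the **site mean** (`site_means()`): one row per
(watershed, elevation band), i.e. $16 \times 3 = 48$ sites in the default
design. Garden traits are averaged in two stages (replicates to genotype,
then genotypes to site) so genotypes with more surviving cuttings do not
weigh more. Field and garden data are z-scored separately before pattern
comparison — the two datasets measure different quantities on different
scales (mature-tree DBH in cm versus first-year shoot growth in mm), and
the comparison is about response *shape*, not magnitude. Whether to
standardize raw records or site means is a genuinely open choice; we
standardize the site means, which are the actual regression inputs.

## Slope inference

Significance of $b_\tau$ is decided, by default, by the regression
rank-score test (Gutenbrunner–Jurečková–Koenker–Portnoy, iid form), the
small-sample standard for quantile regression, with a confidence interval
obtained by inverting the test over the pairwise-slope breakpoints. The
significance flag *is* "the interval excludes zero": both are derived from
the same statistic, so they can never disagree. Simulated at $\tau = 0.95$,
$n = 48$ under the null, the test's rejection rate is close to (slightly
below) the nominal 5%.

The rank test has a structural power ceiling at extreme quantiles: with
$n = 48$ and $\tau = 0.95$ only $\approx 2.4$ observations sit above the
fitted line, and the statistic can only reject when those few carriers
coincide with extreme trait values. No effect size escapes this ceiling,
because rescaling a response-shape's slopes rescales its noise with it (see
below). For power-sensitive work the package therefore offers a pairs
(x, y) bootstrap (`method = "xy-bootstrap"`, percentile interval, seeded),
which exploits the actual sampling variability of the slope estimate and is
markedly more powerful at the outer quantiles while remaining slightly
conservative under the null. The default stays rank: it is the method the
field's standard software defaults to at this sample size.

## Response shapes and cline calls

Each trait–climate pair is classified from the outer quantiles
($\tau = 0.05/0.95$; the $0.10/0.90$ pair repeats the rule as a robustness
flag, and the median quantiles are reported but never enter the label):

* **aligned** (rhombus) — both outer slopes significant, same sign: the
  trait shifts the whole climate niche without changing its width;
* **one-sided** (wedge) — exactly one outer slope significant: the trait is
  constrained at one climate extreme;
* **reverse** (acute triangle) — both significant, opposite signs: the
  climate range narrows from both ends as the trait changes;
* **none** — no significant outer slope.

These labels partition every significance/sign combination, so
classification is a pure function of the inference output.

Field patterns confound genetic and environmental causes; common-garden
patterns (clonal replicates in one environment) isolate the genetic part.
`call_cline()` compares the two per climate limit: both significant in the
same direction is evidence of a **genetic cline**; a field-only signal is
consistent with **phenotypic plasticity**. Calls are made per limit because
one trait–climate pair can legitimately show a cline at one limit and
plasticity at the other. The field trait is paired to its garden analog
(DBH with annual shoot growth diameter) — an interpretive pairing, not an
identity. "Consistent in the same direction" is implemented literally at
the primary outer quantiles, as the mapping filter requires.

Broad-sense heritability is estimated from the clonal replicates by one-way
method-of-moments variance components with the unbalanced-design correction
$n_0 = (N - \sum_i n_i^2/N)/(k-1)$; $H^2 = V_G/(V_G + V_E)$, negative
moment estimates clamped to zero and flagged. We chose moments over REML to
match the plain "variance explained by genotype" definition, and the test
suite checks the two agree on simulated designs.

## Mapping constraints

For (trait, climate, limit) triples passing the genetic-cline filter, the
field-fit quantile equation **in raw units** is inverted over gridded
climate: an upper-limit line with $b < 0$ gives a per-cell trait maximum
$(y - a)/b$; a positive slope gives a trait *minimum* (cells demanding more
trait than ever observed are no-go); a zero slope is a pure threshold.
Per-cell bounds are combined by the minimum ("the lowest trait value per
cell is the strongest constraint"), clamped to the observed trait range;
cells whose bound falls below the observed minimum are no-go, and cells
outside the per-variable min–max rectangle of observed site climates are
masked out-of-range. The field coefficients are projected (the garden fits
only gate) because the published maps are in field units; raw rather than
standardized coefficients for the same reason. The whole construction is
checked against a brute-force per-cell feasibility scan over a dense trait
grid.

Maps are written as ESRI ASCII grids (a float trait-max band and an integer
mask band with codes unconstrained/constrained/no-go/out-of-range) plus a
JSON provenance sidecar; the plain-text format keeps every artifact
diffable and round-trips bit-exactly.

## The synthetic generator

Real transect data cannot be bundled, so the generator reproduces the study
geometry and plants known truth in exactly the quantities the pipeline
estimates:

* **Transects** — 16 watersheds, 3 sites each at strictly increasing
  elevation, 5–10 genotypes per site; coordinate and elevation windows match
  a Rocky Mountain transect survey (latitudes 33.7–45.4°N, elevations
  1373–2808 m).
* **Climate** — 15 ENVIREM-style variables, each linear in elevation and
  latitude plus Gaussian noise; temperature-type variables get a negative
  lapse (−0.006 °C/m for the monthly extremes). Shared drivers make the
  variables realistically inter-correlated.
* **Response shapes** — for a chosen trait–climate pair the climate value
  is drawn *conditional on the standardized site-mean trait*:
  $y = a + bx + (c + dx)u$ with $u$ standard normal (or uniform on
  $[-1,1]$). The planted $\tau$-quantile slope is $b + d\,q_u(\tau)$, so
  the target shape is analytic: $d = 0$ plants alignment, $d \ne 0$ opens a
  wedge or triangle. Specifications implying quantile crossing
  ($c + dx \le 0$ somewhere on the trait support) are rejected at
  construction. Truth is planted in the fitted direction deliberately:
  ground truth must live in the quantity the pipeline estimates.
* **Genetics** — site-mean traits combine a genetic cline and a plastic
  response to the standardized elevation driver; genotypes deviate by
  genetic and residual noise split so that the garden genotype-variance
  share equals $H^2$. Garden replicates share their genotype's genetic
  value (default 3 cuttings per genotype, matching a ~2.7 observed ratio);
  the field adds the plastic site term the garden removes.

What the generator does **not** emulate: hybrid zones, UV/light gradients
confounded with elevation, soil feedbacks, spatial autocorrelation of
residuals, or measurement error structure. Passing tests show the pipeline
recovers truth planted under its own model assumptions — they do not
validate the biology of any particular field system.

## Numerical choices and scale decisions

* Simplex: Dantzig pricing switching to Bland's rule after $20n$ iterations
  (anti-cycling), ratio-test ties broken by smallest basis index;
  tolerances $10^{-9}$.
* Quantile crossing of fitted outer lines is *flagged, never rearranged*;
  the analysis reports raw fits.
* "Slope ≈ 0" is always an inference statement (interval containing zero),
  never a numeric epsilon.
* Wedge and triangle recovery is invariant to jointly rescaling planted
  slopes and noise, so recovery studies are parameterized by the
  scale-to-slope ratio `c/|d|`; the power studies in the acceptance suite
  use the bounded (uniform) noise variant with the bootstrap test — the
  conditions under which the outer-quantile truth is sharpest — at a ratio
  of 2.7 for wedges, halved for the triangle so each of its two sides
  carries the same per-quantile signal-to-noise, over 200 datasets of 48
  sites per shape. The trait support of a planted wedge is truncated only
  on the side where it pinches shut (the non-crossing constraint binds
  nowhere else), leaving the opposite tail free to supply the
  extreme-trait carriers that outer-quantile tests depend on. Heritability
  recovery uses 200 genotypes × 4 replicates; oracle-equivalence checks run
  at $n \le 12$ where enumeration is exact; mapping oracles use 10×10 grids
  against a 10,000-point trait scan.
* The end-to-end pipeline writes plain CSV/ASCII/JSON artifacts only, with
  a manifest carrying the seed and a config hash, so any artifact can be
  regenerated from the manifest alone.

## Known limitations

* At $n = 48$ sites, outer-quantile inference is weak by nature, and the
  acceptance studies quantify the ceiling: aligned shapes are recovered
  essentially always, but wedges (a detection *plus* a correct
  non-rejection) level off around 85%, triangles near 80%, and the
  all-null shape near 90% — the last two bounded by the bootstrap's
  small-sample per-side false-positive rate of roughly 5%. No effect size
  escapes these ceilings, because rescaling a planted shape's slopes
  rescales its noise with it. Tallies on real-scale data should be read
  with that asymmetry in mind.
* The rank-score test assumes iid errors; planted wedges are
  heteroscedastic by construction, which slightly inflates the false-positive
  rate on the null side of a wedge. The bootstrap option mitigates but does
  not remove this.
* The climate envelope is a per-variable rectangle; a convex hull would be
  tighter and is left as future work.
* No resampling or reprojection: mapped climate grids must share geometry,
  and mismatches are an error, never silently interpolated.
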