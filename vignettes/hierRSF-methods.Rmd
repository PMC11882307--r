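---
title: "Methods: hierarchical structuring of resource selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical structuring of resource selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Partially migratory ungulate populations contain migrants, which move
seasonally between distinct winter and summer ranges, and residents, which
stay on one range year-round. Whether these strategies also differ in
*fine-scale* resource selection — and whether herd identity, season, or
strategy structures that behaviour most strongly — is the question this
package operationalizes as a tested pipeline:

1. classify each animal-year as migrant or resident from its net squared
   displacement (NSD) profile and estimate migration timing;
2. delineate seasonal ranges as 95% isopleths of bivariate normal kernel
   density estimates (KDE) with the reference bandwidth;
3. fit a third-order resource selection function (RSF) per
   herd–season–strategy from used vs. available locations;
4. summarize differentiation with consistency scores — mean absolute
   differences between selection coefficients across levels of one index —
   with Monte Carlo uncertainty propagation and Dunnett's T3 ranking.

Because real telemetry deployments cannot ship inside a package, a
synthetic-data module generates landscapes and GPS trajectories with
*known* selection coefficients and migration timing, so every downstream
stage is benchmarked against ground truth.

# Synthetic landscapes

`make_landscape()` builds a flat projected grid (default 240 × 240 cells
at 250 m, i.e. 60 × 60 km). Landcover (forest, herbaceous, crops,
residential, other) is assigned by quantile bands of a smooth random
field, a terrain-position proxy: residential and crops occupy the
"valley" band, forest the "upland" band. This yields exactly the
requested class proportions, connected patches with a controllable
characteristic diameter (`patch_km`, default 1.2 km), and the ecological
association between development, agriculture, and low terrain. Roads are
straight transects (default 12, emulating a county road network's
within-range density). Distance layers are exact Euclidean distances from
cell centers to the nearest source cell; a layer without sources (an
all-forest map has no residential cells) saturates at the landscape
diagonal rather than becoming infinite. NDVI is an 8-day period stack:
a spatial base field (SD 0.18, patch-scale texture), a spatial amplitude
field, and a within-year cosine peaking near day 200, clipped to
[-1, 1]. The fine spatial texture matters: third-order selection is
identified only by within-range contrast, so a landscape smooth at the
home-range scale would make NDVI selection unidentifiable no matter how
the animals behave.

# The movement and selection generator

Each animal holds a circular seasonal range (radius `range_radius`,
default 3 km, ≈ 28 km²) around a centre. At every fix interval the
generator proposes `n_candidates` (default 30) positions uniformly within
the disc and keeps one with probability proportional to
`exp(beta' x)` evaluated on the candidate's covariates — a discrete-choice
thinning whose stationary used distribution is the exponential RSF over a
uniform availability domain, exactly the model the estimator assumes.
Migrant centres relocate between winter and summer centres (default
separation 40 km) along a logistic displacement curve, which produces the
double-sigmoid NSD signature; the true departure/arrival dates recorded in
the truth table are the days the *squared* displacement of the centre path
crosses 5% and 95% of its plateau, i.e. the same definition the classifier
applies to fitted NSD curves (on the falling return transition the
crossings mirror).

Two design choices deserve comment:

* **Uniform-disc proposals rather than an autocorrelated walk.** An
  Ornstein–Uhlenbeck-style attraction walk produces centre-weighted
  usage; fitted against the uniform-within-isopleth availability that the
  RSF stage (and the field's standard practice) assumes, that
  centre-weighting acts as an unmodelled spatial covariate and biased
  smooth covariates severely in recovery experiments — NDVI coefficients
  could even change sign. The disc generator trades step-level
  autocorrelation (which no stage of this pipeline uses) for an exactly
  well-specified selection model. Consequently the synthetic data do *not*
  emulate serial autocorrelation of fixes, fix-loss gaps, or behavioural
  states beyond range residency and migration, and passing tests say
  nothing about those features of real data.
* **Finite candidate sets attenuate.** With K candidates the realized
  enrichment is slightly weaker than `exp(beta' x)`, and the fitted 95%
  isopleth trims low-use area, enriching the availability sample. Both
  shrink coefficients by a roughly covariate-uniform factor (about
  0.65–0.9 in the recovery runs), so recovery is asserted on rank
  correlation and tolerance bands, not equality.

True coefficient grids come from `make_beta_grid()`. The default
"hierarchical" style plants additive herd, season, and strategy offsets
(scales 0.5 / 0.3 / 0.12) weighted most heavily on anthropogenic
covariates and least on NDVI — the ordering the consistency analysis is
expected to recover. The "distinct" style gives every herd–season–strategy
model a different signed permutation of six well-separated values in
[-1, 1] and exists for coefficient-recovery benchmarks.

# Movement-strategy classification

`compute_nsd()` is anchored at the first fix and reports km² against days
since first fix (keeping optimizer magnitudes O(1)–O(10³)).
`fit_nsd_models()` fits the five-model family — resident (constant), nomad
(linear drift), disperser (single logistic), migrant (double logistic,
equal asymptotes), mixed migrant (free return asymptote) — by
Levenberg–Marquardt least squares with data-driven starts (asymptote = max
NSD, midpoints at the half-maximum crossings, 7-day timescale) and box
constraints (non-negative asymptotes, positive timescales); migratory fits
with out-of-order transitions are invalidated rather than silently kept.

Model selection uses AICc; the call is `ambiguous` when the top two models
are within 2 AICc but imply different strategies. Two further rules:

* tracking spans of ≤ 5 months are excluded as insufficient data;
* a fitted displacement amplitude below `min_delta` (default 25 km²,
  i.e. a 5 km shift) implies residency regardless of model class. Without
  this, small-amplitude sigmoids routinely out-fit the constant model on
  wandering-but-stationary series, misclassifying residents; ecologically
  these are the short-distance commuters that belong with residents.
  Nomad-class fits (sustained drift) map to the disperser strategy, which
  also covers settling dispersal.

Migration departure and arrival are the deterministic 5%/95% asymptote
crossings of the fitted sigmoid, `theta ± phi·ln 19`, so the transition
window has width `2·phi·ln 19` exactly and collapses to the midpoint as
`phi → 0`. Elevation shifts are not used by the classifier (the pipeline
carries no elevation layer); the hook is the ambiguity threshold, which is
configurable.

Season delineation follows the three-range approach: migrants are cut at
their own fitted dates with transit fixes excluded; residents are cut at
their herd's median migrant dates. Animals first located after spring
departure simply lack a first winter and continue with a summer-led
sequence. A seasonal range is usable with ≥ 50 fixes spanning ≥ 30 days
(configurable); animals with fewer than two usable ranges are flagged
unclear and dropped from selection modelling — a documented stand-in for
the exclusion of animals whose seasonal space use cannot define
availability.

# Range delineation

The reference (ad hoc) bandwidth is `h = sigma·n^(-1/6)` with
`sigma² = (var(x)+var(y))/2`. The KDE is evaluated on a grid defaulting to
the point extent plus 3.5 h margin at resolution h/3 (coarsened beyond
250,000 cells); margins below 3 h are rejected once clipped kernel mass
exceeds 0.1%. Cell masses are renormalized to sum to one, making the
isopleth property exactly testable: the 95% isopleth is the minimal
density-sorted prefix of cells reaching 0.95 cumulative mass, ties broken
deterministically in cell storage order. Isopleths are kept as raster cell
sets (GeoJSON export writes the cell squares); disjoint patches are all
retained. Movement-model estimators (dBBMM, autocorrelated KDE) and
cross-validated bandwidths are out of scope.

# RSF estimation

Availability is the animal's own seasonal 95% isopleth: 10,000 available
points per animal-season-year, uniform over isopleth cells and uniform
within a cell, each given a date resampled with replacement from the
stratum's used-fix dates so that NDVI is date-matched on both sides of the
design (used points are matched to their own fix dates — the
date-matched interpretation is assumed for both). Landcover enters as
indicators against the forest reference; distances are
`ln(d + 1)` with d in meters; continuous covariates are centred and scaled
by the pooled rows of each model's own table, with the constants recorded
for back-transformation. Because scaling is per model, consistency
comparisons operate on standardized coefficients — an interpretive caveat
inherited from scaling "before inclusion in models" without a global
reference. Covariates with VIF ≥ 10 (computed on available rows,
iteratively dropping the worst) are excluded, and the covariate set is
harmonized within each herd-season so the migrant and resident models of a
pair stay comparable.

The default estimator is two-stage: an unconditional logistic fit per
stratum, pooled per covariate by inverse-variance weighting with a
DerSimonian–Laird between-stratum variance (`metafor::rma.uni`,
method "DL") — the meta-analytic mirror of a random-slopes model, at a
small fraction of its cost. A storage-identical `mixed` estimator
(glmmTMB, random intercept + independent random slopes per stratum) is
available where the full likelihood is wanted. A stratum informs a
covariate only where its estimate is bounded (|beta| ≤ 15, SE ≤ 50 on the
standardized scale); separation and within-range absence of a landcover
class surface as unbounded estimates and are excluded cell-wise with a
warning. The weighted-likelihood RSF refinement (large weights on
available points) is deliberately not used, matching the plain binomial
fit; it can be grafted on per stratum if needed.

# Consistency analysis

The consistency score for a comparison is the mean over all unordered
level pairs of the varying index (herd, season, or strategy) and over the
covariates considered of |beta_i − beta_j|: non-negative, zero only for
identical vectors, translation invariant. Aggregate groupings average the
score over the fixed-index combinations with equal weights (whether to
weight by animals per model is unstated in the source methodology;
unweighted is used). Herds lacking one strategy are excluded from all
comparisons — the all-migrant herd case. Uncertainty is propagated by
drawing every coefficient independently from `Normal(beta, se²)` (models
are fit independently, so no cross-covariance exists) and recomputing each
grouping score B = 10,000 times (seeded, configurable).

Dunnett's T3 compares the Monte Carlo distributions: Welch statistics with
Welch–Satterthwaite degrees of freedom, p-values from the studentized
maximum modulus distribution sized by the number of pairwise comparisons
(one-dimensional numerical integration over the chi density; the normal
limit is used above 2000 df where the integrand is numerically
degenerate), and compact-letter-display letters by insert-and-absorb
merging at alpha = 0.05. Because the "samples" entering T3 are Monte Carlo
draws, p-values are budget-dependent — they are reported alongside the
score means and intervals, never alone. Strategy-composition summaries use
Goodman simultaneous multinomial intervals (chi-square based,
Bonferroni-sized across the four categories). The migrant-prevalence
correlation is a plain two-sided Pearson test across herd-level scores.

# Pipeline

`run_pipeline()` orchestrates simulate/load → classify → ranges → rsf →
consistency from one configuration (R list or YAML), fanning a single
global seed out deterministically to per-stage seeds so stages can be
rerun in isolation. Every stage writes plain CSV; the JSON manifest
records seeds, row counts, and the animal-year accounting (every input
animal-year lands in exactly one of analyzed / excluded-with-reason).
Rerunning an identical configuration reproduces byte-identical CSVs.
Stage toggles reuse cached CSVs; a missing upstream artifact fails naming
the stage. `inst/scripts/hierrsf.R` is a thin optparse wrapper exposing
the stages as shell subcommands.

# Numerical and testing choices

* NSD residual floors (1e-12) keep AICc finite on exact fits; the
  resident and nomad members have closed-form least-squares solutions.
* KDE evaluation uses the separability of the isotropic Gaussian kernel
  (two thin matrices and one product), so a 5,000-point range on a
  250,000-cell grid stays in milliseconds.
* The test suite runs the pipeline end-to-end at reduced problem sizes
  chosen to keep the full suite within a coffee break while leaving the
  asserted properties identifiable: 20 × 20 km landscapes for unit tests,
  40 km landscapes with 16–40 animals for recovery and hierarchy checks,
  100 animal-years × 3 seeds for classification accuracy, B = 10^5 draws
  for the closed-form Monte Carlo check, and 1,000 simulated families for
  the T3 calibration.
* Classification benchmarks simulate with all selection coefficients at
  zero: strategy and timing are properties of the movement geometry, and
  the zero-selection generator exercises the identical kernel at a
  fraction of the cost.

# Known limitations

* Selection recovery is approximate by construction (finite candidate
  sets, isopleth trimming); magnitudes shrink by a covariate-uniform
  factor and only rankings and signs should be interpreted strictly.
* Standardized coefficients are compared across models whose scaling
  constants differ; with strongly different within-range covariate
  spreads this mixes scaling differences into consistency scores.
* The simulator emits complete fix series; fix-failure gaps are left as a
  configuration hook.
* Real-raster ingestion is limited to the package's plain-text grid
  format; projected-meter coordinates are assumed throughout (no
  geodesy).
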