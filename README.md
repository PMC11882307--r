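# hierRSF

Hierarchical structuring of resource selection in partially migratory
ungulates: a simulation-backed analysis pipeline for asking *what
structures fine-scale habitat selection most — herd, season, or movement
strategy?*

Partially migratory populations hold migrants (distinct winter and summer
ranges) and residents (one year-round range) side by side. `hierRSF`
implements the full chain needed to compare their selection behaviour
across herds and seasons:

1. **Movement-strategy classification** from net squared displacement
   (NSD): the five-model family — resident `NSD(t) = c`, nomad
   `beta·t`, disperser `delta / (1 + e^{(theta - t)/phi})`, migrant
   `delta [1/(1+e^{(theta-t)/phi}) - 1/(1+e^{(theta2-t)/phi2})]`, and a
   mixed-migrant variant with a free return asymptote — fit by nonlinear
   least squares and selected by AICc, with migration departure/arrival
   at the 5%/95% asymptote crossings `theta ± phi·ln 19`.
2. **Seasonal range delineation**: 95% isopleths of bivariate normal
   kernel density estimates with the reference bandwidth
   `h = sigma·n^{-1/6}`.
3. **Third-order resource selection functions** per herd–season–strategy:
   used fixes vs. 10,000 available points per animal-season-year drawn
   from the animal's own isopleth, exponential RSF
   `w(x) = exp(beta' x)` fit as used/available logistic regression with
   animal-season-year strata (two-stage inverse-variance pooling with
   method-of-moments between-stratum variance, or a glmmTMB random-slopes
   mixed model), forest as the landcover reference, `ln(d+1)` distances,
   VIF ≥ 10 screening.
4. **Consistency scores**: for an index (herd, season, strategy), the
   mean absolute difference of selection coefficients over all unordered
   level pairs and covariates — larger means more differentiation — with
   Monte Carlo uncertainty propagation from the coefficient standard
   errors, Dunnett's T3 ranking with compact letters, covariate-group
   subsets (anthropogenic / habitat / productivity), and Goodman
   simultaneous intervals for strategy composition.

A first-class **synthetic-data module** generates landscapes (landcover,
distance-to-development, distance-to-roads, 8-day NDVI) and GPS
trajectories with *known* selection coefficients and migration timing, so
classification accuracy, timing error, and coefficient recovery are all
benchmarked against ground truth without downloading anything.

## Worked example

```r
library(hierRSF)

scen <- make_scenario(
  herds = data.frame(herd = c("North", "South"), n = c(8, 8),
                     migrant_prop = c(0.5, 0.5)),
  fix_interval_h = 4, sep_km = 20,
  landscape_args = list(n_rows = 160, n_cols = 160, cell_size = 250))
pop <- simulate_population(scen, seed = 1)
pop
#> <rsf_population> 16 animal-years, 32848 fixes (North, South)
#>         migrant resident
#>   North       4        4
#>   South       4        4

calls <- classify_population(pop$fixes)
table(calls$herd, calls$strategy)     # every animal-year called correctly
#>         migrant resident
#>   North       4        4
#>   South       4        4

season_table <- herd_median_dates(calls)
round(season_table[, c("dep1", "arr1", "dep2", "arr2")])
#>   dep1 arr1 dep2 arr2
#> 1  142  162  258  277
#> 2  147  158  270  287
```

Spring departure around day 145 and an autumn return near day 270 are the
herd median migration dates (study days); residents are cut into the same
seasonal windows. Ranges, RSFs, and the consistency analysis:

```r
strata <- build_strata(pop$fixes, calls, season_table)
coefs  <- fit_all_rsf(strata, pop$stack, n_available = 2000, seed = 2)
subset(coefs, herd == "North" & season == "winter" & strategy == "migrant",
       select = c(covariate, beta, se))
#>             covariate        beta         se
#> 1               crops -0.40957970 0.18650247
#> 2          herbaceous  0.13084686 0.13371383
#> 3               other -0.65622161 0.12519549
#> 4 ln_dist_development  0.45913940 0.05417940
#> 5       ln_dist_roads -0.76566303 0.01747634
#> 6                ndvi  0.01968655 0.04267500

ca <- consistency_analysis(coefs, B = 5000, seed = 3)
subset(ca$scores, subset == "all")
#>                grouping subset mean lo95 hi95 letter
#>              among_herd    all 0.67 0.62 0.72      a
#>          between_season    all 0.31 0.26 0.35      b
#>        between_strategy    all 0.21 0.17 0.25      d
#>  season_strategy:winter    all 0.19 0.14 0.25      e
#>  season_strategy:summer    all 0.23 0.17 0.29      c
#>              herd:North    all 0.22 0.15 0.28   <NA>
#>              herd:South    all 0.20 0.16 0.25   <NA>
```

Coefficients are standardized log odds of selection relative to
availability. A positive coefficient on a log-distance covariate means
selecting areas *farther* from the feature: herd North's winter migrants
avoid development (`ln_dist_development` +0.46) while sitting close to
roads (`ln_dist_roads` −0.77) — a planted herd-level contrast in the
simulation's true coefficient grid. The consistency table reads: selection behaviour differs
most among herds (0.67, letter `a`), then between seasons (0.31), and
least between strategies within a herd-season (0.21), with migrants and
residents more alike in winter (sympatric, 0.19) than in summer
(allopatric, 0.23); all five distributions are significantly distinct
(distinct letters). The `ca$scores` rows with `subset != "all"` give the
same groupings restricted to anthropogenic, habitat, or productivity
covariates, and `ca$pairwise` holds the Dunnett T3 p-value table.

The whole chain, including CSV artifacts and a JSON run manifest, is one
call:

```r
res <- run_pipeline(default_config(seed = 1, out_dir = "run1"))
```

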