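---
title: "Methods: comparing the climatic niches of oviparous and viviparous clades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing the climatic niches of oviparous and viviparous clades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parityNiche)
```

# The scientific question

The Eurasian common lizard (*Zootoca vivipara*) reproduces in two ways:
two of its six genetic clades (A, B) lay eggs (oviparity) and four
(C--F) bear live young (viviparity). The three main hypotheses for the
evolution and maintenance of viviparity make distinct predictions about
the climate each parity mode should occupy **during the reproductive
period (May--July)**:

* **cold-climate hypothesis (CCH)** -- viviparous animals occupy colder
  average temperatures (prediction CCP~1~);
* **maternal-manipulation hypothesis (MMH)** -- viviparous animals
  occupy colder (MMP~1~) or warmer (MMP~2~) and/or *more* variable
  (MMP~3~) climates;
* **selfish-mother hypothesis (SMH)** -- viviparous mothers favour
  habitats that are less risky for themselves: *less* variable (SMP~1~)
  and possibly warmer (SMP~2~) climates.

`parityNiche` implements the full analytical machinery needed to test
these predictions from monthly climate rasters and georeferenced clade
occurrences: window-specific bioclimatic variables, a
background-calibrated PCA ordination of climate with kernel occupancy
surfaces and Schoener's *D*, permutation niche similarity and
equivalency tests, classification trees discriminating parity mode, and
the nine-row lookup that maps an observed difference pattern to the
hypotheses it supports.

# Bioclimatic variables over a month window

All variables are computed per pixel from monthly minimum temperature,
maximum temperature (degC) and precipitation (mm) over a configurable
window of calendar months, with `tavg_m = (tmin_m + tmax_m) / 2`:

| variable | definition | units |
|---|---|---|
| BIO1 | mean of `tavg_m` | degC |
| BIO2 | mean diurnal range `mean(tmax_m - tmin_m)` | degC |
| BIO3 | isothermality `100 * BIO2 / (max(tmax_m) - min(tmin_m))` | % |
| BIO4 | temperature seasonality `100 * sd(tavg_m)` | degC x 100 |
| BIO6 | minimum temperature of the coldest window month | degC |
| BIO15 | precipitation seasonality `100 * sd(prec_m) / (1 + mean(prec_m))` | % |
| minTmax | minimum over window months of monthly `tmax` | degC |
| meanTmin | mean over window months of monthly `tmin` | degC |

Conventions, chosen once and recorded in the `BioclimSet` object:
standard deviations are *sample* SDs (denominator `n - 1`, the common
bioclim convention), and BIO15 uses the `+1` in the denominator so the
coefficient of variation is defined for dry pixels. A window of one
month is rejected (its SD is undefined); a pixel whose window
temperature range is zero gets `BIO3 = NA` with a warning. The default
variable sets are the seven-variable reproductive set
(`reproductiveVars()`: BIO2, BIO3, BIO4, BIO6, BIO15, minTmax,
meanTmin) and a six-variable annual set (`annualVars()`: BIO1, BIO2,
BIO3, BIO4, BIO6, BIO15); both are plain character vectors and fully
configurable.

Rasters are exchanged as ESRI ASCII grids (`tmin_01.asc` ..
`prec_12.asc`), a plain-text raster format that keeps worlds, fixtures
and real data interchangeable; an integer-storage scale factor
(temperatures stored as degC x 10) is supported on read. Points map to
pixels by the pixel-is-area floor convention.

# Niche quantification (PCA-env)

The analysis extent is the convex hull of the occurrence coordinates; a
background of `bgN` pixels (study design: 20,000) is sampled uniformly
without replacement inside the hull. A correlation-matrix PCA is
calibrated on the pooled background + occurrence climate rows (mixed
units make unit-variance scaling mandatory); axis signs are fixed so the
largest-magnitude loading of each axis is positive, which makes runs
reproducible without changing the subspace.

A grid of `gridSize x gridSize` cells (default 100 x 100) is laid over
the first two axes. Extents are the min/max of the background scores
expanded by a 5% margin per side so kernels are not clipped at the data
envelope; the identical extents are reused for every clade in a run,
which is what makes the surfaces comparable. Each clade's occurrence
scores are smoothed with a Gaussian product kernel (Silverman
rule-of-thumb bandwidth per axis, estimated from the clade's own scores,
with a scalar multiplier for sensitivity analysis; a degenerate axis
falls back to 1/20 of the grid extent). Occupancy comes in two modes:

* `"corrected"` (default): `z` is proportional to `o / e`, the occurrence
  density divided by the background availability density, so `z`
  measures *preference* relative to what climate is available; cells
  whose availability is at or below `eps = 1e-12 * max(e)` get `z = 0`.
* `"raw"`: `z` is proportional to `o` alone.

Both are normalized so `sum(z) = 1`. Overlap between clades is
Schoener's

$$D = 1 - \tfrac{1}{2}\sum_{cells} |z_1 - z_2| \in [0, 1].$$

# Permutation tests

**Similarity** (two-tailed): per replicate, *both* clades' occupancy
surfaces are translated by independent uniform random cell offsets --
the surface's density-weighted centroid is sent to a uniformly drawn
cell inside the bounding box of the background-supported region; mass
shifted off the grid is dropped and the surface renormalized. A
documented flag shifts only one surface instead.

**Equivalency** (lower-tailed, rejects when `D_obs` is *smaller* than
chance): per replicate, the pooled occurrences of the pair are randomly
re-partitioned into the original group sizes and both surfaces are
rebuilt from scratch, bandwidths re-estimated from the permuted groups
-- the permutation repeats the entire estimation procedure, which is
what makes the test exact under exchangeability.

P-values use the add-one convention,
`p = (1 + #{D_sim <= D_obs}) / (n + 1)` (never exactly zero); the
two-tailed p doubles the smaller tail and caps at 1. Replicate `r`
draws from seed `base + r`, so runs are reproducible and trivially
parallelizable. Inside one replicate, random draws are assigned to the
two clades in sorted label order, so swapping the arguments reproduces
identical results -- a property the test suite asserts exactly.
Significance codes for tables: `**` p <= 0.01, `*` p < 0.05, `NS`
otherwise; the pairwise output table carries `D` (with similarity
asterisks) below the diagonal and equivalency codes above it.

# Discriminating parity modes with a classification tree

The tree machinery is authored in the package so that every quantity the
analysis reports (surrogate agreement, per-split importance, direction
tags) is available exactly as defined, and it is cross-checked against
`rpart` in the test suite:

* **Growing**: binary Gini splits (`dG = G(parent) - weighted child
  impurity`) over midpoints of consecutive distinct values; `cp = 0` so
  every impurity-decreasing split is kept; defaults `minsplit = 20`,
  `minbucket = 7` (classic CART practice; tests use small-data
  overrides). Ties go to the smaller threshold, then the earlier
  covariate -- deterministic trees.
* **Surrogates**: up to `n_covariates - 1` per split, kept only when
  they beat the blind majority-direction rule, used to route missing
  values (surrogates in agreement order, then majority direction).
* **Pruning**: weakest-link cost-complexity on the misclassification
  cost; the reported sequence starts at the cp = 0 *optimum* (branches
  with zero cost reduction are already collapsed, so each row of the
  sequence is exactly what `pruneAt()` returns). 10-fold
  *stratified* cross-validation evaluates the sequence at the geometric
  means of consecutive cp values; `xerror` is relative to the root
  (majority-rule) error and `xstd` is its binomial standard error. The
  final tree is the smallest subtree within one `xstd` of the minimal
  `xerror` (1-SE rule).
* **Importance**: each split credits its primary variable with
  `dG x n_informative` and each surrogate with that credit weighted by
  its *adjusted* agreement, `(agreement - baseline) / (1 - baseline)`
  where the baseline is the majority-direction rule. Raw agreement was
  considered and rejected: any retained surrogate agrees at least as
  often as the majority share (~0.5--0.6), so raw weighting hands
  uninformative covariates 10--15% importance each and defeats the
  significance rule below; the adjusted form is also what `rpart`, the
  reference implementation of this analysis, uses. Credits are
  normalized to percent globally or per split; a covariate is
  *significant* when its share exceeds `100 / n_covariates`. Direction
  tags report the sign of the Spearman correlation with the scope's
  main variable on the node's cases.
* **Confusion summaries** report correct counts and one-decimal
  percentages per parity mode, per clade and overall
  (`percentCorrect()` is the single rounding point). Resubstitution
  predictions are used for the per-clade table, matching the convention
  that leaf counts add up to the full sample.

# From tree to hypotheses

Covariates are classed as *variability*-type (BIO2, BIO3, BIO4, BIO15)
or *average-temperature*-type (BIO1, BIO6, minTmax, meanTmin). For each
class, the direction of the viviparous-oviparous difference is decided
by majority vote over the *significant* covariates of that class, using
the sign of the standardized mean difference (viviparous minus
oviparous); an exact tie yields `none` with a warning. The resulting
pattern is looked up in the nine-row combination table
(`hypothesisCombinations()`); rows 6 and 8 are conditional and are
reported with their footnotes attached rather than resolved, because the
trade-off magnitudes they reference have no decision rule. The report
(`hypothesisReport()`) serializes losslessly to JSON.

# The synthetic world

No occurrence or climate data are redistributable, so the package ships
a generator whose defaults mirror the study design: six clades with 37,
41, 19, 26, 47 and 15 occurrences (185 in total; A, B oviparous), a
200 x 200 pixel world, and the May--July reproductive window.

Monthly mean temperature per pixel is
`base + amp * cos(2*pi*(m - 7)/12) + w * s_m + noise`, where `base`
(mean 11, SD 4 degC), `amp` (mean 8, SD 2 degC) and the diurnal range
(mean 10, SD 2 degC) are smooth Gaussian random fields (spectral
smoothing of white noise on a torus, correlation length 1/8 of the grid
side), and `w` (SD 3 degC) multiplies the pattern `s = (-1, 0, +1)`
over May/June/July. The `w` field is the deliberate core of the design:
it modulates *within-window* temperature spread without moving the
window mean, so reproductive-window seasonality (BIO4) can be varied
independently of both annual seasonality (driven by `amp`) and window
average temperature -- without it, "lower window seasonality" would
mechanically imply "lower window mean temperature" and every
variability scenario would leak into the average-temperature variables.
Precipitation is log-normal with a smooth seasonal modulation, giving
spatial variation in BIO15.

Occurrences are sampled per clade without replacement with probability
proportional to a Gaussian suitability around the clade's niche
centroid, expressed in standard deviations of the named bioclim field.
Presets: `null` (uniform suitability -- clades exchangeable, the basis
of the type-I experiments), `smh_reproductive` (viviparous window BIO4
and BIO15 centroids 1.5 SD lower), `cch_cold` (meanTmin and BIO6 1.5 SD
lower), `mmh_variable` (BIO4 and BIO15 1.5 SD higher) and
`annual_reversal` (window BIO4 1.5 SD lower *and* annual BIO4 1.5 SD
higher, reproducing the qualitative sign flip between the reproductive
and annual analyses).

What the generator does *not* emulate: orography and lapse rates,
spatial clustering of clades into geographic ranges (suitability is
purely climatic), dispersal limitation, and observation error in
coordinates. Passing tests therefore demonstrate that the statistical
machinery recovers known niche structure from clean climatic signals at
the study's sample sizes -- not that it would survive the sampling
biases of real atlas data.

# Numerical choices and problem sizes

* Kernel availability floor `eps = 1e-12 * max(e)`; cells at or below it
  get `z = 0` in corrected mode.
* Degenerate-bandwidth fallback: extent/20.
* Tie-breaks in the tree are deterministic (smaller threshold, earlier
  covariate); predictions for ties in leaf majorities go to the first
  class level (oviparous).
* All randomness flows from explicit seeds; helper `withSeed()`
  restores the caller's RNG state, so library calls never perturb a
  session's stream.
* The test suite runs the permutation-calibration experiment at 500
  simulated null datasets x 99 permutations with a 2,000-pixel
  background, scenario recovery at 100 seeded worlds, and the pipeline
  tests on 60 x 60 worlds with reduced background and permutation
  counts; the acceptance script additionally runs one full-scale
  reproductive-period analysis (20,000 background pixels, 100 x 100
  grid, 1,000 permutations per pair). These sizes keep a complete run
  on one desktop core in the minutes range while leaving the binomial
  confidence of the rate checks well inside the asserted bounds.

# Known limitations

* Geographic-space overlap, MaxEnt-style suitability models and niche
  metrics beyond Schoener's *D* (e.g. Hellinger's *I*) are out of
  scope.
* The similarity test's shift distribution ("uniform within the
  background-supported extent") is one of several reasonable readings
  of surface-shift permutation; the choice is isolated in
  `similarityTest()` and exercised by an exhaustive small-grid oracle.
* Importance credit for surrogates follows the adjusted-agreement
  convention; the reference software documents its exact formula only
  loosely, so small numeric differences from other implementations are
  expected even though primary-split credit is identical.
* The hypothesis lookup reports conditional combinations (6, 8) with
  footnotes instead of resolving them; resolving would require
  quantifying the fitness trade-offs, which no input here measures.
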