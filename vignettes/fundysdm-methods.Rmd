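---
title: "Methods: presence-only maximum-entropy habitat models for Bay of Fundy basking sharks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only maximum-entropy habitat models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundysdm)
```

## The estimation problem

Basking shark occurrence in the lower Bay of Fundy is known only from
surface sightings collected opportunistically from whale-watch and
survey vessels. There are no absences, the sampling effort is
concentrated near one coast, and repeat sightings of aggregations
inflate local densities. `fundysdm` treats this as a presence-only
density-estimation problem on a raster: estimate, for each month from
July to October, a probability distribution over the grid cells of the
study area that is as close to uniform as possible (maximum entropy)
while matching the environmental conditions observed at the sighting
cells.

The distribution is the Gibbs density `p_λ(i) ∝ exp(Σ_j λ_j f_j(i))`
normalized over *background* cells — a sample of the available
environment (all unmasked cells up to a cap of 10 000, with presence
cells always included, following the convention that presences are part
of the background). Features `f_j` are transforms of the ten predictor
layers (depth, aspect, slope, distances to the 0/50/100/150/200 m
isobaths, chlorophyll-a, SST): linear, quadratic, pairwise product,
threshold steps and hinge ramps, each scaled to [0, 1] over the
background. Threshold and hinge knots sit at evenly spaced background
quantiles, at most `knots_per_variable` (default 10) per variable, and
are frozen into the feature expansion so that permuted or held-out data
are expanded identically.

## Fitting and regularization

The weights maximize the penalized mean log-probability of the `m`
presences,

$$\frac1m \sum_{\text{presences}} \log p_\lambda(i)
  \;-\; \beta \sum_j s_j \lvert\lambda_j\rvert,
  \qquad s_j = \frac{\mathrm{sd}_{\text{bg}}(f_j)}{\sqrt m}.$$

The per-feature scale `s_j` is a single simple rule applied uniformly to
all feature classes; class-specific tuning tables used by some
implementations are deliberately not reproduced, and the rule is
documented here precisely so results are interpretable. The solver is
proximal-gradient ascent with backtracking line search: a gradient step
on the smooth part followed by soft-thresholding at `t·β·s_j`. This
choice matters for model selection — soft-thresholding produces *exact*
zeros, so the parameter count `k` entering AICc is well defined rather
than an arbitrary epsilon cutoff. Defaults are `tol = 1e-5` on the
largest weight update, `max_iter = 500`; hitting the cap returns the
current iterate flagged `converged = FALSE`, which is routine for L1
problems near the optimum and harmless for the cumulative (rank-based)
output. The optimization uses no randomness, so identical inputs give
bit-identical weights.

The training gain is the mean log ratio of fitted presence-cell
probability to the uniform baseline, in nats; 0 for the uniform model.
Suitability is reported on the cumulative 0–100 scale: a cell's score is
100 times the total raw probability of all cells with equal or lower
probability, ties sharing a value, so the most probable cells always
score 100. The logistic transform is intentionally not implemented —
the cumulative output is the one used throughout this analysis, and
offering one output avoids ambiguity about which scale downstream
thresholds refer to.

Per month, β is selected by AICc = 2k − 2 log L + 2k(k+1)/(n − k − 1)
over the grid β ∈ {1, 3, …, 17}, where log L is the presence
log-likelihood of the suitability surface re-standardized to sum to 1
and n is the presence count. AICc is undefined when n ≤ k + 1; such
records are flagged rather than dropped silently, ties go to the
smaller (more regularized) grid value, and selection errors only if
every candidate is undefined. The likelihood is evaluated on the model
refit to *all* presences, not on cross-validation folds, matching the
procedure order of the monthly analysis (select first, then replicate).

## Thinning and autocorrelation diagnostics

Shore-biased effort produces spatially clustered sightings that violate
the implicit assumption of effort-independent sampling. Sightings are
therefore decimated before fitting: the expected average
nearest-neighbor distance under complete spatial randomness,
`0.5/√(n/A)`, is computed from the month's unique sighting locations
(`A` = the modelled area when supplied, else the bounding rectangle — the
common GIS default), and a greedy pass in seeded random order keeps each
location only if it lies at least that far from every location already
kept. Greedy seeded decimation is used because the original GIS routine
is unspecified; the seed is recorded so runs are reproducible. Months
whose retained count would be 5 or fewer are passed through unthinned
with a logged `skipped` flag — with so few points decimation is
meaningless and the records are assumed to come from the more uniform
survey platform. Thinning operates on unique locations rather than
expanded individual counts, since repeat individuals at one location are
exactly the duplication thinning is meant to remove. Moran's I
correlograms (binary distance-band weights, null expectation −1/(n−1))
and empirical semivariograms (γ = mean of half squared differences per
distance bin) are provided as diagnostics; variogram *model fitting* is
out of scope, as distance-based decimation proved unusable for these
data and only the ANN routine is load-bearing.

## Evaluation

Background cells act as pseudo-negatives (the standard device for
presence-only ROC analysis; the negative set is a modelling choice, not
data). AUC is computed in Mann–Whitney form — the probability a
presence outscores a background cell, ties counting half — and the
published discrimination bins are applied verbatim: below 0.5 worse
than random, 0.5–0.7 no discrimination, above 0.7 better than random, 1
perfect. The habitat threshold is the cumulative score maximizing
sensitivity + specificity over the observed scores, ties resolved
toward the *lower* threshold: the more inclusive habitat map is the
conservative choice for conservation delineation, and "suitable" means
score ≥ threshold so that threshold 0 marks everything suitable and
area accounting is bit-exact.

Three replicated fitting routines are provided. Cross-validation
partitions presences into `k = min(replicates, n)` folds (so a request
for 100 replicates on 4 presences is leave-one-out); bootstrap refits on
n-out-of-n resamples and reports training AUC; subsampling uses seeded
75/25 train/test splits. All cap at 100 replicates. Ensembles report
the AUC mean/SD and cellwise mean/SD suitability maps; the SD map is
exactly zero at one replicate.

Variable importance comes in three forms. *Percent contribution*
allocates each optimizer iteration's gain increase to variables in
proportion to the penalty-scaled weight movement `Σ |Δλ_j|·s_j` of
their features (products split evenly between their two variables);
sequential-update attribution has no exact analogue in a
simultaneous-update solver, so this is documented as the approximation
it is. *Permutation importance* permutes one variable's raw values
across the design rows, rebuilds the features with the frozen scaling
and knots, and records the training-AUC drop, floored at zero; both
percentage columns normalize to 100. The *jackknife* refits with each
variable alone and each variable omitted, reporting training gains.

Month-to-month distribution change is the sample (Brownian) distance
correlation between jointly unmasked suitability values of the
replicate-mean surfaces: pairwise absolute-difference matrices are
double-centered and combined as `sqrt(dCov² / sqrt(dVarA·dVarB))` — the
standard sample coefficient in [0, 1], affine-invariant, zero in the
population exactly under independence. Comparisons use replicate-mean
maps because the monthly prediction, not any single replicate, is the
object of interest.

## The synthetic-data generator

No sighting data are published, so the generator is the package's
test bed and defines its study conditions. It emulates: a 40 × 50 cell
domain at 2.5 km resolution (6.25 km² cells, comparable in extent to
the 7539 km² study area), a western coastal margin with a masked land
interior and a narrow unmasked intertidal strip of negative depths (so
the 0 m shore contour exists as a genuine sign change), a shelf
deepening eastward into a > 200 m basin with smooth superimposed
ledges, lognormal chlorophyll-a fields with a late-summer mean maximum
(2.5/3.5/3.0/1.5 mg m⁻³ for July–October), SST with a north-south
gradient cooling into October (13.5/15.0/14.0/10.5 °C offsets), monthly
presence counts defaulting to the observed 90/554/221/19, and a smooth
sampling-effort surface decaying away from the western coast to mimic
shore-based whale-watch effort. The truth surface is a Gibbs density on
a linear combination of scaled predictors, loading by default on
distance to shore, the 150 m and 200 m isobaths, chlorophyll-a and SST —
the variables that dominate the monthly importance rankings — with
coefficients (−2.5, −4, −1.5, +1.5, +1) chosen once to give a strongly
structured but not degenerate surface. Sightings are drawn
cell-multinomially from truth × effort and jittered uniformly within
the cell so thinning distances are continuous.

What the generator does *not* emulate bounds what passing tests show:
fields are smooth Gaussian-bump composites without tidal fronts, gyre
advection or prey dynamics; monthly layers are independent draws rather
than a coherent seasonal evolution; effort bias is smooth rather than
trackline-shaped; and truth is log-linear in the predictors, which
favors recoverability. Green recovery tests therefore demonstrate that
the pipeline's machinery is correct and statistically coherent — not
that real basking shark habitat would be recovered with the same
fidelity.

## Numerical choices and degenerate inputs

- Gradients use central differences on the 4-neighborhood (documented so
  terrain tests are exact); aspect is the compass direction of
  increasing depth and is undefined (masked) at zero gradient.
- A contour cell is a cell exactly on the level or one of a strictly
  straddling 4-neighbor pair; distances are center-to-center Euclidean.
- Constant variables are dropped from the feature expansion with a
  warning; constant features have zero gradient and keep zero weight.
- A presence on a zero-probability cell yields −∞ likelihood with an
  explicit flag; AICc records with n ≤ k + 1 carry an undefined flag;
  constant-value Moran's I is flagged NA rather than propagating NaN.
- Rasters serialize as ESRI ASCII at 10 significant digits; pipeline
  rerun determinism is byte-exact because reruns recompute identical
  doubles and format them identically.
- Seeds: every stochastic step (background sampling, decimation order,
  fold assignment, resampling, permutation, all generator fields) takes
  an explicit integer seed; monthly generator seeds are small fixed
  offsets of the scenario seed, recorded in the manifest.

## Problem sizes

The test suite runs the statistical core against brute-force oracles on
instances of up to 200 elements, and the end-to-end suites on
single-month scenarios of 40 × 50 cells with 150–500 presences —
5-fold cross-validation for the recovery checks, the full nine-value β
grid (plus β = 0.01 and 100 endpoints) with linear + quadratic +
product features for the selection check. These sizes give stable
stochastic margins (CV AUC > 0.7 on signal, ≈ 0.5 on null, Spearman
> 0.8 against truth) while the whole suite completes in well under a
minute; the same code paths scale unchanged to the full 10 000
background-point configuration.

## Known limitations

- Exact numerical agreement with other maximum-entropy implementations
  is not a goal: the penalty scales, feature-class details and update
  order differ, though the estimand and the selection machinery match.
- No clamping or projection: predictions apply only to the background
  region the model was fit on.
- Bootstrap replicates report training AUC (there is no held-out set),
  so bootstrap AUCs are optimistic relative to cross-validation — the
  routines are provided for comparison, not as interchangeable
  estimates of the same quantity.
- The ANN statistic is the classical uncorrected form; its ratio
  carries a small positive edge-effect bias (~2% at n = 500 on a
  square), which the tests account for.
- `presences_to_cells` drops out-of-extent or masked presences with a
  logged count rather than failing: field data are messy, and silent
  loss is the failure mode actually worth guarding against.
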