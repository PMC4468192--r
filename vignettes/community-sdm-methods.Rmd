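---
title: "Community-based species distribution modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-based species distribution modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Historical biodiversity compilations — museum lots, agency surveys, atlas
projects — record only where a species *was found*. A species never
recorded at a site may be genuinely absent there, or the site may simply
never have been sampled. Treating unsampled sites as absences poisons a
presence–absence species distribution model (SDM) with false negatives;
throwing the absences away entirely forces a presence-only design whose
"background" contrast is much weaker.

This package implements a middle path built on *community* evidence.
Historical fish surveys are community surveys: when a crew sampled a
stream segment, they recorded every species caught. So if other species
were recorded at a segment while the focal species never was, the segment
was demonstrably sampled, and the focal species' absence there is
informative. Formally, for focal species $f$ with incidence matrix
$Y \in \{0,1\}^{S\times K}$ over segments $S$ and species $K$:

$$
\text{label}(s) =
\begin{cases}
1 & Y_{sf} = 1\\
0 & Y_{sf} = 0 \;\wedge\; \sum_{k \ne f,\, k \notin G} Y_{sk} \ge m\\
\text{unlabeled} & \text{otherwise,}
\end{cases}
$$

where $G$ is the set of game species (their presences often reflect
stocking rather than community sampling, so they are excluded from the
evidence by default) and $m$ (`min_other_nongame`, default 1) is the
minimum community evidence required. Unlabeled segments are *not*
absences and never enter the training data.

## Model kinds

Three model families share one prediction contract
(`predict_probability()`, the probability of presence):

* **Lasso logistic regression** (`fit_lasso_logistic`): coefficients
  maximize $\log L(\beta) - \lambda \sum_j |\beta_j|$; $\lambda$ is tuned
  by stratified k-fold cross-validated binomial deviance. Coordinate
  descent is delegated to glmnet.
* **Boosted regression trees** (`fit_brt`): stagewise trees on the logit
  scale with shrinkage (`learning_rate`), depth limit
  (`tree_complexity`), and per-tree row subsampling (`bag_fraction`).
  The ensemble size is chosen at the held-out-deviance minimum over a
  block grid, mirroring the classical stagewise-growth procedure.
  Boosting is delegated to xgboost (exact splits, single thread, seeded),
  and relative influence is the per-variable share of squared split
  improvement, normalized to 100.
* **Presence-background surrogate** (`fit_presence_background`):
  penalized logistic regression of presences against a negative class on
  a linear + quadratic feature expansion — a transparent stand-in for
  maximum-entropy presence-only modeling. Its scientific content is the
  *negative class*: community-inferred absences versus random background
  draws.

Model evaluation is by AUC (Mann–Whitney rank form, ties at 1/2) under
stratified k-fold cross-validation that refits the *entire* recipe —
including internal hyperparameter tuning — inside each fold
(`kfold_cv`). Default k = 5; the prevalence experiment uses k = 10.

## Spatial structure

Residual spatial autocorrelation is diagnosed with Moran's I on Bernoulli
deviance residuals:

$$
I = \frac{n}{\sum_{ij} w_{ij}}
\cdot \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2},
\qquad E[I] = \frac{-1}{n-1},
$$

with a permutation test (default 999 permutations; the p-value
$(1+\#\text{exceedances})/(1+n_\text{perm})$ can never fall below its
resolution) or a Cliff–Ord randomization normal approximation. The weight
matrix is used exactly as supplied — no silent row-standardization.

Spatial predictors come from PCNM (principal coordinates of neighbour
matrices): inter-site distances beyond a truncation threshold $t$
(default: the longest minimum-spanning-tree edge, which keeps the
neighbour graph connected) are replaced by $4t$; $-D^2/2$ is
Gower-centered and eigendecomposed. Eigenvectors are kept when their
eigenvalue is positive and their Moran's I is significant and above the
null expectation (`select_vectors`). "Spatialization" (`spatialize`)
replaces each habitat variable with its fitted values from a regression
on the selected eigenvectors — an idempotent projection onto the
spatially structured subspace.

A deliberate consequence: spatialization *discards* the spatially
independent component of every predictor. When a species truly responds
to fine-grained local habitat, spatialized models will validate worse
than their non-spatial counterparts — visible in the synthetic framework
runs here, where virtual species respond to the full observed habitat.
Spatialization earns its keep when the predictors are noisy observations
of smooth environmental fields, which is exactly the regime the
spatial-filtering experiment constructs.

## The synthetic metacommunity

Because the original environmental and occurrence data cannot ship with
the package, every claim is exercised on a transparent generator whose
defaults are the study conditions:

* **Landscape** (`generate_landscape`): segments uniform on a square of
  extent 100; habitat variables driven by Gaussian random fields with
  exponential covariance $(1-\nu)e^{-d/\rho} + \nu\,1[d=0]$, range
  $\rho = 25$ and nugget $\nu = 0.3$ by default, then mapped to
  realistic scales (temperature, precipitation, elevation, slope, flow,
  base-flow index, land cover, disturbance). Basins are coherent
  vertical strips; coarse watershed units nest inside basins.
* **Species** (`generate_species`): at most one response curve per
  habitat variable — logistic $b(x - m)$, Gaussian
  $-\tfrac12((x-o)/w)^2$, or threshold step — summed on the logit scale.
  The baseline logit is calibrated by root finding so mean occupancy hits
  a target drawn from $U(0.1, 0.6)$; per-visit detection is drawn from
  $U(0.4, 0.9)$; a fraction (default 0.15) are game species.
* **Surveys** (`simulate_surveys`): occupancy drawn once per
  segment × species, then independent per-visit detection; only presence
  rows are emitted, which is precisely the historical-data pathology the
  framework addresses.
* **Rarity** (`classify_rarity`): the three classical dimensions —
  range size (occupied fraction), habitat breadth (mean curve width in
  sd units), local population (proxied by detection) — each dichotomized
  at its median, giving eight classes A–H with A common on all axes.

What the generator deliberately does **not** emulate: stream network
topology (segments are points, not reaches with up/downstream structure),
temporal trends in occupancy across survey years, observer-specific
detection differences, and dispersal limitation beyond what the spatial
covariance induces. These omissions keep every mechanism in the
experiments attributable.

## Experiments and why their settings look the way they do

* **Prevalence bootstrap** (`prevalence_experiment`): resamples to total
  size 100 at prevalences 0.1–0.9 with 100 bootstrap replicates, exact
  class counts drawn without replacement, plain logistic fits, 10-fold
  cross-validation. The U-shaped *training* AUC at extreme prevalence is
  an overfitting artifact — with few minority-class rows the model can
  rank them almost perfectly in-sample — and it vanishes under
  cross-validation. The study condition here is one weak-moderate driver
  (logistic slope 0.7 per sd) with all ten habitat variables offered, so
  the overfitting margin is visible but not saturated.
* **Background comparison** (`background_comparison_experiment`): survey
  effort is uneven — only 60% of segments are ever visited
  (`sampled_fraction = 0.6`). Random background points therefore land on
  unsampled-but-occupied segments (false negatives), while inferred
  absences are confined to community-evidenced segments. This is the
  mechanism that makes presence-absence modeling on inferred absences
  validate better; with complete survey coverage the two designs
  coincide and the comparison is uninformative.
* **Spatial filtering** (`spatial_filtering_experiment`): the species
  responds to a smooth field observed with 60% noise; the non-spatial
  fit leaves the smooth signal in its residuals (significant Moran's I),
  the spatialized refit recovers it.
* **Calibration** (`moran_type1_calibration`,
  `ancova_null_calibration`): type-I error of the permutation test at
  nominal 0.05, and mean treatment F ≈ 1 for the blocked ANCOVA under a
  null response.
* **Recovery** (`brt_threshold_experiment`,
  `influence_recovery_experiment`): planted occupancy thresholds must be
  found by partial dependence within one grid step; planted drivers must
  rank first in relative influence.

## The factorial comparison

`run_framework` fits every species × basin × model kind × spatial flag ×
resolution combination and feeds the long results table to a blocked
ANCOVA on Box-Cox-transformed cross-validated AUC, with sequential
(Type I) sums of squares in the order: model type, spatial flag, rarity
type, resolution, then the blocking factors basin and species, with
family number as a covariate. Only models of the same species × basin
dataset are directly comparable, which is what the blocks encode. Tukey
HSD contrasts follow for the model-type factor. Because family is
constant within species, the family covariate is aliased once species
blocks enter — the fit drops it with a warning rather than silently
re-attributing its variance.

## Numerical choices

* All seeds derive from one master seed via a Lehmer-style split
  (`child_seed`), keeping every stage's stream independent and every
  result below-`2^31` reproducible.
* Problem sizes in the analysis scripts (300 segments, 30 species, 25
  replicates per experiment) are the package's own defaults, chosen so
  the full workflow stays desk-scale while every rate estimate has
  enough replicates to be stable.
* The eigendecomposition in `pcnm` is a full symmetric solve;
  degenerate eigenvalues (|λ| below 1e-10 of the spectral radius) are
  excluded from Moran testing.
* glmnet occasionally reports non-convergence at the smallest penalties
  of a cross-validation path; those path tails do not affect the
  selected penalty.

## Limitations

Inferred absences remain imperfect: a community-sampled segment can hold
an undetected focal species, so label 0 carries detection error that the
models absorb as noise. The presence-background surrogate is a penalized
logistic approximation, not a maximum-entropy implementation; its role
is the negative-class comparison, not feature-class fidelity. And the
rarity classification uses detection probability as a stand-in for local
population size — adequate for the generator, where the two are linked
by construction, but not a field method.
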