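# commSDM

High-resolution species distribution models (SDMs) from historical,
presence-only community survey data.

## The problem

Decades of museum records and agency fish surveys tell us where species
*were found* — never where they were absent. A segment with no record of
a species is ambiguous: truly unsuitable, or simply never sampled?
Feeding unsampled segments to a presence–absence model as zeros poisons
it with false negatives; discarding absences entirely forces a
presence-only design against an uninformative background.

`commSDM` implements a community-based resolution. Historical fish
surveys are community surveys: a sampled segment yields records of every
species caught. So a segment where *other* (non-game) species were
recorded but the focal species never was, is evidenced as sampled, and
the focal species' absence there is informative. For focal species $f$
over the incidence matrix $Y$ (segments × species):

$$\text{label}(s)=\begin{cases}1 & Y_{sf}=1\\[2pt] 0 & Y_{sf}=0\ \wedge\ \sum_{k\neq f,\,k\notin G} Y_{sk}\ge m\\[2pt] \text{unlabeled} & \text{otherwise}\end{cases}$$

with $G$ the game species (stocked presences are excluded from the
evidence) and $m$ the minimum community evidence (default 1). On these
labeled data the package fits and compares three model families under
one prediction contract — Lasso-penalized logistic regression, boosted
regression trees, and a presence-background surrogate — with optional
"spatialization" of predictors on PCNM spatial eigenvectors
(Moran-eigenvector filters), evaluation by stratified k-fold
cross-validated AUC, and a blocked Box-Cox ANCOVA + Tukey HSD factorial
comparison across model kind, spatial treatment, rarity type, and
spatial resolution.

Because the original occurrence and environmental data cannot ship with
the package, every methodological claim is exercised on a transparent
synthetic metacommunity generator (`generate_landscape`,
`generate_species`, `simulate_surveys`) whose defaults are the study
conditions. See the vignette (`vignettes/community-sdm-methods.Rmd`) for
the model in full notation and the design rationale.

## Worked example

Simulate a metacommunity, accumulate presence-only survey records, infer
absences for one focal species from community evidence, and fit a
cross-validated Lasso SDM:

```r
library(commSDM)

landscape <- generate_landscape(n_segments = 200, n_basins = 2,
                                n_units = 8, seed = 1)
species   <- generate_species(landscape, n_species = 15, seed = 2)
records   <- simulate_surveys(landscape, species,
                              survey_design(3L, seed = 3))
summarize_records(records)[c("n_records", "n_segments", "n_species")]
#> $n_records
#> [1] 1734
#> $n_segments
#> [1] 197
#> $n_species
#> [1] 15

meta <- build_incidence(records, species_metadata(species))
meta
#> Metacommunity incidence: 197 segments x 15 species; 795 presences

ds <- build_species_dataset(meta, landscape$habitat, focal = "sp_003")
table(ds$y)            # presences and community-inferred absences
#>   0   1
#>  78 119

fit <- fit_lasso_logistic(ds$X, ds$y, seed = 4)
round(fit$beta[fit$beta != 0], 4)
#> (Intercept)         ele  dist_score
#>      5.1870     -0.0139     -0.0104

kfold_cv(function(X, y) fit_lasso_logistic(X, y, seed = 4),
         ds$X, ds$y, k = 5, seed = 4)
#> AUC: train 0.893, 5-fold cv 0.884 (folds: 0.906 0.799 0.846 0.925 0.945)
```

The selected model uses two habitat variables (elevation and a
disturbance score) and validates at cv AUC 0.88.

## The analysis workflow

The `analysis/` directory holds the numbered drivers of the full study,
each a thin script around package functions, writing tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate_data.R` | simulate the landscape, species pool, and survey records |
| `02_fit_models.R` | full factorial framework run + ANCOVA + Tukey contrasts |
| `03_background_comparison.R` | inferred absences vs random background, paired by species |
| `04_prevalence.R` | prevalence bootstrap: U-shaped training AUC vs flat cv AUC |
| `05_spatial_diagnostics.R` | residual Moran's I before/after spatialization; test calibration |
| `06_thresholds.R` | boosted-tree threshold and driver recovery |

Run them in order from the package root, e.g.
`Rscript analysis/01_simulate_data.R`.

## Repository layout

```
R/                 all computation (generator, inference, models, spatial
                   filters, evaluation, experiments, pipeline)
analysis/          numbered workflow drivers (thin, write to results/)
scripts/           acceptance.R (JSON summary of headline quantities)
tests/testthat/    unit, property, oracle, and acceptance tests
vignettes/         methods vignette (model, assumptions, design rationale)
```
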