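#!/usr/bin/env Rscript

# Step 4: prevalence bootstrap — resample a labeled dataset to fixed total
# size across a prevalence grid and contrast training AUC (U-shaped from
# overfitting at extreme class imbalance) with cross-validated AUC (flat).
#
# Writes: results/prevalence.csv

library(commSDM)

seed <- 20L
dir.create("results", showWarnings = FALSE)

landscape <- generate_landscape(400, 1, 1, spatial_range = 25,
                                seed = child_seed(seed, 1))
x <- landscape$habitat[, "tmp"]
sp <- generate_species(landscape, niche_spec = list(list(
  curves = list(tmp = list(type = "logistic", midpoint = median(x),
                           slope = 0.7 / sd(x))),
  baseline_logit = 0
)), seed = child_seed(seed, 2))[[1]]
set.seed(child_seed(seed, 3))
y <- rbinom(400, 1, sp$true_occupancy)

ex <- prevalence_experiment(list(X = landscape$habitat, y = y),
                            n_total = 100, n_boot = 100, cv_k = 10,
                            seed = seed)
write.csv(ex$cells, "results/prevalence.csv", row.names = FALSE)
print(ex)
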