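#!/usr/bin/env Rscript

# Step 1: simulate the study system — a stream-segment landscape with
# spatially autocorrelated habitat, a pool of virtual species with known
# niches, and accumulated presence-only survey records.
#
# Writes: results/occurrences.csv, results/habitat.csv,
#         results/segments.csv, results/species.csv, results/rarity.csv

library(commSDM)

seed <- 1L
dir.create("results", showWarnings = FALSE)

landscape <- generate_landscape(n_segments = 300, n_basins = 4,
                                n_units = 60, spatial_range = 25,
                                seed = child_seed(seed, 1))
species <- generate_species(landscape, n_species = 30,
                            seed = child_seed(seed, 2))
records <- simulate_surveys(landscape, species,
                            survey_design(3L, seed = child_seed(seed, 3)))

write_occurrences(records, "results/occurrences.csv")
write.csv(cbind(segment_id = rownames(landscape$habitat),
                as.data.frame(landscape$habitat)),
          "results/habitat.csv", row.names = FALSE)
write.csv(landscape$segments, "results/segments.csv", row.names = FALSE)
write.csv(species_metadata(species), "results/species.csv", row.names = FALSE)
write.csv(classify_rarity(species, landscape), "results/rarity.csv",
          row.names = FALSE)

s <- summarize_records(records, species_metadata(species))
cat(sprintf("simulated %d records over %d segments, %d species, %d families\n",
            s$n_records, s$n_segments, s$n_species, s$n_families))
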