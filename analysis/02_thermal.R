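#!/usr/bin/env Rscript
# Stage 2 — thermal analysis of the cooling traces.
#
# Detects the latent-heat exotherm in every leaf trace and summarises the
# ice nucleation temperature (NT) and freezing point (FP) per species as
# mean +/- SE over detected leaves.

library(frostfd)

traces <- read_frost_table("results/data/traces.csv",
                           c("species_id", "leaf_id", "time_s", "temp_C"))
leaf <- detect_exotherms(traces)
species <- summarize_species_thermal(leaf)

write_frost_table(leaf, "results/leaf_nt_fp.csv")
write_frost_table(species, "results/species_thermal.csv")

cat("Detected exotherms in", sum(leaf$detected), "of", nrow(leaf),
    "leaves across", nrow(species), "species.\n")
cat(sprintf("NT range: %.1f to %.1f degC; FP range: %.1f to %.1f degC\n",
            min(species$nt_mean_C), max(species$nt_mean_C),
            min(species$fp_mean_C), max(species$fp_mean_C)))
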