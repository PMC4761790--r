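#!/usr/bin/env Rscript
# Stage 3 — freezing damage (LT50) from chlorophyll fluorescence.
#
# Converts Fv/Fm readings to photoinactivation (PhI = 1 - FvFm/Fmax) and
# estimates each species' LT50 by bracketed linear interpolation of mean PhI
# across the -5/-10/-15/-19 degC treatments.

library(frostfd)

assays <- read_frost_table("results/data/damage_assays.csv",
                           c("species_id", "leaf_id", "treatment", "fv_fm"))
lt50 <- lt50_table(assays)

write_frost_table(lt50, "results/species_lt50.csv")
write_frost_table(attr(lt50, "phi_table"), "results/phi_by_temperature.csv")

cat("Estimated LT50 for", sum(lt50$censored == "none"), "of", nrow(lt50),
    "species (", sum(lt50$censored == "below_range"),
    "censored below -19 degC,", sum(lt50$censored == "above_range"),
    "above -5 degC).\n")
cat(sprintf("LT50 range: %.1f to %.1f degC; mean %.1f degC\n",
            min(lt50$lt50_C, na.rm = TRUE), max(lt50$lt50_C, na.rm = TRUE),
            mean(lt50$lt50_C, na.rm = TRUE)))
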