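#!/usr/bin/env Rscript
# Stage 4 — freezing-resistance mechanisms.
#
# Compares each species' NT replicates against its LT50: freezing tolerant
# (FT) when LT50 is significantly colder than NT, avoidant (FA) when the two
# coincide, sensitive (FS) when damage occurs before nucleation. Then counts
# per-plot FT/FA/FS fractions over the cover matrix.

library(frostfd)

leaf <- read_frost_table("results/leaf_nt_fp.csv")
lt50 <- read_frost_table("results/species_lt50.csv")
community <- read_frost_table("results/data/community.csv")

mech <- classify_species(leaf, lt50)
props <- mechanism_proportions(community, mech)

write_frost_table(mech, "results/species_mechanism.csv")
write_frost_table(props, "results/mechanism_proportions.csv")

tab <- table(factor(mech$mechanism, c("FT", "FA", "FS")))
cat(sprintf("Mechanisms: %d FT (%.1f%%), %d FA (%.1f%%), %d FS (%.1f%%)\n",
            tab["FT"], 100 * tab["FT"] / sum(tab),
            tab["FA"], 100 * tab["FA"] / sum(tab),
            tab["FS"], 100 * tab["FS"] / sum(tab)))
ft_trend <- linear_trend(props$prop_FT, props$altitude_m)
cat(sprintf("FT fraction vs altitude: slope %.2e per m (R2 %.2f, p %.3g)\n",
            ft_trend$slope, ft_trend$r_squared, ft_trend$p_value))
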