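#!/usr/bin/env Rscript
# Stage 6 — trend and contrast statistics.
#
# Linear models of each functional component (CWM, Rao FD) and of the FT/FA
# fractions against altitude; Kruskal-Wallis with Nemenyi post hoc of FP and
# LT50 across growth forms; Spearman correlations of the freezing traits
# with Hmax, SLA, LDMC and seed mass. Writes a JSON analysis report.

library(frostfd)

components <- read_frost_table("results/functional_components.csv")
props <- read_frost_table("results/mechanism_proportions.csv")
thermal <- read_frost_table("results/species_thermal.csv")
lt50 <- read_frost_table("results/species_lt50.csv")
traits <- read_frost_table("results/data/trait_table.csv")

profile <- Reduce(function(a, b) merge(a, b, by = "species_id"),
                  list(thermal[, c("species_id", "fp_mean_C")],
                       lt50[, c("species_id", "lt50_C")],
                       traits[, c("species_id", "growth_form", "hmax_m",
                                  "sla_mm2_mg", "ldmc_mg_g", "seed_mass_mg")]))

trends <- list()
for (tc in unique(components$trait)) {
  sub <- components[components$trait == tc, ]
  trends[[paste0("cwm_", sub("_C$", "", tc))]] <-
    linear_trend(sub$cwm, sub$altitude_m)
  trends[[paste0("fd_", sub("_C$", "", tc))]] <-
    linear_trend(sub$fd_rao, sub$altitude_m)
}
trends$prop_ft <- linear_trend(props$prop_FT, props$altitude_m)
trends$prop_fa <- linear_trend(props$prop_FA, props$altitude_m)

contrasts <- list(
  fp = kruskal_nemenyi(profile$fp_mean_C, profile$growth_form),
  lt50 = kruskal_nemenyi(profile$lt50_C, profile$growth_form))

correlations <- list(
  fp_lt50 = trait_correlation(profile$fp_mean_C, profile$lt50_C, "spearman"))
for (tr in c("hmax_m", "sla_mm2_mg", "ldmc_mg_g", "seed_mass_mg")) {
  correlations[[paste0(tr, "_fp")]] <-
    trait_correlation(profile[[tr]], profile$fp_mean_C, "spearman")
  correlations[[paste0(tr, "_lt50")]] <-
    trait_correlation(profile[[tr]], profile$lt50_C, "spearman")
}

report <- list(trends = lapply(trends, unclass),
               growth_form_contrasts = lapply(contrasts, function(gc)
                 list(kw_statistic = gc$kw_statistic, kw_df = gc$kw_df,
                      kw_p = gc$kw_p, letters = as.list(gc$letters))),
               correlations = correlations)
jsonlite::write_json(report, "results/analysis_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

for (n in names(trends))
  cat(sprintf("%-10s slope %+.3e per m  R2 %.2f  p %.3g\n", n,
              trends[[n]]$slope, trends[[n]]$r_squared, trends[[n]]$p_value))
cat("LT50 by growth form:",
    paste(names(contrasts$lt50$letters), contrasts$lt50$letters,
          collapse = ", "),
    sprintf(" (KW chi2 %.1f, p %.3g)\n", contrasts$lt50$kw_statistic,
            contrasts$lt50$kw_p))
cat(sprintf("LDMC vs LT50: Spearman rho %.2f (p %.3g)\n",
            correlations$ldmc_mg_g_lt50$estimate,
            correlations$ldmc_mg_g_lt50$p_value))
cat("Report written to results/analysis_report.json\n")
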