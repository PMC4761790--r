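#' Run the full freezing-resistance analysis pipeline
#'
#' Executes every stage in order: exotherm detection on the thermograms
#' (NT/FP per leaf, then per species), LT50 estimation from the fluorescence
#' assays, mechanism classification (FT/FA/FS) and per-plot mechanism
#' proportions, community functional components (CWM and Rao FD of FP and
#' LT50, engineer species excluded), and the trend statistics: linear models
#' of each functional component and of the FT/FA proportions against
#' altitude, Kruskal-Wallis with Nemenyi post hoc of FP and LT50 across
#' growth forms, and correlations of the freezing traits with Hmax, SLA,
#' LDMC and seed mass. The same inputs always produce the same report.
#'
#' @param traces Long thermogram table (`species_id`, `leaf_id`, `time_s`,
#'   `temp_C`) or a CSV path.
#' @param assays Fluorescence assay table (`species_id`, `leaf_id`,
#'   `treatment`, `fv_fm`) or a CSV path.
#' @param traits Species table with `species_id`, `growth_form` and the
#'   functional trait columns `hmax_m`, `sla_mm2_mg`, `ldmc_mg_g`,
#'   `seed_mass_mg` (extra columns ignored), or a CSV path.
#' @param community Wide cover matrix (`plot_id`, `altitude_m`, species
#'   columns) or a CSV path.
#' @param alpha Significance level for classification and letter displays.
#' @param exclude Engineer species column excluded from the functional
#'   components (NULL to keep all species).
#' @param config [exotherm_config()] for the detection stage.
#' @param out_dir Optional directory: per-stage CSV tables and a JSON report
#'   are written there.
#' @return List of class `frost_report` with elements `leaf_results`,
#'   `species_thermal`, `lt50`, `profiles`, `mechanism_props`, `components`,
#'   `trends`, `growth_form_contrasts`, `correlations`, `settings`.
#' @export
run_frost_pipeline <- function(traces, assays, traits, community,
                               alpha = 0.05,
                               exclude = "Festuca_curvifolia",
                               config = exotherm_config(),
                               out_dir = NULL) {
  if (is.character(traces))
    traces <- read_frost_table(traces, c("species_id", "leaf_id", "time_s",
                                         "temp_C"))
  if (is.character(assays))
    assays <- read_frost_table(assays, c("species_id", "leaf_id", "treatment",
                                         "fv_fm"))
  if (is.character(traits))
    traits <- read_frost_table(traits, c("species_id", "growth_form"))
  if (is.character(community))
    community <- read_frost_table(community, c("plot_id", "altitude_m"))

  # stage 1: thermal analysis
  leaf_results <- detect_exotherms(traces, config)
  species_thermal <- suppressWarnings(summarize_species_thermal(leaf_results))

  # stage 2: freezing damage
  lt50 <- lt50_table(assays)

  # stage 3: mechanism classification and per-plot proportions
  mech <- classify_species(leaf_results, lt50, alpha)
  profiles <- merge(species_thermal, lt50, by = "species_id", all = TRUE)
  profiles <- merge(profiles, mech, by = "species_id", all.x = TRUE)
  profiles <- merge(profiles,
                    traits[, intersect(names(traits),
                                       c("species_id", "growth_form",
                                         "hmax_m", "sla_mm2_mg", "ldmc_mg_g",
                                         "seed_mass_mg")), drop = FALSE],
                    by = "species_id", all.x = TRUE)
  mech_props <- suppressWarnings(mechanism_proportions(community, mech))

  # stage 4: community functional components on estimated FP and LT50
  trait_vals <- data.frame(species_id = profiles$species_id,
                           fp_C = profiles$fp_mean_C,
                           lt50_C = profiles$lt50_C,
                           stringsAsFactors = FALSE)
  components <- suppressWarnings(
    functional_components(community, trait_vals,
                          trait_cols = c("fp_C", "lt50_C"),
                          exclude = exclude))

  # stage 5: trend and contrast statistics
  trends <- list()
  for (tc in unique(components$trait)) {
    sub <- components[components$trait == tc, ]
    trends[[paste0("cwm_", sub("_C$", "", tc))]] <-
      linear_trend(sub$cwm, sub$altitude_m)
    trends[[paste0("fd_", sub("_C$", "", tc))]] <-
      linear_trend(sub$fd_rao, sub$altitude_m)
  }
  trends$prop_ft <- linear_trend(mech_props$prop_FT, mech_props$altitude_m)
  trends$prop_fa <- linear_trend(mech_props$prop_FA, mech_props$altitude_m)

  contrasts <- list()
  if ("growth_form" %in% names(profiles)) {
    contrasts$fp <- suppressWarnings(
      kruskal_nemenyi(profiles$fp_mean_C, profiles$growth_form, alpha))
    contrasts$lt50 <- suppressWarnings(
      kruskal_nemenyi(profiles$lt50_C, profiles$growth_form, alpha))
  }

  correlations <- list(
    fp_lt50 = trait_correlation(profiles$fp_mean_C, profiles$lt50_C,
                                "spearman"))
  for (tr in c("hmax_m", "sla_mm2_mg", "ldmc_mg_g", "seed_mass_mg")) {
    if (!tr %in% names(profiles)) next
    correlations[[paste0(tr, "_fp")]] <-
      trait_correlation(profiles[[tr]], profiles$fp_mean_C, "spearman")
    correlations[[paste0(tr, "_lt50")]] <-
      trait_correlation(profiles[[tr]], profiles$lt50_C, "spearman")
  }

  report <- structure(list(
    leaf_results = leaf_results,
    species_thermal = species_thermal,
    lt50 = lt50,
    profiles = profiles,
    mechanism_props = mech_props,
    components = components,
    trends = trends,
    growth_form_contrasts = contrasts,
    correlations = correlations,
    settings = list(alpha = alpha, exclude = exclude,
                    exotherm = unclass(config))),
    class = "frost_report")

  if (!is.null(out_dir)) write_frost_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Per-stage CSV tables plus `report.json` with the trend, contrast and
#' correlation results and the settings echo.
#'
#' @param report A `frost_report` from [run_frost_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frost_report <- function(report, dir) {
  stopifnot(inherits(report, "frost_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_frost_table(report$leaf_results, file.path(dir, "leaf_nt_fp.csv"))
  write_frost_table(report$species_thermal,
                    file.path(dir, "species_thermal.csv"))
  write_frost_table(report$lt50, file.path(dir, "species_lt50.csv"))
  write_frost_table(report$profiles, file.path(dir, "species_profiles.csv"))
  write_frost_table(report$mechanism_props,
                    file.path(dir, "mechanism_proportions.csv"))
  write_frost_table(report$components,
                    file.path(dir, "functional_components.csv"))
  json <- list(
    trends = lapply(report$trends, unclass),
    growth_form_contrasts = lapply(report$growth_form_contrasts, function(gc)
      list(kw_statistic = gc$kw_statistic, kw_df = gc$kw_df, kw_p = gc$kw_p,
           letters = as.list(gc$letters))),
    correlations = report$correlations,
    settings = report$settings)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
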