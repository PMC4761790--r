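#' Scenario parameters for the synthetic study
#'
#' One object holding every parameter of the synthetic data generator. The
#' defaults emulate the study design the pipeline targets: 42 species in four
#' growth forms (8 cushions, 8 graminoids, 23 forbs, 3 shrubs), 38 plots
#' spanning 1940-2428 m, a 2 degC/h cooling ramp from 0 to -19 degC sampled
#' at 1 Hz, freezing-damage assays at -5/-10/-15/-19 degC plus a 4 degC
#' control with 5 replicate leaves, a negative LDMC-LT50 rank correlation of
#' -0.55, and an engineer grass present in every plot at high cover.
#'
#' Growth-form LT50 archetypes place graminoids as the hardiest group
#' (mean -13.5 degC) with cushions, forbs and shrubs 4.3, 6.3 and 7.2 K
#' warmer respectively; species truths are clamped to the observed span
#' [-18.5, -5.1] degC. Mechanism archetypes are assigned by LT50 rank: the
#' 20 coldest species are freezing tolerant (NT about 4.5 K above LT50), the
#' next 18 avoidant (NT at LT50) and the 4 warmest sensitive (NT about 2 K
#' below LT50), i.e. 47.6/42.9/9.5 percent of the pool.
#'
#' @param n_species,n_plots Pool and plot counts.
#' @param altitude_range_m Altitude span of the plots (m a.s.l.).
#' @param growth_form_counts Named integer vector over
#'   cushion/graminoid/forb/shrub; must sum to `n_species`.
#' @param lt50_form_means_C Named archetype means per growth form (degC).
#' @param lt50_sd_K Between-species SD around the archetype mean.
#' @param lt50_limits_C Species truths clamped to this span.
#' @param mech_counts Named vector FT/FA/FS assigned by LT50 rank.
#' @param ft_gap_K,fa_gap_sd_K,fs_gap_K NT placement relative to LT50 for
#'   each mechanism archetype (mean gap for FT and FS, SD for FA).
#' @param fp_offset_K Mean FP elevation above NT; FP capped at `fp_max_C`.
#' @param fp_max_C Warmest allowed freezing point.
#' @param replicates Leaves per species for both thermal and damage assays.
#' @param nt_rep_sd_K,fp_rep_sd_K Between-leaf replicate SDs.
#' @param cooling_rate_C_per_h,ramp_start_C,ramp_end_C,sampling_hz Cooling
#'   program of the thermal assay.
#' @param rise_time_s,decay_tau_s Exotherm shape: linear rise to FP over
#'   `rise_time_s`, then exponential relaxation back to the ramp.
#' @param trace_noise_sd_K Gaussian sensor noise on the trace.
#' @param target_temps_C Damage-assay target temperatures (degC).
#' @param damage_slope_k Logistic damage steepness (1/K).
#' @param f_max_true Healthy Fv/Fm level.
#' @param fv_fm_noise_sd Gaussian noise on Fv/Fm readings.
#' @param ldmc_lt50_rho Target Spearman correlation between LDMC and LT50.
#' @param engineer_species,engineer_cover_pct Ubiquitous engineer species
#'   and its mean cover.
#' @param niche_coupling Strength in [0, 1] of the LT50-to-optimum coupling:
#'   1 places optima by LT50 rank (hardier species peak higher), 0 places
#'   them uniformly at random.
#' @param niche_opt_noise_m SD of species' altitudinal optimum around its
#'   LT50-determined position.
#' @param niche_width_base_m,niche_width_slope Gaussian niche width at the
#'   bottom of the gradient and its increase per metre of plot altitude
#'   (communities higher up admit a broader slice of the trait pool).
#' @param cover_cmax_meanlog,cover_cmax_sdlog Lognormal peak covers.
#' @param cover_noise_sdlog Multiplicative lognormal noise on realised
#'   covers (field cover estimation error).
#' @param cover_threshold Covers below this are treated as absence.
#' @return List of class `frost_scenario`.
#' @export
frost_scenario <- function(n_species = 42L,
                           n_plots = 38L,
                           altitude_range_m = c(1940, 2428),
                           growth_form_counts = c(cushion = 8L, graminoid = 8L,
                                                  forb = 23L, shrub = 3L),
                           lt50_form_means_C = c(cushion = -9.2,
                                                 graminoid = -13.5,
                                                 forb = -7.2, shrub = -6.3),
                           lt50_sd_K = 2.0,
                           lt50_limits_C = c(-18.5, -5.1),
                           mech_counts = c(FT = 20L, FA = 18L, FS = 4L),
                           ft_gap_K = 4.5,
                           fa_gap_sd_K = 0.3,
                           fs_gap_K = 2.0,
                           fp_offset_K = 3.2,
                           fp_max_C = -0.6,
                           replicates = 5L,
                           nt_rep_sd_K = 1.1,
                           fp_rep_sd_K = 0.7,
                           cooling_rate_C_per_h = 2,
                           ramp_start_C = 0,
                           ramp_end_C = -19,
                           sampling_hz = 1,
                           rise_time_s = 30,
                           decay_tau_s = 120,
                           trace_noise_sd_K = 0.05,
                           target_temps_C = c(-5, -10, -15, -19),
                           damage_slope_k = 1.5,
                           f_max_true = 0.8,
                           fv_fm_noise_sd = 0.03,
                           ldmc_lt50_rho = -0.55,
                           engineer_species = "Festuca_curvifolia",
                           engineer_cover_pct = 55,
                           niche_coupling = 1,
                           niche_opt_noise_m = 60,
                           niche_width_base_m = 100,
                           niche_width_slope = 0.3,
                           cover_cmax_meanlog = log(10),
                           cover_cmax_sdlog = 0.5,
                           cover_noise_sdlog = 0.4,
                           cover_threshold = 0.5) {
  sc <- as.list(environment())
  if (sum(sc$growth_form_counts) != sc$n_species)
    stop("growth_form_counts must sum to n_species", call. = FALSE)
  if (sum(sc$mech_counts) != sc$n_species)
    stop("mech_counts must sum to n_species", call. = FALSE)
  stopifnot(sc$cooling_rate_C_per_h > 0, sc$damage_slope_k > 0,
            sc$replicates >= 1, sc$trace_noise_sd_K >= 0,
            sc$fv_fm_noise_sd >= 0)
  structure(sc, class = "frost_scenario")
}

#' Simulate one leaf cooling thermogram
#'
#' A 1 Hz trace following the scenario's linear cooling ramp plus Gaussian
#' sensor noise. When the ramp reaches `nt_true` the latent-heat exotherm is
#' injected: a linear rise to `fp_true` over `rise_time_s`, then exponential
#' relaxation (time constant `decay_tau_s`) back toward the ramp. An
#' `nt_true` at or below the ramp end yields a censored trace with no
#' exotherm — a valid outcome, not an error.
#'
#' @param nt_true,fp_true Injected nucleation temperature and freezing point
#'   (degC), `fp_true > nt_true`.
#' @param scenario A [frost_scenario()].
#' @param seed Integer seed; the trace is byte-identical for a given
#'   (scenario, seed).
#' @return Data frame `time_s`, `temp_C`.
#' @export
simulate_thermogram <- function(nt_true, fp_true,
                                scenario = frost_scenario(), seed = 1L) {
  stopifnot(inherits(scenario, "frost_scenario"))
  has_exo <- is.finite(nt_true) && nt_true > scenario$ramp_end_C
  if (has_exo && !(fp_true > nt_true))
    stop("fp_true must exceed nt_true", call. = FALSE)
  set.seed(seed)
  rate <- scenario$cooling_rate_C_per_h / 3600   # K per second
  dur <- (scenario$ramp_start_C - scenario$ramp_end_C) / rate
  time_s <- seq(0, dur, by = 1 / scenario$sampling_hz)
  base <- scenario$ramp_start_C - rate * time_s
  temp <- base
  if (has_exo) {
    t0 <- (scenario$ramp_start_C - nt_true) / rate
    rise <- time_s > t0 & time_s <= t0 + scenario$rise_time_s
    temp[rise] <- nt_true +
      (fp_true - nt_true) * (time_s[rise] - t0) / scenario$rise_time_s
    t_peak <- t0 + scenario$rise_time_s
    post <- time_s > t_peak
    amp <- fp_true - (scenario$ramp_start_C - rate * t_peak)
    temp[post] <- base[post] +
      amp * exp(-(time_s[post] - t_peak) / scenario$decay_tau_s)
  }
  if (scenario$trace_noise_sd_K > 0)
    temp <- temp + stats::rnorm(length(temp), 0, scenario$trace_noise_sd_K)
  data.frame(time_s = time_s, temp_C = temp)
}

#' Simulate thermograms for every leaf of a species table
#'
#' Draws per-leaf NT/FP replicates around each species' truths and renders
#' one trace per leaf.
#'
#' @param trait_table From [simulate_trait_table()].
#' @param scenario A [frost_scenario()].
#' @param seed Integer seed.
#' @return Long data frame `species_id`, `leaf_id`, `time_s`, `temp_C`.
#' @export
simulate_thermograms <- function(trait_table, scenario = frost_scenario(),
                                 seed = 1L) {
  require_columns(trait_table, c("species_id", "nt_true_C", "fp_true_C"),
                  "trait_table")
  set.seed(seed)
  temps <- list(); sp_ids <- character(0); leaf_ids <- character(0)
  m <- NULL
  for (i in seq_len(nrow(trait_table))) {
    for (r in seq_len(scenario$replicates)) {
      nt_i <- trait_table$nt_true_C[i] + stats::rnorm(1, 0, scenario$nt_rep_sd_K)
      nt_i <- min(nt_i, scenario$fp_max_C - 0.5)
      fp_i <- trait_table$fp_true_C[i] + stats::rnorm(1, 0, scenario$fp_rep_sd_K)
      fp_i <- min(scenario$fp_max_C, max(fp_i, nt_i + 0.5))
      tr <- simulate_thermogram(nt_i, fp_i, scenario,
                                seed = sample.int(.Machine$integer.max, 1))
      if (is.null(m)) { m <- nrow(tr); time_s <- tr$time_s }
      temps[[length(temps) + 1L]] <- tr$temp_C
      sp_ids <- c(sp_ids, trait_table$species_id[i])
      leaf_ids <- c(leaf_ids, paste0(trait_table$species_id[i], "_L", r))
    }
  }
  data.frame(species_id = rep(sp_ids, each = m),
             leaf_id = rep(leaf_ids, each = m),
             time_s = rep(time_s, length(temps)),
             temp_C = unlist(temps), stringsAsFactors = FALSE)
}

#' Simulate a chlorophyll-fluorescence damage assay for one species
#'
#' True damage is logistic in temperature,
#' PhI(T) = 1 / (1 + exp(k (T - LT50_true))), so PhI = 0.5 exactly at the
#' true midpoint. Fv/Fm readings are f_max (1 - PhI) plus Gaussian noise,
#' clamped to [0, 1], with `replicates` leaves per target temperature plus
#' controls kept at 4 degC.
#'
#' @param lt50_true True damage midpoint (degC).
#' @param scenario A [frost_scenario()] (slope `damage_slope_k`, noise
#'   `fv_fm_noise_sd`, targets `target_temps_C`).
#' @param seed Integer seed.
#' @param species_id Identifier for the output records.
#' @return Data frame `species_id`, `leaf_id`, `treatment`, `fv_fm`.
#' @export
simulate_damage_assay <- function(lt50_true, scenario = frost_scenario(),
                                  seed = 1L, species_id = "sp") {
  stopifnot(inherits(scenario, "frost_scenario"))
  set.seed(seed)
  k <- scenario$damage_slope_k
  f_max <- scenario$f_max_true
  rows <- list()
  add <- function(treatment, fv, tag) {
    data.frame(species_id = species_id,
               leaf_id = paste0(species_id, "_", tag, seq_along(fv)),
               treatment = treatment, fv_fm = fv, stringsAsFactors = FALSE)
  }
  fv_ctrl <- f_max + stats::rnorm(scenario$replicates, 0,
                                  scenario$fv_fm_noise_sd)
  rows[[1]] <- add("control", pmin(1, pmax(0, fv_ctrl)), "C")
  for (tt in scenario$target_temps_C) {
    phi <- 1 / (1 + exp(k * (tt - lt50_true)))
    fv <- f_max * (1 - phi) + stats::rnorm(scenario$replicates, 0,
                                           scenario$fv_fm_noise_sd)
    rows[[length(rows) + 1L]] <- add(as.character(tt), pmin(1, pmax(0, fv)),
                                     paste0("T", abs(tt), "_"))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Simulate damage assays for every species of a trait table
#' @inheritParams simulate_thermograms
#' @return Long data frame `species_id`, `leaf_id`, `treatment`, `fv_fm`.
#' @export
simulate_damage_assays <- function(trait_table, scenario = frost_scenario(),
                                   seed = 1L) {
  require_columns(trait_table, c("species_id", "lt50_true_C"), "trait_table")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nrow(trait_table))
  out <- lapply(seq_len(nrow(trait_table)), function(i)
    simulate_damage_assay(trait_table$lt50_true_C[i], scenario, seeds[i],
                          species_id = trait_table$species_id[i]))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Simulate the species trait and freezing-truth table
#'
#' Draws per-species LT50 truths around growth-form archetypes, assigns
#' mechanism archetypes by LT50 rank (coldest species tolerant), places NT
#' and FP accordingly, and generates the four functional traits. LDMC is
#' coupled to LT50 through a Gaussian copula so their Spearman correlation
#' targets `ldmc_lt50_rho` (the copula parameter uses the standard
#' 2 sin(pi rho / 6) conversion).
#'
#' @param scenario A [frost_scenario()].
#' @param seed Integer seed.
#' @return Data frame with `species_id`, `growth_form`, `nt_true_C`,
#'   `fp_true_C`, `lt50_true_C`, `mechanism_true`, `hmax_m`, `sla_mm2_mg`,
#'   `ldmc_mg_g`, `seed_mass_mg`.
#' @export
simulate_trait_table <- function(scenario = frost_scenario(), seed = 1L) {
  stopifnot(inherits(scenario, "frost_scenario"))
  set.seed(seed)
  n <- scenario$n_species
  gf <- rep(names(scenario$growth_form_counts), scenario$growth_form_counts)
  species_id <- sprintf("sp%02d", seq_len(n))

  lt50 <- scenario$lt50_form_means_C[gf] +
    stats::rnorm(n, 0, scenario$lt50_sd_K)
  lt50 <- pmin(max(scenario$lt50_limits_C),
               pmax(min(scenario$lt50_limits_C), lt50))

  mech <- rep(NA_character_, n)
  ord <- order(lt50)                       # coldest first
  idx <- cumsum(c(0, scenario$mech_counts))
  mech[ord[seq_len(scenario$mech_counts["FT"])]] <- "FT"
  mech[ord[(idx[2] + 1):idx[3]]] <- "FA"
  mech[ord[(idx[3] + 1):idx[4]]] <- "FS"

  gap <- numeric(n)
  is_ft <- mech == "FT"; is_fa <- mech == "FA"; is_fs <- mech == "FS"
  gap[is_ft] <- pmax(2.5, stats::rnorm(sum(is_ft), scenario$ft_gap_K, 0.8))
  gap[is_fa] <- stats::rnorm(sum(is_fa), 0, scenario$fa_gap_sd_K)
  gap[is_fs] <- -pmax(1.0, stats::rnorm(sum(is_fs), scenario$fs_gap_K, 0.5))
  nt <- lt50 + gap
  nt <- pmin(-1.5, pmax(scenario$ramp_end_C + 1, nt))

  fp <- nt + pmax(0.5, stats::rnorm(n, scenario$fp_offset_K, 0.8))
  fp <- pmin(scenario$fp_max_C, fp)
  fp <- pmax(fp, nt + 0.3)

  # Gaussian copula: normal scores of LT50, correlated normal for LDMC
  rho_g <- 2 * sin(pi * scenario$ldmc_lt50_rho / 6)
  z1 <- stats::qnorm((rank(lt50, ties.method = "average") - 0.5) / n)
  z2 <- rho_g * z1 + sqrt(1 - rho_g^2) * stats::rnorm(n)
  ldmc <- exp(log(320) + 0.25 * z2)        # mg/g, lognormal around 320

  hmax_mean <- c(cushion = 0.05, graminoid = 0.25, forb = 0.15, shrub = 0.5)
  hmax <- exp(log(hmax_mean[gf]) + stats::rnorm(n, 0, 0.3))
  sla <- exp(log(10) + stats::rnorm(n, 0, 0.3))
  seed_mass <- exp(log(0.5) + stats::rnorm(n, 0, 0.8))

  data.frame(species_id = species_id, growth_form = gf,
             nt_true_C = nt, fp_true_C = fp, lt50_true_C = lt50,
             mechanism_true = mech, hmax_m = unname(hmax),
             sla_mm2_mg = sla, ldmc_mg_g = ldmc, seed_mass_mg = seed_mass,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate the plot-by-species cover matrix along altitude
#'
#' Plot altitudes are uniform on the scenario range. Each species gets a
#' Gaussian niche whose optimum rises as its true LT50 falls (hardier
#' species peak higher, plus noise) and whose width grows with the optimum's
#' altitude, so freezing-resistance CWMs decline and Rao FD rises with
#' altitude. An engineer species is present in every plot at high cover.
#' Every plot is guaranteed at least two non-engineer species.
#'
#' @param trait_table From [simulate_trait_table()].
#' @param scenario A [frost_scenario()].
#' @param seed Integer seed.
#' @return Wide data frame `plot_id`, `altitude_m`, engineer column, one
#'   column per species (percent cover).
#' @export
simulate_community <- function(trait_table, scenario = frost_scenario(),
                               seed = 1L) {
  require_columns(trait_table, c("species_id", "lt50_true_C"), "trait_table")
  set.seed(seed)
  np <- scenario$n_plots
  alt_lo <- scenario$altitude_range_m[1]; alt_hi <- scenario$altitude_range_m[2]
  alt <- sort(stats::runif(np, alt_lo, alt_hi))
  lt50 <- trait_table$lt50_true_C
  u <- (max(lt50) - lt50) / max(diff(range(lt50)), 1e-9)
  u <- scenario$niche_coupling * u +
    (1 - scenario$niche_coupling) * stats::runif(length(lt50))
  opt <- alt_lo + u * (alt_hi - alt_lo) +
    stats::rnorm(length(lt50), 0, scenario$niche_opt_noise_m)
  # niche breadth grows with plot altitude: high-altitude communities draw
  # from a broader slice of the trait pool than low-altitude ones
  width <- pmax(60, scenario$niche_width_base_m +
                  scenario$niche_width_slope * (alt - alt_lo))
  cmax <- stats::rlnorm(length(lt50), scenario$cover_cmax_meanlog,
                        scenario$cover_cmax_sdlog)
  cover <- sapply(seq_along(lt50), function(s)
    cmax[s] * exp(-0.5 * ((alt - opt[s]) / width)^2))
  if (scenario$cover_noise_sdlog > 0)
    cover <- cover * matrix(stats::rlnorm(length(cover), 0,
                                          scenario$cover_noise_sdlog),
                            nrow(cover))
  colnames(cover) <- trait_table$species_id
  cover[cover < scenario$cover_threshold] <- 0
  for (p in seq_len(np)) {            # keep >= 2 non-engineer species per plot
    if (sum(cover[p, ] > 0) < 2L) {
      raw <- cmax * exp(-0.5 * ((alt[p] - opt) / width[p])^2)
      top <- order(raw, decreasing = TRUE)[1:2]
      cover[p, top] <- pmax(raw[top], scenario$cover_threshold)
    }
  }
  eng <- pmax(30, stats::rnorm(np, scenario$engineer_cover_pct, 8))
  out <- data.frame(plot_id = sprintf("plot%02d", seq_len(np)),
                    altitude_m = alt, stringsAsFactors = FALSE)
  out[[scenario$engineer_species]] <- eng
  cbind(out, as.data.frame(cover))
}

#' Generate every pipeline input for one scenario
#'
#' Convenience wrapper producing the four input tables (thermograms, damage
#' assays, trait table, community matrix) from a single seed, optionally
#' writing them as CSV.
#'
#' @param scenario A [frost_scenario()].
#' @param seed Integer seed.
#' @param dir Optional output directory; when given, writes `traces.csv`,
#'   `damage_assays.csv`, `trait_table.csv`, `community.csv`.
#' @return Named list `traits`, `traces`, `assays`, `community`.
#' @export
simulate_frost_inputs <- function(scenario = frost_scenario(), seed = 1L,
                                  dir = NULL) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 3)
  traits <- simulate_trait_table(scenario, seed)
  traces <- simulate_thermograms(traits, scenario, seeds[1])
  assays <- simulate_damage_assays(traits, scenario, seeds[2])
  community <- simulate_community(traits, scenario, seeds[3])
  out <- list(traits = traits, traces = traces, assays = assays,
              community = community)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_frost_table(traits, file.path(dir, "trait_table.csv"))
    write_frost_table(traces, file.path(dir, "traces.csv"))
    write_frost_table(assays, file.path(dir, "damage_assays.csv"))
    write_frost_table(community, file.path(dir, "community.csv"))
  }
  invisible(out)
}
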