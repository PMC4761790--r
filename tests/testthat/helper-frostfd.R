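# Reduced scenario for fast unit tests: fewer species and plots, same study
# conditions otherwise (cooling program, target temperatures, noise levels).
small_scenario <- function(...) {
  frost_scenario(n_species = 12L, n_plots = 15L,
                 growth_form_counts = c(cushion = 3L, graminoid = 3L,
                                        forb = 4L, shrub = 2L),
                 mech_counts = c(FT = 6L, FA = 4L, FS = 2L),
                 ...)
}

noise_free_scenario <- function(...) {
  frost_scenario(trace_noise_sd_K = 0, fv_fm_noise_sd = 0,
                 nt_rep_sd_K = 0, fp_rep_sd_K = 0, ...)
}

# One-sample-per-temperature damage curve built directly from points.
curve_from_points <- function(temp_C, mean_phi, species_id = "sp",
                              f_max = 0.8) {
  structure(list(species_id = species_id, f_max = f_max,
                 points = data.frame(temp_C = temp_C, mean_phi = mean_phi,
                                     n = rep(5L, length(temp_C)))),
            class = "damage_curve")
}

# Brute-force Rao double sum: independent of the package implementation.
rao_brute <- function(p, x, range) {
  s <- 0
  for (i in seq_along(p)) for (j in seq_along(p)) {
    d <- min(1, abs(x[i] - x[j]) / range)
    s <- s + p[i] * p[j] * d
  }
  unname(s)
}
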