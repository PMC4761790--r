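#' Choose between t-test and Mann-Whitney for a two-sample comparison
#'
#' Applies the conventional assumption screen: both samples must pass a
#' Shapiro-Wilk normality check at `alpha` and an F-test of variance
#' homogeneity; otherwise the nonparametric Mann-Whitney U test is used.
#' Zero-variance samples (Shapiro-Wilk undefined) fall back to Mann-Whitney.
#'
#' @param sample_a,sample_b Numeric vectors, n >= 3 each.
#' @param alpha Screening level, default 0.05.
#' @return `"t_test"` or `"mann_whitney"`.
#' @export
choose_test <- function(sample_a, sample_b, alpha = 0.05) {
  if (length(sample_a) < 3L || length(sample_b) < 3L)
    stop("each sample needs n >= 3", call. = FALSE)
  normal_ok <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value >= alpha
  }
  if (!normal_ok(sample_a) || !normal_ok(sample_b)) return("mann_whitney")
  if (stats::var.test(sample_a, sample_b)$p.value < alpha) return("mann_whitney")
  "t_test"
}

#' Classify a species' freezing-resistance mechanism
#'
#' Compares ice nucleation temperature (NT) replicates against LT50. A
#' species is freezing tolerant (FT) when LT50 is significantly lower
#' (colder) than NT — tissue survives below the temperature at which it
#' freezes; freezing avoidant (FA) when the two are not significantly
#' different — damage coincides with ice formation; freezing sensitive (FS)
#' when LT50 is significantly higher (warmer) than NT — damage occurs before
#' nucleation on the cooling axis.
#'
#' With a single LT50 value (the default pipeline output: one interpolated
#' LT50 per species) a one-sample comparison of the NT replicates against
#' that value is used (t or Wilcoxon signed-rank by the same normality
#' screen). With LT50 replicates a two-sample comparison is chosen by
#' [choose_test()]. An all-NA LT50 censored below the tested range is
#' classified FT with `p_value` NA: damage provably lies below the coldest
#' nucleation temperature.
#'
#' @param nt_samples NT replicates in degC, n >= 3.
#' @param lt50_samples LT50 value(s) in degC (length 1 for the one-sample
#'   mode), or all NA for below-range censoring.
#' @param alpha Two-sided significance level, default 0.05.
#' @return List of class `mechanism_class`: `value` ("FT", "FA" or "FS"),
#'   `p_value`, `test_used`, `note`.
#' @export
classify_mechanism <- function(nt_samples, lt50_samples, alpha = 0.05) {
  nt_samples <- nt_samples[!is.na(nt_samples)]
  if (length(nt_samples) < 3L)
    stop("nt_samples needs n >= 3 non-missing values", call. = FALSE)
  out <- function(value, p, test, note = NA_character_)
    structure(list(value = value, p_value = p, test_used = test, note = note),
              class = "mechanism_class")

  if (all(is.na(lt50_samples)))
    return(out("FT", NA_real_, NA_character_,
               "LT50 censored below tested range; damage below coldest NT"))
  lt50_samples <- lt50_samples[!is.na(lt50_samples)]

  if (length(lt50_samples) == 1L) {
    mu <- lt50_samples
    if (stats::sd(nt_samples) == 0) {
      # degenerate NT spread: signed-rank reduces to a sign comparison
      if (all(nt_samples == mu)) return(out("FA", 1, "mann_whitney"))
      ht <- suppressWarnings(stats::wilcox.test(nt_samples, mu = mu,
                                                exact = FALSE))
      test <- "mann_whitney"
    } else if (stats::shapiro.test(nt_samples)$p.value >= alpha) {
      ht <- stats::t.test(nt_samples, mu = mu)
      test <- "t_test"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(nt_samples, mu = mu,
                                                exact = FALSE))
      test <- "mann_whitney"
    }
    diff_sig <- ht$p.value < alpha
    lt_mean <- mu
  } else {
    if (length(lt50_samples) < 3L)
      stop("two-sample mode needs n >= 3 LT50 replicates (or a single value)",
           call. = FALSE)
    test <- choose_test(nt_samples, lt50_samples, alpha)
    # pooled t: the homogeneity screen in choose_test licenses equal variances
    ht <- if (test == "t_test")
      stats::t.test(nt_samples, lt50_samples, var.equal = TRUE) else
      suppressWarnings(stats::wilcox.test(nt_samples, lt50_samples,
                                          exact = FALSE))
    diff_sig <- ht$p.value < alpha
    lt_mean <- mean(lt50_samples)
  }

  value <- if (!diff_sig) "FA"
    else if (lt_mean < mean(nt_samples)) "FT"
    else "FS"
  out(value, ht$p.value, test)
}

#' Classify every species from pipeline summary tables
#'
#' Joins per-leaf NT results with the per-species LT50 table and classifies
#' each species' mechanism.
#'
#' @param nt_results Per-leaf exotherm results as from [detect_exotherms()].
#' @param lt50 Per-species LT50 table as from [lt50_table()].
#' @param alpha Significance level, default 0.05.
#' @return Data frame `species_id`, `mechanism`, `p_value`, `test_used`.
#' @export
classify_species <- function(nt_results, lt50, alpha = 0.05) {
  require_columns(nt_results, c("species_id", "detected", "nt_C"), "nt_results")
  require_columns(lt50, c("species_id", "lt50_C", "censored"), "lt50")
  rows <- list()
  for (s in unique(lt50$species_id)) {
    nt <- nt_results$nt_C[nt_results$species_id == s &
                            nt_results$detected %in% TRUE]
    if (length(nt) < 3L) next
    cen <- lt50$censored[lt50$species_id == s][1]
    val <- lt50$lt50_C[lt50$species_id == s][1]
    if (identical(cen, "above_range")) {
      # damage already above the warmest test; warmer than any observed NT
      rows[[s]] <- data.frame(species_id = s, mechanism = "FS",
                              p_value = NA_real_, test_used = NA_character_,
                              stringsAsFactors = FALSE)
      next
    }
    cl <- classify_mechanism(nt, if (identical(cen, "below_range")) NA_real_
                             else val, alpha)
    rows[[s]] <- data.frame(species_id = s, mechanism = cl$value,
                            p_value = cl$p_value, test_used = cl$test_used,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Per-plot proportions of freezing-resistance mechanisms
#'
#' For every plot, the fraction of present species (cover > 0) in each
#' mechanism class, over the classified species only. Present species without
#' a classification are dropped with one warning. Fractions sum to 1 per
#' plot; a plot with zero classified species yields an NA row.
#'
#' @param community Wide plot-by-species cover data frame: columns `plot_id`,
#'   `altitude_m`, then one column per species.
#' @param mechanisms Either a data frame `species_id`, `mechanism` or a named
#'   character vector species -> class.
#' @return Data frame `plot_id`, `altitude_m`, `prop_FT`, `prop_FA`,
#'   `prop_FS`, `n_classified`.
#' @export
mechanism_proportions <- function(community, mechanisms) {
  require_columns(community, c("plot_id", "altitude_m"), "community")
  if (is.data.frame(mechanisms)) {
    require_columns(mechanisms, c("species_id", "mechanism"), "mechanisms")
    mech <- stats::setNames(mechanisms$mechanism, mechanisms$species_id)
  } else mech <- mechanisms
  sp_cols <- setdiff(names(community), c("plot_id", "altitude_m"))
  unknown <- sp_cols[!sp_cols %in% names(mech)]
  has_cover <- unknown[vapply(unknown, function(s)
    any(community[[s]] > 0, na.rm = TRUE), logical(1))]
  if (length(has_cover))
    warning("dropping unclassified species: ",
            paste(has_cover, collapse = ", "), call. = FALSE)
  classes <- c("FT", "FA", "FS")
  rows <- lapply(seq_len(nrow(community)), function(i) {
    present <- sp_cols[!is.na(as.numeric(community[i, sp_cols])) &
                         as.numeric(community[i, sp_cols]) > 0]
    present <- present[present %in% names(mech)]
    n <- length(present)
    if (n == 0L)
      return(data.frame(plot_id = community$plot_id[i],
                        altitude_m = community$altitude_m[i],
                        prop_FT = NA_real_, prop_FA = NA_real_,
                        prop_FS = NA_real_, n_classified = 0L))
    cnt <- table(factor(mech[present], levels = classes))
    data.frame(plot_id = community$plot_id[i],
               altitude_m = community$altitude_m[i],
               prop_FT = as.numeric(cnt["FT"]) / n,
               prop_FA = as.numeric(cnt["FA"]) / n,
               prop_FS = as.numeric(cnt["FS"]) / n,
               n_classified = n)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
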