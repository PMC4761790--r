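#' Gower dissimilarity for a single quantitative trait
#'
#' Range-normalised absolute difference |x_i - x_j| / range, 0 for
#' functionally equivalent species and 1 at maximal differentiation across
#' the species pool. The range is the global pool range (max - min over all
#' species carrying the trait), not a per-plot range, so distances are
#' comparable across plots.
#'
#' @param x_i,x_j Trait values (vectorised).
#' @param range Trait range over the species pool, > 0.
#' @return Dissimilarity in [0, 1].
#' @export
gower_distance <- function(x_i, x_j, range) {
  if (!is.numeric(range) || length(range) != 1L || !is.finite(range) ||
      range <= 0)
    stop("range must be a single positive number", call. = FALSE)
  pmin(1, pmax(0, abs(x_i - x_j) / range))
}

#' Drop an ecosystem-engineer species from a cover matrix
#'
#' Removes one species' cover from every plot before computing functional
#' components, so that a matrix-forming dominant present everywhere at high
#' cover does not mask the functional signal of the remaining species.
#'
#' @param community Wide cover data frame (`plot_id`, `altitude_m`, species
#'   columns).
#' @param species_id Column name of the species to exclude.
#' @return The community without that column. Plots left with no positive
#'   cover are reported via one warning and become NA downstream.
#' @export
exclude_engineer <- function(community, species_id) {
  require_columns(community, c("plot_id", "altitude_m"), "community")
  if (!species_id %in% names(community)) {
    warning("species '", species_id, "' not present in any plot",
            call. = FALSE)
    return(community)
  }
  out <- community[, setdiff(names(community), species_id), drop = FALSE]
  sp_cols <- setdiff(names(out), c("plot_id", "altitude_m"))
  cover <- as.matrix(out[, sp_cols, drop = FALSE])
  empty <- rowSums(cover > 0, na.rm = TRUE) == 0
  if (any(empty))
    warning("plots emptied by engineer exclusion: ",
            paste(out$plot_id[empty], collapse = ", "), call. = FALSE)
  out
}

retained_weights <- function(cover, trait) {
  keep <- names(cover)[!is.na(cover) & cover > 0]
  keep <- keep[keep %in% names(trait) & !is.na(trait[keep])]
  if (!length(keep)) return(NULL)
  w <- cover[keep]
  tot <- sum(w)
  if (tot <= 0) return(NULL)
  list(p = w / tot, x = trait[keep])
}

#' Community-weighted mean of a trait
#'
#' CWM = sum_i p_i x_i with p_i the cover of species i renormalised over the
#' species retained in the plot (positive cover and a non-missing trait
#' value). Invariant to rescaling all covers.
#'
#' @param cover Named numeric vector species -> cover (any nonnegative unit).
#' @param trait Named numeric vector species -> trait value.
#' @return The CWM, or NA when no species is retained.
#' @export
community_weighted_mean <- function(cover, trait) {
  rw <- retained_weights(cover, trait)
  if (is.null(rw)) return(NA_real_)
  sum(rw$p * rw$x)
}

#' Rao quadratic entropy for a single trait
#'
#' FD_Rao = sum_i sum_j p_i p_j d_ij over all ordered pairs of retained
#' species, with d_ij the Gower dissimilarity and p renormalised as in
#' [community_weighted_mean()]. Since d_ii = 0 and d is symmetric this equals
#' 2 sum_{i<j} p_i p_j d_ij. The abundance-weighted expected trait
#' dissimilarity of two randomly drawn individuals; 0 for a monoculture or a
#' functionally uniform plot, bounded by 1.
#'
#' @param cover Named numeric vector species -> cover.
#' @param trait Named numeric vector species -> trait value.
#' @param range Pool trait range used by [gower_distance()]; defaults to the
#'   range of `trait` itself.
#' @return FD_Rao in [0, 1], or NA when no species is retained.
#' @export
rao_fd <- function(cover, trait, range = NULL) {
  rw <- retained_weights(cover, trait)
  if (is.null(rw)) return(NA_real_)
  if (length(rw$p) == 1L) return(0)
  if (is.null(range)) range <- diff(range(trait, na.rm = TRUE))
  if (range <= 0) return(0)
  d <- abs(outer(rw$x, rw$x, "-")) / range
  d[d > 1] <- 1
  as.numeric(rw$p %*% d %*% rw$p)
}

#' Per-plot functional components (CWM and Rao FD) for freezing traits
#'
#' Computes the community-weighted mean and Rao quadratic entropy of each
#' trait for every plot, optionally after excluding an engineer species.
#' Species missing a trait value are dropped per trait, so different traits
#' may use different effective pools; the Gower range is the global pool
#' range of each trait.
#'
#' @param community Wide cover data frame (`plot_id`, `altitude_m`, species
#'   columns).
#' @param traits Data frame with `species_id` and one column per trait (e.g.
#'   `fp_C`, `lt50_C`).
#' @param trait_cols Trait columns to use; default all non-id columns.
#' @param exclude Optional engineer species column name to remove first.
#' @return Data frame `plot_id`, `altitude_m`, `trait`, `cwm`, `fd_rao`
#'   (NA rows for plots with no retained species).
#' @export
functional_components <- function(community, traits,
                                  trait_cols = NULL, exclude = NULL) {
  require_columns(community, c("plot_id", "altitude_m"), "community")
  require_columns(traits, "species_id", "traits")
  if (is.null(trait_cols)) trait_cols <- setdiff(names(traits), "species_id")
  if (!length(trait_cols)) stop("no trait columns", call. = FALSE)
  if (!is.null(exclude))
    community <- suppressWarnings(exclude_engineer(community, exclude))
  sp_cols <- setdiff(names(community), c("plot_id", "altitude_m"))
  if (!any(sp_cols %in% traits$species_id))
    stop("no overlap between community species and trait table", call. = FALSE)
  out <- list()
  for (tc in trait_cols) {
    x <- stats::setNames(traits[[tc]], traits$species_id)
    x <- x[!is.na(x)]
    rng <- if (length(x) >= 2L) diff(range(x)) else NA_real_
    for (i in seq_len(nrow(community))) {
      cov <- stats::setNames(as.numeric(community[i, sp_cols]), sp_cols)
      out[[length(out) + 1L]] <- data.frame(
        plot_id = community$plot_id[i],
        altitude_m = community$altitude_m[i],
        trait = tc,
        cwm = community_weighted_mean(cov, x),
        fd_rao = if (is.na(rng) || rng <= 0) 0 else rao_fd(cov, x, rng),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
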