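#' Photoinactivation from chlorophyll fluorescence
#'
#' PhI = 1 - FvFm_treated / Fmax, the fractional loss of photosystem II
#' integrity of a freezing-treated, dark-adapted leaf relative to the maximum
#' Fv/Fm observed for the species (controls included). 0 is undamaged, 1 is
#' dead (a dead leaf has Fv/Fm of zero). Clamped to [0, 1]: noisy Fv/Fm can
#' slightly exceed Fmax and negative damage is not meaningful.
#'
#' @param fv_fm_treated Fv/Fm of the treated leaf (>= 0).
#' @param f_max Maximum Fv/Fm over all individuals including the control
#'   (> 0).
#' @return Photoinactivation fraction in [0, 1]. Vectorised.
#' @examples
#' photoinactivation(0.6, 0.8) # 0.25
#' @export
photoinactivation <- function(fv_fm_treated, f_max) {
  if (any(!is.finite(f_max)) || any(f_max <= 0))
    stop("f_max must be > 0", call. = FALSE)
  if (any(fv_fm_treated < 0))
    stop("fv_fm_treated must be >= 0", call. = FALSE)
  pmin(1, pmax(0, 1 - fv_fm_treated / f_max))
}

damage_treatments <- function() c(-5, -10, -15, -19)

# Treatment column: "control" or a numeric target temperature in degC.
parse_treatment <- function(x) {
  x <- trimws(as.character(x))
  tt <- suppressWarnings(as.numeric(x))
  is_ctrl <- tolower(x) == "control"
  if (any(!is_ctrl & is.na(tt)))
    stop("treatment must be 'control' or a numeric temperature; got: ",
         paste(unique(x[!is_ctrl & is.na(tt)]), collapse = ", "),
         call. = FALSE)
  list(is_control = is_ctrl, temp_C = tt)
}

#' Build a species damage curve
#'
#' Computes Fmax as the maximum Fv/Fm over every record of the species
#' (control included) and the mean photoinactivation per treatment
#' temperature over replicate leaves, sorted warm to cold.
#'
#' @param assay Data frame with columns `leaf_id`, `treatment` (either the
#'   string "control" or a temperature in degC) and `fv_fm` in [0, 1], all
#'   records belonging to one species.
#' @param species_id Identifier stored in the result (defaults to the
#'   `species_id` column when present).
#' @return List of class `damage_curve`: `species_id`, `f_max`, and `points`,
#'   a data frame `temp_C`, `mean_phi`, `n` sorted by descending temperature.
#' @export
build_damage_curve <- function(assay, species_id = NULL) {
  require_columns(assay, c("leaf_id", "treatment", "fv_fm"), "assay")
  if (is.null(species_id))
    species_id <- if ("species_id" %in% names(assay))
      unique(assay$species_id)[1] else NA_character_
  if (any(assay$fv_fm < 0 | assay$fv_fm > 1))
    stop("fv_fm must lie in [0, 1]", call. = FALSE)
  tr <- parse_treatment(assay$treatment)
  if (!any(tr$is_control))
    stop("assay needs at least one control record", call. = FALSE)
  f_max <- max(assay$fv_fm)
  if (f_max <= 0)
    stop("f_max must be > 0: all Fv/Fm are zero", call. = FALSE)
  temps <- sort(unique(tr$temp_C[!tr$is_control]), decreasing = TRUE)
  if (!length(temps))
    stop("assay has no freezing-treatment records", call. = FALSE)
  pts <- do.call(rbind, lapply(temps, function(tc) {
    sel <- !tr$is_control & tr$temp_C == tc
    phi <- photoinactivation(assay$fv_fm[sel], f_max)
    data.frame(temp_C = tc, mean_phi = mean(phi), n = sum(sel))
  }))
  structure(list(species_id = species_id, f_max = f_max, points = pts),
            class = "damage_curve")
}

#' LT50 by bracketed linear interpolation
#'
#' LT50 is the temperature at which photoinactivation reaches 50%. Scanning
#' the treatment-level mean PhI curve from the warmest to the coldest tested
#' temperature, the first crossing of 0.5 defines the bracket: T1 (warm side,
#' PhI < 0.5) and T2 (cold side, PhI > 0.5), and
#' LT50 = T1 + (0.5 - PhI1) (T2 - T1) / (PhI2 - PhI1). A mean PhI of exactly
#' 0.5 at a tested temperature returns that temperature. Curves that never
#' reach 50% are censored `below_range` (resistance beyond the coldest test);
#' curves already above 50% at the warmest test are censored `above_range`.
#' No extrapolation beyond the tested grid is attempted.
#'
#' @param curve A `damage_curve` from [build_damage_curve()].
#' @return List of class `lt50_result`: `species_id`, `lt50_C` (NA when
#'   censored), `censored` one of "none", "below_range", "above_range", and
#'   `bracket` (data frame of the two points used, or NULL).
#' @examples
#' crv <- structure(list(species_id = "sp", f_max = 0.8,
#'                       points = data.frame(temp_C = c(-5, -10),
#'                                           mean_phi = c(0.2, 0.8),
#'                                           n = c(5, 5))),
#'                  class = "damage_curve")
#' lt50_interpolate(crv)$lt50_C # -7.5
#' @export
lt50_interpolate <- function(curve) {
  stopifnot(inherits(curve, "damage_curve"))
  pts <- curve$points
  if (nrow(pts) < 2L)
    stop("damage curve needs at least 2 treatment temperatures", call. = FALSE)
  pts <- pts[order(pts$temp_C, decreasing = TRUE), , drop = FALSE]
  res <- function(lt50, censored, bracket = NULL)
    structure(list(species_id = curve$species_id, lt50_C = lt50,
                   censored = censored, bracket = bracket),
              class = "lt50_result")

  for (j in seq_len(nrow(pts))) {
    phi <- pts$mean_phi[j]
    if (abs(phi - 0.5) < 1e-12)
      return(res(pts$temp_C[j], "none",
                 pts[j, c("temp_C", "mean_phi"), drop = FALSE]))
    if (phi > 0.5) {
      if (j == 1L) return(res(NA_real_, "above_range"))
      t1 <- pts$temp_C[j - 1L]; p1 <- pts$mean_phi[j - 1L]
      t2 <- pts$temp_C[j];      p2 <- pts$mean_phi[j]
      if (p2 <= p1)
        stop("non-monotone bracket: PhI(", t2, ") = ", signif(p2, 4),
             " <= PhI(", t1, ") = ", signif(p1, 4), call. = FALSE)
      lt <- t1 + (0.5 - p1) * (t2 - t1) / (p2 - p1)
      return(res(lt, "none", pts[c(j - 1L, j), c("temp_C", "mean_phi")]))
    }
  }
  res(NA_real_, "below_range")
}

#' LT50 table for a multi-species assay
#'
#' Builds a damage curve and interpolates LT50 for every species in a
#' long-format fluorescence assay table.
#'
#' @param assays Data frame with columns `species_id`, `leaf_id`, `treatment`,
#'   `fv_fm`.
#' @return Data frame `species_id`, `f_max`, `lt50_C`, `censored`, plus the
#'   per-temperature mean PhI table in `attr(, "phi_table")`.
#' @export
lt50_table <- function(assays) {
  require_columns(assays, c("species_id", "leaf_id", "treatment", "fv_fm"),
                  "assays")
  sp <- unique(assays$species_id)
  rows <- list(); phis <- list()
  for (s in sp) {
    crv <- build_damage_curve(assays[assays$species_id == s, , drop = FALSE],
                              species_id = s)
    r <- lt50_interpolate(crv)
    rows[[s]] <- data.frame(species_id = s, f_max = crv$f_max,
                            lt50_C = r$lt50_C, censored = r$censored,
                            stringsAsFactors = FALSE)
    phis[[s]] <- cbind(species_id = s, crv$points)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "phi_table") <- do.call(rbind, c(phis, make.row.names = FALSE))
  out
}
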