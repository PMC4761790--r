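#' Exotherm detection configuration
#'
#' Thresholds controlling how the freezing exotherm is located in a leaf
#' cooling trace. At a 2 degC/h ramp sampled at 1 Hz, inter-sample cooling is
#' about 0.00056 K, so a cumulative rise of 0.3 K within 60 s is far outside
#' what the cooling program can produce and robustly flags latent-heat release.
#'
#' @param rise_threshold_K Minimum cumulative temperature rise (K) within
#'   `rise_window_s` that qualifies as an exotherm onset. Default 0.3.
#' @param rise_window_s Window (s) over which the rise must accumulate.
#'   Default 60.
#' @param smooth_window_s Width (s) of the centred moving-average smoother
#'   applied before detection. Default 5.
#' @return An object of class `exotherm_config`.
#' @export
exotherm_config <- function(rise_threshold_K = 0.3, rise_window_s = 60,
                            smooth_window_s = 5) {
  if (!is.numeric(rise_threshold_K) || rise_threshold_K <= 0)
    stop("rise_threshold_K must be > 0", call. = FALSE)
  if (!is.numeric(rise_window_s) || rise_window_s <= 0)
    stop("rise_window_s must be > 0", call. = FALSE)
  if (!is.numeric(smooth_window_s) || smooth_window_s <= 0)
    stop("smooth_window_s must be > 0", call. = FALSE)
  structure(list(rise_threshold_K = rise_threshold_K,
                 rise_window_s = rise_window_s,
                 smooth_window_s = smooth_window_s),
            class = "exotherm_config")
}

# Centred moving average; edges keep the raw values so the series length and
# the temperature range of the trace are preserved.
smooth_trace <- function(x, width) {
  w <- max(1L, as.integer(round(width)))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L || length(x) < w) return(x)
  sm <- stats::filter(x, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  na <- is.na(sm)
  sm[na] <- x[na]
  sm
}

validate_trace <- function(time_s, temp_C) {
  if (length(time_s) != length(temp_C))
    stop("time_s and temp_C must have equal length", call. = FALSE)
  keep <- !duplicated(time_s)
  time_s <- time_s[keep]; temp_C <- temp_C[keep]
  if (length(time_s) < 60L)
    stop("trace too short: need at least 60 samples", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing after de-duplication",
         call. = FALSE)
  if (any(!is.finite(temp_C)) || any(temp_C < -40) || any(temp_C > 40))
    stop("temp_C must be finite and within [-40, 40] degC", call. = FALSE)
  list(time_s = time_s, temp_C = temp_C)
}

#' Detect the freezing exotherm in one leaf cooling trace
#'
#' Locates the first sustained temperature rise against the cooling trend:
#' the first sample from which the smoothed temperature climbs by at least
#' `rise_threshold_K` within `rise_window_s`. The ice nucleation temperature
#' (NT) is the smoothed local minimum immediately preceding that rise — the
#' lowest leaf temperature reached before extracellular freezing starts. The
#' freezing point (FP) is the maximum smoothed temperature the exotherm
#' reaches before the trace falls back below NT (or ends). An absent exotherm
#' is a data outcome, not an error: leaves can stay unfrozen down to -19 degC.
#'
#' @param time_s Sample times in seconds (1 Hz typical), strictly increasing
#'   after de-duplication, at least 60 samples.
#' @param temp_C Leaf temperature in degC, one value per time point.
#' @param config An [exotherm_config()].
#' @return A list with elements `detected` (logical), `nt_C`, `fp_C`
#'   (NA when not detected) and `onset_index` (index of the NT sample).
#' @examples
#' tr <- simulate_thermogram(nt_true = -6, fp_true = -1.5,
#'                           scenario = frost_scenario(trace_noise_sd = 0),
#'                           seed = 1)
#' detect_exotherm(tr$time_s, tr$temp_C)
#' @export
detect_exotherm <- function(time_s, temp_C, config = exotherm_config()) {
  stopifnot(inherits(config, "exotherm_config"))
  tr <- validate_trace(time_s, temp_C)
  time_s <- tr$time_s; temp_C <- tr$temp_C
  n <- length(temp_C)
  dt <- stats::median(diff(time_s))
  s <- smooth_trace(temp_C, config$smooth_window_s / dt)

  none <- list(detected = FALSE, nt_C = NA_real_, fp_C = NA_real_,
               onset_index = NA_integer_)

  # forward-looking max over the rise window: fmax[i] = max(s[i+1 .. i+W])
  W <- max(1L, as.integer(round(config$rise_window_s / dt)))
  W <- min(W, n - 1L)
  fmax <- rep(-Inf, n)
  for (k in seq_len(W)) {
    idx <- seq_len(n - k)
    fmax[idx] <- pmax(fmax[idx], s[idx + k])
  }
  qualifies <- (fmax - s) >= config$rise_threshold_K
  qualifies[n] <- FALSE
  if (!any(qualifies)) return(none)
  i0 <- which(qualifies)[1L]

  # refine onset: local minimum of the smoothed series before the windowed peak
  win <- i0:min(n, i0 + W)
  peak_rel <- which.max(s[win])
  nt_idx <- win[which.min(s[win[seq_len(peak_rel)]])]
  nt <- s[nt_idx]

  # exotherm extent: from onset until the trace falls back below NT (or ends)
  after <- if (nt_idx < n) (nt_idx + 1L):n else integer(0)
  back <- after[s[after] < nt]
  end_idx <- if (length(back)) back[1L] else n
  fp <- max(s[nt_idx:end_idx])
  if (fp <= nt) return(none)

  list(detected = TRUE, nt_C = nt, fp_C = fp, onset_index = nt_idx)
}

#' Detect exotherms for a table of traces
#'
#' Applies [detect_exotherm()] to each leaf in a long-format thermogram table.
#'
#' @param traces Data frame with columns `species_id`, `leaf_id`, `time_s`,
#'   `temp_C`.
#' @param config An [exotherm_config()].
#' @return Data frame with one row per leaf: `species_id`, `leaf_id`,
#'   `detected`, `nt_C`, `fp_C`, `onset_index`.
#' @export
detect_exotherms <- function(traces, config = exotherm_config()) {
  require_columns(traces, c("species_id", "leaf_id", "time_s", "temp_C"),
                  "traces")
  key <- paste(traces$species_id, traces$leaf_id, sep = "\r")
  idx <- split(seq_along(key), factor(key, levels = unique(key)))
  out <- lapply(idx, function(sel) {
    r <- detect_exotherm(traces$time_s[sel], traces$temp_C[sel], config)
    data.frame(species_id = traces$species_id[sel[1]],
               leaf_id = traces$leaf_id[sel[1]],
               detected = r$detected, nt_C = r$nt_C, fp_C = r$fp_C,
               onset_index = r$onset_index, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Per-species NT and FP summaries
#'
#' Mean and standard error (sample SD / sqrt(n)) of NT and FP over the
#' detected leaves of each species, as conventionally reported
#' ("mean +/- SE"). Leaves without a detected exotherm are excluded and
#' counted; a species with zero detected leaves yields no summary row but is
#' returned in the `skipped` attribute.
#'
#' @param results Per-leaf results as from [detect_exotherms()].
#' @return Data frame `species_id`, `n_detected`, `n_undetected`, `nt_mean_C`,
#'   `nt_se`, `fp_mean_C`, `fp_se`. SE is NA for n = 1. Species with no
#'   detected leaf are listed in `attr(, "skipped")`.
#' @export
summarize_species_thermal <- function(results) {
  require_columns(results, c("species_id", "detected", "nt_C", "fp_C"),
                  "results")
  sp <- unique(results$species_id)
  rows <- list(); skipped <- character(0)
  for (s in sp) {
    sub <- results[results$species_id == s, , drop = FALSE]
    det <- sub[sub$detected %in% TRUE, , drop = FALSE]
    if (nrow(det) == 0L) { skipped <- c(skipped, s); next }
    se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
    rows[[s]] <- data.frame(
      species_id = s,
      n_detected = nrow(det),
      n_undetected = nrow(sub) - nrow(det),
      nt_mean_C = mean(det$nt_C), nt_se = se(det$nt_C),
      fp_mean_C = mean(det$fp_C), fp_se = se(det$fp_C),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(species_id = character(0), n_detected = integer(0),
               n_undetected = integer(0), nt_mean_C = numeric(0),
               nt_se = numeric(0), fp_mean_C = numeric(0), fp_se = numeric(0))
  if (length(skipped))
    warning("no detected exotherm for: ", paste(skipped, collapse = ", "),
            call. = FALSE)
  attr(out, "skipped") <- skipped
  out
}
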