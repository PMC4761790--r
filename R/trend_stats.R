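#' Linear trend of a per-plot quantity along altitude
#'
#' Ordinary least squares fit of `y` on `x` with a two-sided slope test.
#'
#' @param y Response (e.g. a CWM, FD or mechanism proportion per plot).
#' @param x Predictor (altitude in m). NA pairs are dropped.
#' @return List of class `trend_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
linear_trend <- function(y, x) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in predictor", call. = FALSE)
  if (stats::sd(y) == 0)
    return(structure(list(slope = 0, intercept = y[1], r_squared = 0,
                          p_value = 1, n = length(y)), class = "trend_fit"))
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  p <- if (nrow(sm$coefficients) < 2L || sm$sigma == 0) {
    # a perfectly collinear fit has no residual error; slope p is 0 unless flat
    if (abs(stats::coef(fit)[2]) > 0) 0 else 1
  } else sm$coefficients[2, 4]
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared, p_value = unname(p),
                 n = length(y)),
            class = "trend_fit")
}

# Nemenyi many-to-many rank comparison (Tukey-range form, tie corrected):
# q_ij = |Rbar_i - Rbar_j| / sqrt(C * N(N+1)/12 * (1/n_i + 1/n_j)),
# p from the studentized range distribution with k groups and infinite df.
nemenyi_pairwise <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  lev <- levels(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(C * N * (N + 1) / 12 * (1 / n[i] + 1 / n[j]))
    q <- abs(rbar[i] - rbar[j]) / se
    p[i, j] <- p[j, i] <- stats::ptukey(q * sqrt(2), k, Inf,
                                        lower.tail = FALSE)
  }
  diag(p) <- 1
  p
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Groups sharing at least one letter are not significantly different at
#' `alpha`. Uses the insert-and-absorb algorithm: start from one letter
#' covering all groups, split it on each significant pair, drop letter sets
#' contained in another.
#'
#' @param p Symmetric matrix of pairwise p-values with group dimnames.
#' @param alpha Significance level.
#' @return Named character vector of letter strings per group.
#' @export
compact_letters <- function(p, alpha = 0.05) {
  g <- rownames(p)
  sets <- list(g)
  pairs <- which(upper.tri(p) & p < alpha, arr.ind = TRUE)
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    a <- g[pairs[r, 1]]; b <- g[pairs[r, 2]]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb: drop sets that are subsets of another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) for (j in seq_along(new_sets)) {
      if (i != j && keep[i] && keep[j] &&
          all(new_sets[[i]] %in% new_sets[[j]]) &&
          (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j))
        keep[i] <- FALSE
    }
    sets <- new_sets[keep]
  }
  letters_used <- letters[seq_along(sets)]
  out <- stats::setNames(rep("", length(g)), g)
  for (i in seq_along(sets)) for (m in sets[[i]])
    out[m] <- paste0(out[m], letters_used[i])
  out
}

#' Kruskal-Wallis test with Nemenyi post hoc across groups
#'
#' Tie-corrected Kruskal-Wallis rank-sum test of a trait across growth forms,
#' followed by the Nemenyi many-to-many rank comparison (Tukey studentized
#' range form) and a compact letter display at `alpha`. Groups with fewer
#' than 2 members are excluded with a warning.
#'
#' @param values Numeric trait values per species.
#' @param groups Group labels (growth forms), same length.
#' @param alpha Level for the letter display, default 0.05.
#' @return List of class `group_contrast`: `kw_statistic`, `kw_df`, `kw_p`,
#'   `pairwise` (symmetric p matrix), `letters`.
#' @export
kruskal_nemenyi <- function(values, groups, alpha = 0.05) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(as.character(groups[ok]))
  n <- table(groups)
  small <- names(n)[n < 2]
  if (length(small)) {
    warning("excluding groups with < 2 members: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !groups %in% small
    values <- values[keep]; groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2L)
    stop("need >= 2 groups with >= 2 members", call. = FALSE)
  kw <- stats::kruskal.test(values, groups)
  pw <- nemenyi_pairwise(values, groups)
  structure(list(kw_statistic = unname(kw$statistic),
                 kw_df = unname(kw$parameter),
                 kw_p = kw$p.value,
                 pairwise = pw,
                 letters = compact_letters(pw, alpha)),
            class = "group_contrast")
}

#' Correlation between two species-level traits
#'
#' Pearson's or Spearman's correlation; `method = "auto"` picks Pearson when
#' both variables pass a Shapiro-Wilk normality check at 0.05 and Spearman
#' otherwise.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped (>= 4 required).
#' @param method "auto", "pearson" or "spearman".
#' @return List: `method`, `estimate` in [-1, 1], `p_value`, `n`.
#' @export
trait_correlation <- function(x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need >= 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance", call. = FALSE)
  if (method == "auto") {
    normal <- stats::shapiro.test(x)$p.value >= 0.05 &&
      stats::shapiro.test(y)$p.value >= 0.05
    method <- if (normal) "pearson" else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(method = method, estimate = unname(ct$estimate),
       p_value = ct$p.value, n = length(x))
}
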