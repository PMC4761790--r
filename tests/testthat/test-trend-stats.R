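test_that("linear_trend recovers exact and degenerate fits", {
  alt <- seq(1940, 2428, length.out = 10)
  f <- linear_trend(2 * alt + 1, alt)
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  flat <- linear_trend(rep(3, 10), alt)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(linear_trend(1:5, rep(2000, 5)), "zero variance")
  expect_error(linear_trend(c(1, 2, NA), c(1, 2, 3)), ">= 3")
})

test_that("regression is invariant to row permutation", {
  set.seed(3)
  x <- runif(20, 1940, 2428); y <- -0.004 * x + rnorm(20, 0, 0.5)
  a <- linear_trend(y, x)
  idx <- sample(20)
  b <- linear_trend(y[idx], x[idx])
  expect_equal(a$slope, b$slope, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("a CWM-like altitudinal coupling is detected as negative", {
  set.seed(14)
  hits <- replicate(200, {
    alt <- runif(38, 1940, 2428)
    y <- -0.004 * alt + rnorm(38, 0, 0.5)
    linear_trend(y, alt)$slope < 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Kruskal-Wallis statistic matches the hand-ranked value", {
  # ranks 1..9 in three groups: H = 12/(N(N+1)) * sum n_g (rbar_g - rbar)^2
  gc <- kruskal_nemenyi(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                        rep(c("g1", "g2", "g3"), each = 3))
  expect_equal(gc$kw_statistic, 7.2, tolerance = 1e-10)
  expect_equal(gc$kw_df, 2)
  # invariance under a strictly monotone transform
  gc2 <- kruskal_nemenyi(exp(c(1, 2, 3, 4, 5, 6, 7, 8, 9) / 2),
                         rep(c("g1", "g2", "g3"), each = 3))
  expect_equal(gc2$kw_statistic, gc$kw_statistic, tolerance = 1e-10)
})

test_that("identical groups share a letter; separated groups do not", {
  same <- kruskal_nemenyi(c(1, 2, 3, 4, 1, 2, 3, 4),
                          rep(c("a", "b"), each = 4))
  expect_gte(same$kw_p, 0.95)
  expect_equal(unname(same$letters["a"]), unname(same$letters["b"]))
  set.seed(5)
  vals <- c(rnorm(8, 0, 0.1), rnorm(8, 10, 0.1), rnorm(8, 20, 0.1))
  gf <- rep(c("low", "mid", "high"), each = 8)
  sep <- kruskal_nemenyi(vals, gf)
  expect_lt(sep$kw_p, 0.05)
  expect_true(sep$pairwise["low", "high"] < 0.05)
  expect_false(grepl(sep$letters["high"], sep$letters["low"], fixed = TRUE))
  # pairwise matrix is symmetric
  expect_equal(sep$pairwise, t(sep$pairwise))
})

test_that("undersized groups are excluded with a warning", {
  expect_warning(gc <- kruskal_nemenyi(c(1, 2, 3, 4, 9),
                                       c("a", "a", "b", "b", "c")), "c")
  expect_false("c" %in% rownames(gc$pairwise))
  expect_error(suppressWarnings(kruskal_nemenyi(c(1, 2, 3), c("a", "a", "b"))),
               ">= 2 groups")
})

test_that("letter displays are consistent with the pairwise matrix", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    vals <- unlist(lapply(1:k, function(g) rnorm(6, g * runif(1, 0, 4), 1)))
    gf <- rep(paste0("g", 1:k), each = 6)
    gc <- kruskal_nemenyi(vals, gf)
    for (a in rownames(gc$pairwise)) for (b in colnames(gc$pairwise)) {
      if (a == b) next
      shared <- any(strsplit(gc$letters[a], "")[[1]] %in%
                      strsplit(gc$letters[b], "")[[1]])
      if (gc$pairwise[a, b] < 0.05) expect_false(shared)
      else expect_true(shared)
    }
  }
})

test_that("trait correlations behave for monotone and linear data", {
  x <- c(1, 2, 4, 8, 16, 32)
  r <- trait_correlation(x, x^3, method = "spearman")
  expect_equal(r$estimate, 1)
  expect_equal(trait_correlation(x, -x, method = "pearson")$estimate, -1,
               tolerance = 1e-12)
  expect_equal(trait_correlation(x, -x, method = "spearman")$estimate, -1)
  expect_error(trait_correlation(x, rep(1, 6)), "zero variance")
  expect_error(trait_correlation(1:3, 1:3), ">= 4")
  # auto mode picks spearman for a heavy-tailed variable
  set.seed(9)
  hv <- exp(rnorm(30, 0, 2.5)); nv <- rnorm(30)
  expect_equal(trait_correlation(hv, nv, "auto")$method, "spearman")
  expect_equal(trait_correlation(rnorm(30), rnorm(30), "auto")$method,
               "pearson")
})

test_that("the LDMC-LT50 copula coupling is recovered on average", {
  sc <- frost_scenario()
  rhos <- vapply(1:200, function(s) {
    tt <- simulate_trait_table(sc, seed = s)
    suppressWarnings(trait_correlation(tt$ldmc_mg_g, tt$lt50_true_C,
                                       "spearman")$estimate)
  }, numeric(1))
  expect_lt(abs(mean(rhos) - (-0.55)), 0.1)
  sc0 <- frost_scenario(ldmc_lt50_rho = 0)
  rhos0 <- vapply(1:100, function(s) {
    tt <- simulate_trait_table(sc0, seed = s)
    suppressWarnings(trait_correlation(tt$ldmc_mg_g, tt$lt50_true_C,
                                       "spearman")$estimate)
  }, numeric(1))
  expect_lt(abs(mean(rhos0)), 0.1)
})
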