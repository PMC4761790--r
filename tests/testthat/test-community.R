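test_that("Gower distance is the range-normalised absolute difference", {
  expect_equal(gower_distance(-7, -7, 10), 0)
  expect_equal(gower_distance(-19, -5, 14), 1)      # pool extremes
  expect_equal(gower_distance(-4, -9, 10), 0.5)
  expect_equal(gower_distance(-4, -30, 10), 1)      # clamped
  expect_error(gower_distance(1, 2, 0), "positive")
})

test_that("engineer exclusion removes the species and flags emptied plots", {
  comm <- data.frame(plot_id = c("p1", "p2", "p3"),
                     altitude_m = c(2000, 2100, 2200),
                     Eng = c(60, 0, 100), A = c(20, 5, 0), B = c(20, 5, 0))
  expect_warning(out <- exclude_engineer(comm, "Eng"), "emptied")
  expect_false("Eng" %in% names(out))
  expect_equal(out$A, comm$A)
  expect_warning(exclude_engineer(comm, "nope"), "not present")
  comm2 <- data.frame(plot_id = "p1", altitude_m = 2000, Eng = 100, A = 0)
  expect_warning(exclude_engineer(comm2, "Eng"), "emptied")
})

test_that("CWM matches hand-computed weighted means", {
  expect_equal(community_weighted_mean(c(A = 3), c(A = -7.2)), -7.2)
  expect_equal(community_weighted_mean(c(A = 20, B = 20), c(A = 2, B = 4)), 3)
  expect_equal(community_weighted_mean(c(A = 50, B = 30, C = 20),
                                       c(A = 0, B = 5, C = 10)), 3.5)
  # species without the trait are dropped before renormalisation
  expect_equal(community_weighted_mean(c(A = 50, B = 50), c(A = 2, B = NA)), 2)
  expect_true(is.na(community_weighted_mean(c(A = 0), c(A = 2))))
})

test_that("Rao matches hand-computed double sums", {
  expect_equal(rao_fd(c(A = 5), c(A = 1), range = 10), 0)
  expect_equal(rao_fd(c(A = 1, B = 1), c(A = 0, B = 10), range = 10), 0.5)
  expect_equal(rao_fd(c(A = 50, B = 30, C = 20), c(A = 0, B = 5, C = 10),
                      range = 10),
               2 * (0.5 * 0.3 * 0.5 + 0.5 * 0.2 * 1.0 + 0.3 * 0.2 * 0.5),
               tolerance = 1e-12)
})

test_that("Rao agrees with the brute-force oracle on random communities", {
  set.seed(505)
  for (i in 1:1000) {
    k <- sample(1:6, 1)
    x <- stats::setNames(runif(k, -19, -5), paste0("s", 1:k))
    cov <- stats::setNames(runif(k, 0.1, 50), names(x))
    rng <- max(diff(range(x)), 1)
    got <- rao_fd(cov, x, range = rng)
    p <- cov / sum(cov)
    expect_equal(got, rao_brute(p, x, rng), tolerance = 1e-12)
    expect_equal(community_weighted_mean(cov, x), sum(p * x),
                 tolerance = 1e-12)
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("CWM and Rao are invariant to cover rescaling and bounded", {
  set.seed(99)
  x <- stats::setNames(runif(8, -19, -5), paste0("s", 1:8))
  cov <- stats::setNames(runif(8, 0, 30), names(x))
  rng <- diff(range(x))
  expect_equal(community_weighted_mean(cov, x),
               community_weighted_mean(cov * 2, x), tolerance = 1e-12)
  expect_equal(rao_fd(cov, x, rng), rao_fd(cov * 2, x, rng),
               tolerance = 1e-12)
  cwm <- community_weighted_mean(cov, x)
  expect_gte(cwm, min(x)); expect_lte(cwm, max(x))
  # relabeling symmetry
  perm <- sample(names(x))
  expect_equal(rao_fd(cov[perm], x[perm], rng), rao_fd(cov, x, rng),
               tolerance = 1e-12)
})

test_that("two-species Rao equals 2p(1-p)d and peaks at p = 0.5", {
  d <- gower_distance(-6, -12, 10)
  ps <- seq(0.05, 0.95, by = 0.05)
  rao <- vapply(ps, function(p)
    rao_fd(c(A = p, B = 1 - p), c(A = -6, B = -12), range = 10), numeric(1))
  expect_equal(rao, 2 * ps * (1 - ps) * d, tolerance = 1e-12)
  expect_equal(ps[which.max(rao)], 0.5)
})

test_that("functional components table matches per-plot hand computation", {
  comm <- data.frame(plot_id = c("p1", "p2"), altitude_m = c(2000, 2400),
                     A = c(50, 0), B = c(30, 10), C = c(20, 10))
  traits <- data.frame(species_id = c("A", "B", "C"),
                       lt50_C = c(-5, -10, -15))
  fc <- functional_components(comm, traits, trait_cols = "lt50_C")
  # p1: p = (.5,.3,.2), x = (-5,-10,-15), pool range 10
  expect_equal(fc$cwm[1], -8.5, tolerance = 1e-12)
  expect_equal(fc$fd_rao[1],
               rao_brute(c(.5, .3, .2), c(-5, -10, -15), 10),
               tolerance = 1e-12)
  # p2: equal covers of B and C
  expect_equal(fc$cwm[2], -12.5, tolerance = 1e-12)
  expect_equal(fc$fd_rao[2], 2 * 0.25 * 0.5, tolerance = 1e-12)
})

test_that("degenerate trait tables give Rao 0 and flat CWM", {
  comm <- data.frame(plot_id = c("p1", "p2"), altitude_m = c(2000, 2400),
                     A = c(5, 1), B = c(2, 8))
  traits <- data.frame(species_id = c("A", "B"), lt50_C = c(-9, -9))
  fc <- functional_components(comm, traits)
  expect_true(all(fc$fd_rao == 0))
  expect_true(all(fc$cwm == -9))
  # doubling covers changes nothing
  comm2 <- comm; comm2$A <- comm$A * 2; comm2$B <- comm$B * 2
  traits2 <- data.frame(species_id = c("A", "B"), lt50_C = c(-5, -12))
  expect_equal(functional_components(comm, traits2),
               functional_components(comm2, traits2), tolerance = 1e-12)
  expect_error(functional_components(comm,
                                     data.frame(species_id = "Z", lt50_C = 1)),
               "overlap")
})
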