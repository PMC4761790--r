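test_that("photoinactivation follows 1 - FvFm/Fmax, clamped to [0, 1]", {
  expect_equal(photoinactivation(0.8, 0.8), 0)      # undamaged identity
  expect_equal(photoinactivation(0, 0.8), 1)        # dead leaf
  expect_equal(photoinactivation(0.6, 0.8), 0.25, tolerance = 1e-12)
  expect_equal(photoinactivation(0.85, 0.8), 0)     # noise above f_max clamps
  expect_error(photoinactivation(0.5, 0), "f_max")
  expect_error(photoinactivation(-0.1, 0.8), "fv_fm_treated")
  # antitone in the treated reading for fixed f_max
  fv <- seq(0, 0.8, by = 0.05)
  expect_true(all(diff(photoinactivation(fv, 0.8)) <= 0))
})

test_that("damage curves take f_max over all records and mean PhI per level", {
  assay <- data.frame(
    leaf_id = paste0("L", 1:6),
    treatment = c("control", "control", "-5", "-5", "-10", "-10"),
    fv_fm = c(0.78, 0.80, 0.80, 0.80, 0.40, 0.48))
  crv <- build_damage_curve(assay, species_id = "sp")
  expect_equal(crv$f_max, 0.80)
  expect_equal(crv$points$temp_C, c(-5, -10))       # warm to cold
  expect_equal(crv$points$mean_phi, c(0, 0.45), tolerance = 1e-12)
  # complete damage at the cold end
  assay2 <- data.frame(leaf_id = c("a", "b", "c"),
                       treatment = c("control", "-19", "-19"),
                       fv_fm = c(0.8, 0, 0))
  expect_equal(build_damage_curve(assay2)$points$mean_phi, 1)
  expect_error(build_damage_curve(
    data.frame(leaf_id = "a", treatment = "-5", fv_fm = 0.5)), "control")
})

test_that("LT50 interpolation matches the closed form on bracketed curves", {
  expect_equal(lt50_interpolate(curve_from_points(c(-5, -10),
                                                  c(0.2, 0.8)))$lt50_C,
               -7.5, tolerance = 1e-12)
  expect_equal(lt50_interpolate(curve_from_points(c(-5, -10),
                                                  c(0.25, 0.75)))$lt50_C,
               -7.5, tolerance = 1e-12)
  r <- lt50_interpolate(curve_from_points(c(-5, -10, -15, -19),
                                          c(0.1, 0.3, 0.7, 0.95)))
  expect_equal(r$censored, "none")
  expect_equal(r$lt50_C, -10 + (0.5 - 0.3) * (-5) / 0.4, tolerance = 1e-12)
  expect_true(r$lt50_C > -15 && r$lt50_C < -10)     # inside its bracket
})

test_that("censoring flags cover both ends and the exact-0.5 case", {
  below <- lt50_interpolate(curve_from_points(c(-5, -10, -15, -19),
                                              c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(below$censored, "below_range")
  expect_true(is.na(below$lt50_C))
  above <- lt50_interpolate(curve_from_points(c(-5, -10), c(0.8, 0.9)))
  expect_equal(above$censored, "above_range")
  expect_true(is.na(above$lt50_C))
  exact <- lt50_interpolate(curve_from_points(c(-5, -10, -15),
                                              c(0.2, 0.5, 0.9)))
  expect_equal(exact$lt50_C, -10)
  expect_equal(exact$censored, "none")
  expect_error(lt50_interpolate(curve_from_points(-5, 0.4)), "at least 2")
})

test_that("a PhI dip before the crossing is resolved by the first crossing", {
  r <- lt50_interpolate(curve_from_points(c(-5, -10, -15, -19),
                                          c(0.30, 0.20, 0.80, 0.90)))
  expect_equal(r$censored, "none")
  expect_equal(r$lt50_C, -10 + (0.5 - 0.2) * (-5) / 0.6, tolerance = 1e-12)
})

test_that("step-function damage pins LT50 to the bracket midpoint", {
  # brute force over true midpoints: in the k -> Inf limit, PhI is 0 at -5
  # and 1 at -10 for any midpoint inside (-10, -5), so LT50 is always -7.5
  sc <- noise_free_scenario(damage_slope_k = 1e6)
  for (m in seq(-9.5, -5.5, by = 0.5)) {
    a <- simulate_damage_assay(m, sc, seed = 1)
    r <- lt50_interpolate(build_damage_curve(a))
    expect_equal(r$lt50_C, -7.5, tolerance = 1e-6)
  }
})

test_that("noise-free logistic damage matches the grid-interpolation oracle", {
  sc <- noise_free_scenario()              # k = 1.5 per K
  # independent oracle: evaluate the logistic on the grid, interpolate by
  # hand; the interpolation bias is bounded by half the local grid spacing
  grid <- c(-5, -10, -15, -19)
  for (m in c(-9, -12, -7.3, -16.1)) {
    phi <- 1 / (1 + exp(sc$damage_slope_k * (grid - m)))
    j <- which(phi > 0.5)[1]
    expected <- grid[j - 1] + (0.5 - phi[j - 1]) * (grid[j] - grid[j - 1]) /
      (phi[j] - phi[j - 1])
    a <- simulate_damage_assay(m, sc, seed = 3)
    r <- lt50_interpolate(build_damage_curve(a))
    expect_equal(r$lt50_C, expected, tolerance = 1e-9)
    expect_lte(abs(r$lt50_C - m), (grid[j - 1] - grid[j]) / 2)
  }
})

test_that("logistic damage with Fv/Fm noise recovers LT50 within 1.5 K", {
  sc <- frost_scenario()                   # k = 1.5, sigma = 0.03, 5 reps
  set.seed(202)
  ms <- runif(200, -17, -6)
  errs <- vapply(seq_along(ms), function(i) {
    a <- simulate_damage_assay(ms[i], sc, seed = 9000 + i)
    r <- lt50_interpolate(build_damage_curve(a))
    abs(r$lt50_C - ms[i])
  }, numeric(1))
  expect_lt(median(errs), 1.5)
})

test_that("lt50_table handles several species and keeps the PhI table", {
  sc <- noise_free_scenario()
  assays <- rbind(simulate_damage_assay(-8, sc, 1, species_id = "a"),
                  simulate_damage_assay(-14, sc, 2, species_id = "b"))
  tab <- lt50_table(assays)
  expect_equal(tab$species_id, c("a", "b"))
  expect_true(all(tab$censored == "none"))
  expect_true(tab$lt50_C[2] < tab$lt50_C[1])
  phi <- attr(tab, "phi_table")
  expect_equal(nrow(phi), 8L)              # 4 temperatures x 2 species
  expect_true(all(phi$mean_phi >= 0 & phi$mean_phi <= 1))
})
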