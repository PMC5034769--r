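# Helper: a data set whose bins are single records at chosen log10 stem
# positions, with leaf mass set from a function of log10 stem. Root mass
# is tiny so binning order follows leaf+stem.
one_record_bins <- function(xs, fy) {
  biomass_data(data.frame(
    species = "s",
    leaf_mass_g = 10^fy(xs), stem_mass_g = 10^xs,
    root_mass_g = 10^(min(xs) - 6)))
}

test_that("equal-frequency bins balance counts and honour stable ties", {
  ds <- generate_fixed(100, seed = 1)
  b <- make_bins(ds, 50)
  expect_equal(b$table$n, rep(2L, 50))
  expect_true(all(diff(b$table$med_log_total) >= 0))

  # many identical totals: stable input order breaks the tie
  df <- data.frame(species = "s", leaf_mass_g = rep(1, 7),
                   stem_mass_g = rep(1, 7), root_mass_g = rep(1, 7),
                   record_id = paste0("r", 1:7))
  b2 <- make_bins(biomass_data(df), 3)
  expect_equal(b2$table$n, c(3L, 2L, 2L))
  expect_equal(b2$assignment, c(1L, 1L, 1L, 2L, 2L, 3L, 3L))

  expect_error(make_bins(ds, 200), "smaller n_bins")
})

test_that("per-bin medians match a hand-enumerated 6-record set", {
  df <- data.frame(species = "s",
                   leaf_mass_g = c(1, 2, 3, 10, 20, 30),
                   stem_mass_g = c(1, 2, 3, 10, 20, 30),
                   root_mass_g = c(1, 2, 3, 10, 20, 30))
  b <- make_bins(biomass_data(df), 2)
  expect_equal(b$table$med_log_leaf, log10(c(2, 20)))
  expect_equal(b$table$med_log_total, log10(3 * c(2, 20)))
})

test_that("triplet slopes are exact on lines and quadratics", {
  ds_lin <- one_record_bins(1:5, function(x) x)
  s_lin <- triplet_slopes(make_bins(ds_lin, 5), "leaf", "stem")
  expect_equal(s_lin, rep(1, 5), ignore_attr = TRUE)

  # y = x^2 at x = 1..5: central slopes 4, 6, 8; per-bin averages
  ds_quad <- one_record_bins(1:5, function(x) x^2)
  s_quad <- triplet_slopes(make_bins(ds_quad, 5), "leaf", "stem")
  expect_equal(s_quad, c(4, 5, 6, 7, 8), ignore_attr = TRUE)
  expect_equal(attr(s_quad, "n_estimates"), c(1L, 2L, 3L, 2L, 1L))
})

test_that("loess smoothing reproduces constants and linear trends", {
  grid <- seq(0, 10, length.out = 40)
  expect_equal(smooth_slopes(rep(0.7, 40), grid), rep(0.7, 40),
               tolerance = 1e-9, ignore_attr = TRUE)
  lin <- 1 - 0.04 * grid
  expect_lt(max(abs(smooth_slopes(lin, grid)[5:36] - lin[5:36])), 1e-6)
  expect_error(smooth_slopes(lin, grid, span = 1.5), "span")
})

test_that("noisy declining slopes are recovered within 0.05", {
  ds <- generate_dynamic(10000, noise_sd = 0.15, seed = 31)
  tr <- attr(ds, "truth")
  b <- make_bins(ds, 50)
  sl <- triplet_slopes(b, "leaf", "stem")
  sm <- smooth_slopes(sl, b$table$med_log_total, family = "symmetric")
  truth <- approx(tr$curve$log10_total, tr$curve$b,
                  xout = b$table$med_log_total, rule = 2)$y
  expect_lt(max(abs(sm - truth)[5:46]), 0.05)
})

test_that("noiseless isometric bootstrap band collapses onto 1.0", {
  ds <- generate_fixed(400, b_leaf_stem = 1, a_leaf_stem = 1,
                       b_stem_root = 1, noise_sd = 0, seed = 5)
  sc <- bootstrap_slope_curve(ds, "leaf", "stem", n_boot = 150, seed = 6)
  expect_lt(max(sc$hi - sc$lo), 1e-9)
  expect_lt(max(abs(sc$slope - 1)), 1e-9)
})

test_that("flat-world band contains the true exponent (3-seed average)", {
  # pointwise bands are a few thousandths wide mid-range, so a single
  # draw can graze the bound; the averaged covered fraction is stable
  covs <- vapply(1:3, function(s) {
    ds <- generate_fixed(3000, noise_sd = 0.15, seed = s)
    sc <- bootstrap_slope_curve(ds, "leaf", "stem", n_boot = 200,
                                seed = s + 10)
    mean(sc$lo <= 0.75 & 0.75 <= sc$hi)
  }, numeric(1))
  expect_gte(mean(covs), 0.9)
})

test_that("flat-world curve stays within two band half-widths of truth", {
  ds <- generate_fixed(3000, noise_sd = 0.15, seed = 21)
  sc <- bootstrap_slope_curve(ds, "leaf", "stem", n_boot = 200, seed = 22)
  expect_true(all(abs(sc$slope - 0.75) <= (sc$hi - sc$lo)))
})

test_that("bootstrap curve is invariant to mass units and record order", {
  ds <- generate_fixed(600, noise_sd = 0.15, seed = 13)
  sc1 <- bootstrap_slope_curve(ds, "leaf", "stem", n_boot = 150, seed = 2)
  # unit rescaling shifts the grid, not the slopes
  df <- as.data.frame(ds)
  for (m in c("leaf_mass_g", "stem_mass_g", "root_mass_g")) {
    df[[m]] <- df[[m]] * 1000
  }
  sc2 <- bootstrap_slope_curve(biomass_data(df), "leaf", "stem",
                               n_boot = 150, seed = 2)
  expect_equal(sc2$slope, sc1$slope, tolerance = 1e-9)
  expect_equal(sc2$grid, sc1$grid + 3, tolerance = 1e-9)

  # stratified scheme: shuffling records leaves the curve unchanged
  sc3 <- bootstrap_slope_curve(ds, "leaf", "stem", n_boot = 150, seed = 2,
                               resample = "within_bins")
  set.seed(99)
  shuffled <- biomass_data(as.data.frame(ds)[sample(nrow(ds)), ])
  sc4 <- bootstrap_slope_curve(shuffled, "leaf", "stem", n_boot = 150,
                               seed = 2, resample = "within_bins")
  expect_equal(sc4$slope, sc3$slope, tolerance = 1e-12)
  expect_equal(sc4$lo, sc3$lo, tolerance = 1e-12)
})

test_that("n_boot below 100 warns about the band", {
  ds <- generate_fixed(300, seed = 1)
  expect_warning(bootstrap_slope_curve(ds, n_boot = 50, seed = 1),
                 "unreliable")
})

test_that("polynomial derivative slopes are the analytic derivative", {
  fit2 <- structure(list(degree = 2, b1 = 1.2, b2 = -0.025, b3 = NULL),
                    class = "poly_fit")
  expect_equal(polynomial_derivative_slope(fit2, c(0, 8)), c(1.2, 0.8))
  fit1 <- structure(list(degree = 1, b1 = 0.9, b2 = NULL, b3 = NULL),
                    class = "poly_fit")
  expect_equal(polynomial_derivative_slope(fit1, -2:2), rep(0.9, 5))
})

test_that("derivative- and triplet-based curves agree on smooth data", {
  ds <- generate_dynamic(8000, noise_sd = 0.05, seed = 17)
  b <- make_bins(ds, 50)
  sl <- smooth_slopes(triplet_slopes(b, "leaf", "stem"),
                      b$table$med_log_total, family = "symmetric")
  pair <- allometric_pair(ds, "leaf", "stem")
  pfit <- fit_polynomial(pair, max_degree = 2)[[2]]
  deriv <- polynomial_derivative_slope(pfit, b$table$med_log_stem)
  expect_lt(max(abs(sl - deriv)[5:46]), 0.05)
})
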