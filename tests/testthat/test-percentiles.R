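# Build a percentile_table-shaped object directly (bypassing the
# generators) for oracle tests of the summary operations.
fake_pt <- function(p_lmf, species, family = "famX", bin = 1L) {
  n <- length(p_lmf)
  structure(data.frame(record_id = sprintf("r%04d", seq_len(n)),
                       species = species, family = family,
                       group_labels = "", bin = bin,
                       lmf = p_lmf / 100, smf = 0.5, rmf = 0.5,
                       p_lmf = p_lmf, p_smf = p_lmf, p_rmf = p_lmf,
                       singleton_bin = FALSE, stringsAsFactors = FALSE),
            class = c("percentile_table", "data.frame"))
}

test_that("midrank percentiles match hand computations incl. ties", {
  df <- data.frame(species = "s", leaf_mass_g = c(5, 1, 3, 2, 4),
                   stem_mass_g = 10, root_mass_g = 10 - c(5, 1, 3, 2, 4))
  ds <- biomass_data(df)  # identical totals -> one bin
  pt <- percentile_ranks(ds, make_bins(ds, 1))
  expect_equal(sort(pt$p_lmf), c(10, 30, 50, 70, 90))
  expect_equal(pt$p_lmf[3], 50)  # middle value

  # two tied among four: ranks 2,3 -> (2.5 - 0.5)/4 * 100 = 50
  df2 <- data.frame(species = "s", leaf_mass_g = c(1, 2, 2, 3),
                    stem_mass_g = 10, root_mass_g = 10 - c(1, 2, 2, 3))
  ds2 <- biomass_data(df2)
  pt2 <- percentile_ranks(ds2, make_bins(ds2, 1))
  expect_equal(pt2$p_lmf, c(12.5, 50, 50, 87.5))
})

test_that("within-bin percentile mean is exactly 50 and ranks are uniform", {
  ds <- generate_fraction_trajectory(10000, seed = 19)
  pt <- percentile_ranks(ds, make_bins(ds, 50))
  means <- tapply(pt$p_lmf, pt$bin, mean)
  expect_lt(max(abs(means - 50)), 1e-12)
  # pooled percentiles are uniform on (0, 100)
  ks <- max(abs(sort(pt$p_lmf) / 100 - (seq_len(nrow(pt)) - 0.5) / nrow(pt)))
  expect_lt(ks, 0.02)
})

test_that("percentiles are invariant under monotone transformation", {
  ds <- generate_fraction_trajectory(1000, seed = 23)
  binning <- make_bins(ds, 20)
  pt <- percentile_ranks(ds, binning)
  # cube the leaf masses (monotone on fractions within a bin? no --
  # transform the fractions themselves via a monotone map of lmf)
  df <- as.data.frame(ds)
  tot <- total_mass(ds)
  lmf <- df$leaf_mass_g / tot
  new_lmf <- plogis(qlogis(lmf) * 2 + 1)      # strictly increasing map
  scale_rest <- (1 - new_lmf) / (1 - lmf)
  df$leaf_mass_g <- new_lmf * tot
  df$stem_mass_g <- df$stem_mass_g * scale_rest
  df$root_mass_g <- df$root_mass_g * scale_rest
  ds2 <- biomass_data(df)
  pt2 <- percentile_ranks(ds2, make_bins(ds2, 20))
  expect_equal(pt2$p_lmf, pt$p_lmf, tolerance = 1e-12)
})

test_that("singleton bins yield percentile 50 with a flag", {
  df <- data.frame(species = "s", leaf_mass_g = c(1, 2, 4),
                   stem_mass_g = c(1, 2, 4), root_mass_g = c(1, 2, 4))
  ds <- biomass_data(df)
  pt <- percentile_ranks(ds, make_bins(ds, 3))
  expect_equal(pt$p_lmf, rep(50, 3))
  expect_true(all(pt$singleton_bin))
})

test_that("species summaries reproduce the t-test oracles", {
  pt <- fake_pt(c(50, 50, 50, 50, 80, 85, 90, 95),
                rep(c("flat", "high"), each = 4))
  ss <- species_summaries(pt, min_records = 4)
  flat <- ss[ss$species == "flat", ]
  expect_equal(flat$median_p_lmf, 50)
  expect_true(is.na(flat$pval_p_lmf))       # zero variance
  high <- ss[ss$species == "high", ]
  expect_equal(high$median_p_lmf, 87.5)
  # frozen one-sample t-test oracle: t = 37.5 / (6.455/2) = 11.62
  expect_equal(high$t_p_lmf, 11.6190, tolerance = 1e-4)
  expect_lt(high$pval_p_lmf, 0.05)

  # min_records excludes sparse species
  pt2 <- fake_pt(c(10, 20, 30, 40, 60), c(rep("a", 4), "b"))
  expect_equal(species_summaries(pt2, min_records = 4)$species, "a")
  expect_equal(nrow(species_summaries(pt2, min_records = 1)), 2L)
})

test_that("family summaries aggregate species medians with both modes", {
  p <- c(40, 40, 40, 40, 45, 45, 45, 45, 55, 55, 55, 55, 60, 60, 60, 60)
  pt <- fake_pt(p, rep(paste0("sp", 1:4), each = 4), family = "famZ")
  fam <- family_summaries(pt, mode = "min4")
  expect_equal(fam$median_p_lmf, 50)       # symmetric -> median 50
  expect_gt(fam$pval_p_lmf, 0.1)
  expect_equal(fam$stars_p_lmf, "ns")
  # min1 mode admits singleton-record species
  pt3 <- fake_pt(c(p, 70), c(rep(paste0("sp", 1:4), each = 4), "sp5"),
                 family = "famZ")
  expect_equal(family_summaries(pt3, mode = "min1")$n_species, 5L)
  expect_error(family_summaries(fake_pt(c(1, 2, 3, 4, 5) * 10,
                                        rep("solo", 5))),
               "no family")
})

test_that("null-world family medians sit within 50 +/- 5", {
  ds <- generate_fraction_trajectory(8000, family_sd = 0, species_sd = 0,
                                     record_sd = 0.3,
                                     n_species = 200, n_families = 10,
                                     seed = 37)
  pt <- percentile_ranks(ds, make_bins(ds, 50))
  fam <- family_summaries(pt, mode = "min4")
  expect_equal(nrow(fam), 10L)
  expect_true(all(abs(fam$median_p_lmf - 50) <= 5))
})

test_that("variance partition recovers known components", {
  # constructed world: species offsets vs residual with equal variance
  set.seed(55)
  n_sp <- 100; per <- 100
  sp <- rep(sprintf("sp%03d", 1:n_sp), each = per)
  p <- rep(rnorm(n_sp, 0, 1), each = per) + rnorm(n_sp * per, 0, 1)
  pt <- fake_pt(50 + 10 * p, sp)
  vp <- variance_partition(pt)
  expect_equal(vp$species + vp$family + vp$residual, 1, tolerance = 1e-12)
  expect_equal(vp$species, 0.5, tolerance = 0.05)
  expect_equal(vp$family, 0, tolerance = 1e-12)  # single family

  expect_error(variance_partition(fake_pt(c(10, 20), c("a", "a"))),
               "single species")

  # generator world: species share exceeds family share, both positive
  ds <- generate_fraction_trajectory(6000, n_species = 300,
                                     n_families = 30, seed = 44)
  ptg <- percentile_ranks(ds, make_bins(ds, 50))
  vg <- variance_partition(ptg)
  expect_gt(vg$species, vg$family)
  expect_gt(vg$family, 0.05)
})

test_that("group contrasts detect a planted shift and stay null otherwise", {
  offs <- c(evergreen = 15, deciduous = 0)
  ds <- generate_fraction_trajectory(
    2000, group_offsets = offs, family_sd = 0, species_sd = 0,
    record_sd = 0.25, smf_record_sd = 0, rmf_record_sd = 0,
    n_species = 100, n_families = 10, seed = 61)
  pt <- percentile_ranks(ds, make_bins(ds, 50))
  ss <- species_summaries(pt, min_records = 4)
  gm <- species_groups(ds, c("evergreen", "deciduous"))
  res <- group_contrast(ss, gm, groups = c("evergreen", "deciduous"))
  expect_lt(res$p.value, 0.001)
  expect_equal(res$stars, "***")
  expect_gt(res$means[["evergreen"]], res$means[["deciduous"]])

  # identical groups: p-value behaves like a null draw across seeds
  ns_frac <- mean(vapply(1:30, function(s) {
    ds0 <- generate_fraction_trajectory(
      600, group_offsets = c(evergreen = 0, deciduous = 0),
      family_sd = 0, species_sd = 0, record_sd = 0.25,
      n_species = 60, n_families = 6, seed = 100 + s)
    pt0 <- percentile_ranks(ds0, make_bins(ds0, 20))
    ss0 <- species_summaries(pt0, min_records = 4)
    gm0 <- species_groups(ds0, c("evergreen", "deciduous"))
    group_contrast(ss0, gm0)$stars == "ns"
  }, logical(1)))
  expect_gte(ns_frac, 0.75)

  expect_error(group_contrast(ss, gm, groups = c("evergreen", "C3")),
               "fewer than 2")
})

test_that("species detection power exceeds 0.8 at 6 records per species", {
  # species-dominated variance: a species' six records cluster tightly in
  # percentile space, so deviating (shifted-group) species are detectable
  ds <- generate_fraction_trajectory(
    3000, group_offsets = c(evergreen = 15, deciduous = 0),
    family_sd = 0, species_sd = 0.3, record_sd = 0.04,
    smf_record_sd = 0, rmf_record_sd = 0,
    n_species = 500, n_families = 10, seed = 71)
  pt <- percentile_ranks(ds, make_bins(ds, 50))
  ss <- species_summaries(pt, min_records = 4)  # 6 records per species
  gm <- species_groups(ds, c("evergreen", "deciduous"))
  m <- merge(as.data.frame(ss), gm, by = "species")
  shifted <- m[m$group == "evergreen", ]
  power <- mean(shifted$pval_p_lmf < 0.05, na.rm = TRUE)
  expect_gt(power, 0.8)
})

test_that("significance stars bin p-values at the conventional cuts", {
  expect_equal(significance_stars(c(0.2, 0.07, 0.03, 0.005, 5e-4, NA)),
               c("ns", "+", "*", "**", "***", NA))
})
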