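# Shared builders for test worlds. Everything is generated in code at test
# time; no fixture files.

# Minimal hand-built data set: masses chosen so totals and fractions are
# easy to verify by eye.
toy_biomass <- function() {
  biomass_data(data.frame(
    record_id = c("a", "b", "c"),
    species = c("sp1", "sp1", "sp2"),
    family = c("famA", "famA", "famB"),
    leaf_mass_g = c(1, 10, 0.5),
    stem_mass_g = c(2, 20, 0.1),
    root_mass_g = c(3, 30, 0.4),
    stringsAsFactors = FALSE))
}

# Write a biomass data frame as a raw CSV the reader should accept.
write_raw_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

# Independent oracle for the family-median percentile recovery world:
# simulates the latent ranking hierarchy directly (no package code).
# Species sit wholly inside one size class; each class holds sp_per_bin
# species of rec_per_sp records; families collect species cycling across
# classes; groups cycle g/e/none across families. Returns the mean over
# families of the family-median pLMF per group.
oracle_family_medians <- function(seed, offsets_pct, fsd, ssd, rsd,
                                  n_bins = 50, sp_per_bin = 24,
                                  rec_per_sp = 10, n_fam = 60) {
  set.seed(seed)
  n_sp <- n_bins * sp_per_bin
  fam_of_sp <- ((seq_len(n_sp) - 1L) %% n_fam) + 1L
  grp_of_fam <- rep(c(names(offsets_pct), "none"), length.out = n_fam)
  st <- sqrt(fsd^2 + ssd^2 + rsd^2)
  delta <- c(stats::qnorm(0.5 + offsets_pct / 100) * st, none = 0)
  sp_lat <- stats::rnorm(n_fam, 0, fsd)[fam_of_sp] +
    stats::rnorm(n_sp, 0, ssd) + delta[grp_of_fam[fam_of_sp]]
  bin_of_sp <- rep(seq_len(n_bins), each = sp_per_bin)
  sp_med <- numeric(n_sp)
  for (b in seq_len(n_bins)) {
    sps <- which(bin_of_sp == b)
    z <- rep(sp_lat[sps], each = rec_per_sp) +
      stats::rnorm(length(sps) * rec_per_sp, 0, rsd)
    p <- (rank(z) - 0.5) / length(z) * 100
    sp_med[sps] <- tapply(p, rep(seq_along(sps), each = rec_per_sp),
                          stats::median)
  }
  fam_med <- tapply(sp_med, fam_of_sp, stats::median)
  tapply(fam_med, grp_of_fam, mean)
}

# The matching package-side world: group labels assigned per family,
# cycling across families so every size class holds a balanced mixture.
family_recovery_world <- function(seed, offsets_pct, fsd, ssd, rsd,
                                  n_rec = 12000, n_sp = 1200, n_fam = 60) {
  grp_of_fam <- rep(c(names(offsets_pct), ""), length.out = n_fam)
  fam_of_sp <- ((seq_len(n_sp) - 1L) %% n_fam) + 1L
  ds <- generate_fraction_trajectory(
    n_rec, group_offsets = offsets_pct,
    group_assignment = grp_of_fam[fam_of_sp],
    family_sd = fsd, species_sd = ssd, record_sd = rsd,
    smf_record_sd = 0, rmf_record_sd = 0,
    n_species = n_sp, n_families = n_fam, seed = seed)
  pt <- percentile_ranks(ds, make_bins(ds, 50))
  fam <- family_summaries(pt, mode = "min4")
  g <- grp_of_fam[as.integer(sub("fam", "", fam$family))]
  g[g == ""] <- "none"
  tapply(fam$median_p_lmf, g, mean)
}
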