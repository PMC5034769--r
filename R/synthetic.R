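# Seeded generators emulating the statistical structure of a global
# leaf/stem/root biomass compilation: total dry mass spanning ten or more
# orders of magnitude, multiplicative lognormal noise on organ masses,
# species that are harvest series occupying narrow size windows, and
# family / functional-group structure in the biomass fractions.

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

.cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

# Contiguous-by-size species labels: each synthetic species is a harvest
# series spanning a narrow size window; species are cycled through families.
.synth_labels <- function(n, n_species, n_families) {
  n_species <- max(1L, min(n_species, n))
  n_families <- max(1L, min(n_families, n_species))
  sizes <- rep(n %/% n_species, n_species)
  extra <- n %% n_species
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sp_idx <- rep.int(seq_len(n_species), sizes)
  fam_idx <- ((seq_len(n_species) - 1L) %% n_families) + 1L
  list(species = sprintf("sp%04d", sp_idx),
       family = sprintf("fam%03d", fam_idx[sp_idx]),
       species_index = sp_idx,
       family_of_species = fam_idx)
}

.check_range <- function(log10_mass_range, n) {
  stopifnot(length(log10_mass_range) == 2L, all(is.finite(log10_mass_range)))
  if (log10_mass_range[1] >= log10_mass_range[2] && n > 1L) {
    stop("degenerate log10_mass_range (lo >= hi) with n_records > 1: ",
         "no size variation to analyse")
  }
}

#' Generate data under fixed-exponent power laws (MST1-style world)
#'
#' Organ masses follow `Y = a X^b` with constant exponents: the world in
#' which metabolic scaling theory's fixed 3/4, 3/4, 1.0 exponents hold. A
#' latent log10 stem size is drawn log-uniformly over the range and each
#' observed log10 organ mass scatters around its power-law value
#' (multiplicative lognormal noise on the mass scale). The scatter is split
#' across the two axes of each fitted pair with error-sd ratio equal to the
#' slope, the error structure under which standardized major axis regression
#' is the appropriate estimator of `b`.
#'
#' With `noise_sd = 0` every record satisfies the power laws exactly.
#'
#' @param n_records number of records.
#' @param log10_mass_range range of latent log10 stem mass, log10 g.
#' @param b_leaf_stem,b_stem_root scaling exponents (> 0): leaf = a_ls *
#'   stem^b_ls; stem = a_sr * root^b_sr.
#' @param a_leaf_stem,a_stem_root allometric constants (natural scale).
#'   Defaults give log10 intercepts of about 0.11 and -0.06, realistic for
#'   global leaf/stem/root compilations.
#' @param noise_sd sd of Gaussian noise on log10 organ mass.
#' @param n_species,n_families synthetic taxonomy sizes.
#' @param seed integer seed; all randomness flows from it.
#' @return `biomass_data`; attribute `"truth"` records the generating
#'   parameters.
#' @export
generate_fixed <- function(n_records, log10_mass_range = c(-3, 7),
                           b_leaf_stem = 0.75, b_stem_root = 1.0,
                           a_leaf_stem = 1.30, a_stem_root = 0.875,
                           noise_sd = 0.15, n_species = 100,
                           n_families = 20, seed) {
  stopifnot(n_records >= 1, b_leaf_stem > 0, b_stem_root > 0,
            a_leaf_stem > 0, a_stem_root > 0, noise_sd >= 0)
  .check_range(log10_mass_range, n_records)
  set.seed(as.integer(seed))
  u <- sort(stats::runif(n_records, log10_mass_range[1], log10_mass_range[2]))
  log_stem <- u + stats::rnorm(n_records, 0, noise_sd)
  log_leaf <- log10(a_leaf_stem) + b_leaf_stem * u +
    stats::rnorm(n_records, 0, b_leaf_stem * noise_sd)
  log_root <- (u - log10(a_stem_root)) / b_stem_root +
    stats::rnorm(n_records, 0, noise_sd / b_stem_root)
  lab <- .synth_labels(n_records, n_species, n_families)
  ds <- biomass_data(data.frame(
    species = lab$species, family = lab$family,
    leaf_mass_g = 10^log_leaf, stem_mass_g = 10^log_stem,
    root_mass_g = 10^log_root, stringsAsFactors = FALSE),
    provenance = "synthetic: fixed-exponent power laws")
  attr(ds, "truth") <- list(regime = "fixed", b_leaf_stem = b_leaf_stem,
                            b_stem_root = b_stem_root,
                            a_leaf_stem = a_leaf_stem,
                            a_stem_root = a_stem_root,
                            noise_sd = noise_sd, seed = seed)
  ds
}

#' Generate data with a smoothly size-varying scaling exponent
#'
#' The local leaf-vs-stem exponent `b` is a supplied function of log10 stem
#' mass, given as control points joined by monotone piecewise-cubic
#' interpolation; log10 leaf mass is the integral of `b` over log10 stem
#' mass, so `d log10(leaf) / d log10(stem)` equals `b` exactly in the
#' noiseless limit. Roots scale isometrically with stems so total mass is a
#' monotone map of the latent size. A constant `b` reduces to
#' [generate_fixed()].
#'
#' @param n_records number of records.
#' @param log10_mass_range latent log10 stem range, log10 g.
#' @param b_control data frame with columns `logm` (log10 stem, g) and `b`
#'   (> 0): control points of the exponent function. Default declines
#'   linearly from 1.0 to 0.6 over the range, the pattern reported for leaf
#'   scaling from seedlings to the largest trees.
#' @param noise_sd sd of Gaussian noise on log10 organ mass.
#' @param n_species,n_families synthetic taxonomy sizes.
#' @param seed integer seed.
#' @return `biomass_data`; attribute `"truth"` holds the exponent function
#'   (`b_fun`, of log10 stem) and `curve`, a fine grid of
#'   (`log10_total`, `b`) pairs for comparison with estimated slope curves.
#' @export
generate_dynamic <- function(n_records, log10_mass_range = c(-3, 7),
                             b_control = data.frame(
                               logm = log10_mass_range, b = c(1.0, 0.6)),
                             noise_sd = 0.15, n_species = 100,
                             n_families = 20, seed) {
  stopifnot(n_records >= 1, noise_sd >= 0, nrow(b_control) >= 2,
            all(b_control$b > 0))
  .check_range(log10_mass_range, n_records)
  lo <- log10_mass_range[1]; hi <- log10_mass_range[2]
  b_fun <- stats::splinefun(b_control$logm, b_control$b, method = "monoH.FC")
  grid <- seq(lo, hi, length.out = 4001L)
  bg <- b_fun(grid)
  if (any(!is.finite(bg)) || any(bg <= 0)) {
    stop("exponent function must be finite and > 0 over the range")
  }
  cum <- .cumtrapz(grid, bg)
  if (any(!is.finite(cum))) stop("non-finite integral of exponent function")
  # leaf equals stem at the small end: small plants are near-isometric
  leaf_fun <- stats::splinefun(grid, lo + cum, method = "natural")
  set.seed(as.integer(seed))
  u <- sort(stats::runif(n_records, lo, hi))
  bu <- b_fun(u)
  log_stem <- u + stats::rnorm(n_records, 0, noise_sd)
  log_leaf <- leaf_fun(u) + stats::rnorm(n_records, 0, bu * noise_sd)
  log_root <- u + stats::rnorm(n_records, 0, noise_sd)
  lab <- .synth_labels(n_records, n_species, n_families)
  ds <- biomass_data(data.frame(
    species = lab$species, family = lab$family,
    leaf_mass_g = 10^log_leaf, stem_mass_g = 10^log_stem,
    root_mass_g = 10^log_root, stringsAsFactors = FALSE),
    provenance = "synthetic: size-varying exponent")
  log_total <- log10(10^grid + 10^leaf_fun(grid) + 10^grid)
  attr(ds, "truth") <- list(regime = "dynamic", b_fun = b_fun,
                            leaf_fun = leaf_fun, noise_sd = noise_sd,
                            seed = seed,
                            curve = data.frame(log10_total = log_total,
                                               b = bg))
  ds
}

#' Control points for breakpoint (MST2-style) scaling
#'
#' Convenience for [generate_dynamic()]: an exponent that is `b_before`
#' below the transition size and `b_after` above it, switching over
#' `width` log10 units (monotone cubic interpolation cannot represent a
#' true discontinuity; a narrow ramp stands in for it).
#'
#' @param transition log10 total/stem mass of the breakpoint (the
#'   proposed transition points range from about 1 g to 64 g).
#' @param b_before,b_after exponents on either side (MST2: 1.0 then 0.75).
#' @param width ramp width in log10 units.
#' @param log10_mass_range range the points must cover.
#' @return data frame `logm`, `b` usable as `b_control`.
#' @export
breakpoint_control_points <- function(transition = log10(64),
                                      b_before = 1, b_after = 0.75,
                                      width = 0.2,
                                      log10_mass_range = c(-3, 7)) {
  stopifnot(transition - width / 2 > log10_mass_range[1],
            transition + width / 2 < log10_mass_range[2])
  data.frame(logm = c(log10_mass_range[1], transition - width / 2,
                      transition + width / 2, log10_mass_range[2]),
             b = c(b_before, b_before, b_after, b_after))
}

# Default mass-fraction target trajectories: LMF declining from ~0.50 in
# seedlings to ~0.015 in the largest trees, SMF rising from ~0.20 to ~0.78,
# RMF (the remainder) near 0.30 up to ~100 g then easing to ~0.20.
default_lmf_points <- function() {
  data.frame(logm = c(-3, 0, 2, 5, 7), value = c(0.50, 0.40, 0.30, 0.05, 0.015))
}
default_smf_points <- function() {
  data.frame(logm = c(-3, 0, 2, 5, 7), value = c(0.20, 0.30, 0.40, 0.70, 0.78))
}

#' Generate data with prescribed biomass-fraction trajectories
#'
#' Total dry mass is log-uniform over the range; target leaf and stem mass
#' fractions are smooth functions of log10 total mass (monotone cubic
#' through control points), with the root fraction as the remainder.
#' Per-record fractions are the targets perturbed on the logit scale and
#' renormalized to sum to one; organ masses are fraction times total, so
#' fractions are exact by construction.
#'
#' The logit perturbation of LMF decomposes into family, species and record
#' components (`family_sd`, `species_sd`, `record_sd`), defaults chosen so
#' the latent variance shares mirror the field observation that species
#' explain roughly 55% and families roughly 23% of size-corrected LMF
#' variation. `group_offsets` adds fixed percentile-scale shifts for
#' functional groups: a `+15` offset places that group's latent LMF at
#' about the 65th percentile of the overall distribution.
#'
#' @param n_records number of records.
#' @param log10_mass_range range of log10 total mass, log10 g.
#' @param lmf_points,smf_points control points (`logm`, `value`) of the
#'   target fraction trajectories; values in (0, 1), pairwise sum < 1.
#' @param family_sd,species_sd,record_sd logit-scale standard deviations of
#'   the LMF variance components. Set all but `record_sd` to 0 for a world
#'   with no taxonomic structure.
#' @param smf_record_sd,rmf_record_sd logit-scale record noise on the other
#'   two fractions.
#' @param group_offsets named numeric vector: group label -> LMF percentile
#'   shift (points). Labels must come from [GROUP_VOCABULARY].
#' @param group_assignment optional character vector (length `n_species`)
#'   assigning each synthetic species a group label (`""` = none). Default:
#'   species cycle round-robin through `names(group_offsets)`.
#' @param n_species,n_families synthetic taxonomy sizes.
#' @param seed integer seed.
#' @return `biomass_data`; attribute `"truth"` holds the target functions,
#'   variance components and per-species latent offsets.
#' @export
generate_fraction_trajectory <- function(n_records,
                                         log10_mass_range = c(-3, 7),
                                         lmf_points = default_lmf_points(),
                                         smf_points = default_smf_points(),
                                         family_sd = 0.24,
                                         species_sd = 0.37,
                                         record_sd = 0.23,
                                         smf_record_sd = record_sd,
                                         rmf_record_sd = record_sd,
                                         group_offsets = NULL,
                                         group_assignment = NULL,
                                         n_species = 100, n_families = 20,
                                         seed) {
  stopifnot(n_records >= 1, family_sd >= 0, species_sd >= 0, record_sd >= 0)
  .check_range(log10_mass_range, n_records)
  lfun <- stats::splinefun(lmf_points$logm, lmf_points$value,
                           method = "monoH.FC")
  sfun <- stats::splinefun(smf_points$logm, smf_points$value,
                           method = "monoH.FC")
  eval_grid <- seq(log10_mass_range[1], log10_mass_range[2],
                   length.out = 513L)
  lg <- lfun(eval_grid); sg <- sfun(eval_grid)
  if (any(lg <= 0 | lg >= 1) || any(sg <= 0 | sg >= 1) ||
      any(lg + sg >= 1)) {
    stop("target fraction curves must lie in (0,1) with pairwise sum < 1 ",
         "everywhere on the evaluation grid")
  }
  set.seed(as.integer(seed))
  log_total <- sort(stats::runif(n_records, log10_mass_range[1],
                                 log10_mass_range[2]))
  lab <- .synth_labels(n_records, n_species, n_families)
  n_sp <- max(lab$species_index)
  n_fam <- max(lab$family_of_species)
  fam_eff <- stats::rnorm(n_fam, 0, family_sd)
  sp_eff <- stats::rnorm(n_sp, 0, species_sd)
  sigma_total <- sqrt(family_sd^2 + species_sd^2 + record_sd^2)
  sp_group <- rep("", n_sp)
  sp_delta <- rep(0, n_sp)
  if (!is.null(group_offsets)) {
    gnames <- names(group_offsets)
    unknown <- setdiff(gnames, GROUP_VOCABULARY)
    if (length(unknown)) stop("unknown group label(s): ",
                              paste(unknown, collapse = ", "))
    if (is.null(group_assignment)) {
      group_assignment <- gnames[((seq_len(n_sp) - 1L) %% length(gnames)) + 1L]
    }
    stopifnot(length(group_assignment) == n_sp)
    sp_group <- group_assignment
    has <- sp_group %in% gnames
    # percentile shift -> latent logit shift relative to the overall spread
    sp_delta[has] <- stats::qnorm(pmin(pmax(
      0.5 + group_offsets[sp_group[has]] / 100, 0.01), 0.99)) *
      max(sigma_total, .Machine$double.eps)
  }
  lmf0 <- lfun(log_total); smf0 <- sfun(log_total)
  rmf0 <- 1 - lmf0 - smf0
  sp_idx <- lab$species_index
  fam_idx <- lab$family_of_species[sp_idx]
  l_lat <- .logit(lmf0) + fam_eff[fam_idx] + sp_eff[sp_idx] +
    sp_delta[sp_idx] + stats::rnorm(n_records, 0, record_sd)
  s_lat <- .logit(smf0) + stats::rnorm(n_records, 0, smf_record_sd)
  r_lat <- .logit(rmf0) + stats::rnorm(n_records, 0, rmf_record_sd)
  f <- cbind(.inv_logit(l_lat), .inv_logit(s_lat), .inv_logit(r_lat))
  f <- f / rowSums(f)
  total <- 10^log_total
  ds <- biomass_data(data.frame(
    species = lab$species, family = lab$family,
    group_labels = sp_group[sp_idx],
    leaf_mass_g = f[, 1] * total, stem_mass_g = f[, 2] * total,
    root_mass_g = f[, 3] * total, stringsAsFactors = FALSE),
    provenance = "synthetic: fraction trajectories")
  attr(ds, "truth") <- list(regime = "fraction_trajectory",
                            lmf_fun = lfun, smf_fun = sfun,
                            family_sd = family_sd, species_sd = species_sd,
                            record_sd = record_sd,
                            group_offsets = group_offsets,
                            species_group = sp_group,
                            species_delta = sp_delta,
                            sigma_total = sigma_total, seed = seed)
  ds
}

#' Generate a shoot/root table with bounded random root fractions
#'
#' The setting of the r-squared inflation demonstration: total mass
#' log-uniform over the range, root mass fraction uniform on `rmf_range`,
#' root = RMF x total and shoot = (1 - RMF) x total. Even with RMF spanning
#' nearly (0, 1) — shoot:root ratios anywhere from 0.01 to 99 — log shoot
#' and log root remain almost perfectly correlated once the size range is
#' wide.
#'
#' @param n number of records (>= 3).
#' @param log10_mass_range range of log10 total mass, log10 g.
#' @param rmf_range bounds of the uniform RMF draw, inside (0, 1).
#' @param seed integer seed.
#' @return data frame with `record_id`, `total_mass_g`, `rmf`,
#'   `root_mass_g`, `shoot_mass_g`.
#' @export
generate_rmf_uniform <- function(n, log10_mass_range = c(-3, 7),
                                 rmf_range = c(0.01, 0.99), seed) {
  stopifnot(n >= 3, length(rmf_range) == 2L,
            rmf_range[1] > 0, rmf_range[2] < 1,
            rmf_range[1] <= rmf_range[2])
  .check_range(log10_mass_range, n)
  set.seed(as.integer(seed))
  total <- 10^stats::runif(n, log10_mass_range[1], log10_mass_range[2])
  rmf <- stats::runif(n, rmf_range[1], rmf_range[2])
  root <- rmf * total
  shoot <- total - root
  # store the rounded sum so shoot + root == total holds to the last bit
  data.frame(record_id = sprintf("r%06d", seq_len(n)),
             total_mass_g = shoot + root, rmf = rmf,
             root_mass_g = root, shoot_mass_g = shoot,
             stringsAsFactors = FALSE)
}

#' Synthetic-world configuration
#'
#' Serializable bundle of generator settings; [generate_dataset()]
#' dispatches on `regime`.
#'
#' @param regime one of `"fixed"`, `"breakpoint"`, `"dynamic"`,
#'   `"fraction_trajectory"`, `"rmf_uniform"`. `"breakpoint"` is the
#'   dynamic regime with [breakpoint_control_points()].
#' @param n_records,log10_mass_range,noise_sd,n_species,n_families,seed see
#'   the individual generators.
#' @param ... regime-specific parameters passed through.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(regime = c("fixed", "breakpoint", "dynamic",
                                    "fraction_trajectory", "rmf_uniform"),
                         n_records = 5000, log10_mass_range = c(-3, 7),
                         noise_sd = 0.15, n_species = 100, n_families = 20,
                         seed = 1L, ...) {
  regime <- match.arg(regime)
  structure(list(regime = regime, n_records = n_records,
                 log10_mass_range = log10_mass_range, noise_sd = noise_sd,
                 n_species = n_species, n_families = n_families,
                 seed = seed, extra = list(...)),
            class = "synth_config")
}

#' Generate a data set from a configuration
#'
#' @param cfg a [synth_config()].
#' @return `biomass_data` (or the shoot/root table for `"rmf_uniform"`).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  common <- list(log10_mass_range = cfg$log10_mass_range, seed = cfg$seed)
  if (cfg$regime == "breakpoint" && is.null(cfg$extra$b_control)) {
    cfg$extra$b_control <- breakpoint_control_points(
      log10_mass_range = cfg$log10_mass_range)
  }
  switch(cfg$regime,
    fixed = do.call(generate_fixed, c(list(
      n_records = cfg$n_records, noise_sd = cfg$noise_sd,
      n_species = cfg$n_species, n_families = cfg$n_families),
      common, cfg$extra)),
    breakpoint = ,
    dynamic = do.call(generate_dynamic, c(list(
      n_records = cfg$n_records, noise_sd = cfg$noise_sd,
      n_species = cfg$n_species, n_families = cfg$n_families),
      common, cfg$extra)),
    fraction_trajectory = do.call(generate_fraction_trajectory, c(list(
      n_records = cfg$n_records, n_species = cfg$n_species,
      n_families = cfg$n_families), common, cfg$extra)),
    rmf_uniform = do.call(generate_rmf_uniform, c(list(
      n = cfg$n_records), common, cfg$extra)))
}

#' Read/write a synthetic configuration as plain key=value text
#'
#' Only scalar and numeric-vector fields are serialized (vectors
#' comma-joined); regime-specific `extra` parameters must be scalars or
#' numeric vectors.
#'
#' @param cfg a [synth_config()].
#' @param path file path.
#' @return `path` (write) or `synth_config` (read).
#' @export
write_synth_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "synth_config"))
  flat <- c(cfg[setdiff(names(cfg), "extra")], cfg$extra)
  lines <- vapply(names(flat), function(k) {
    paste0(k, "=", paste(flat[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(p) {
      v <- strsplit(p[2], ",", fixed = TRUE)[[1]]
      num <- suppressWarnings(as.numeric(v))
      if (!anyNA(num)) num else v
    }),
    vapply(kv, `[`, character(1), 1))
  known <- c("regime", "n_records", "log10_mass_range", "noise_sd",
             "n_species", "n_families", "seed")
  extra <- vals[setdiff(names(vals), known)]
  do.call(synth_config, c(vals[intersect(known, names(vals))], extra))
}
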