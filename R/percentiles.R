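# Size-corrected percentile ranks: within each size class, each record's
# biomass fraction is replaced by its percentile among all records of that
# class. This removes the dominant size trend, so species, family and
# functional-group deviations can be compared across the whole size range.
# The midrank formula (rank - 0.5)/n * 100 makes the within-bin mean
# exactly 50 and avoids 0/100 extremes.

#' Percentile ranks of biomass fractions within size classes
#'
#' Within each bin and independently for LMF, SMF and RMF, the percentile
#' of record i is `(rank_i - 0.5) / n_bin * 100`, ties receiving average
#' ranks. A bin of size one yields percentile 50 and is flagged.
#'
#' @param ds `biomass_data`.
#' @param binning a [make_bins()] result built on `ds`.
#' @return data frame of class `percentile_table`: `record_id`, `species`,
#'   `family`, `group_labels`, `bin`, `lmf`/`smf`/`rmf` and
#'   `p_lmf`/`p_smf`/`p_rmf`, plus `singleton_bin`.
#' @export
percentile_ranks <- function(ds, binning) {
  stopifnot(inherits(binning, "size_binning"))
  if (length(binning$assignment) != nrow(ds)) {
    stop("binning was not built on this data set")
  }
  fr <- compute_fractions(ds)
  bin <- binning$assignment
  pct <- function(v) {
    out <- numeric(length(v))
    for (b in split(seq_along(v), bin)) {
      nb <- length(b)
      out[b] <- (rank(v[b], ties.method = "average") - 0.5) / nb * 100
    }
    out
  }
  sizes <- tabulate(bin, binning$n_bins)
  structure(data.frame(record_id = ds$record_id, species = ds$species,
                       family = ds$family, group_labels = ds$group_labels,
                       bin = bin, lmf = fr$lmf, smf = fr$smf, rmf = fr$rmf,
                       p_lmf = pct(fr$lmf), p_smf = pct(fr$smf),
                       p_rmf = pct(fr$rmf),
                       singleton_bin = sizes[bin] == 1L,
                       stringsAsFactors = FALSE),
            class = c("percentile_table", "data.frame"))
}

.t_vs_50 <- function(p) {
  if (length(p) < 2L || stats::sd(p) == 0) {
    return(c(statistic = NA_real_, p.value = NA_real_))
  }
  tt <- stats::t.test(p, mu = 50)
  c(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Species-level percentile summaries
#'
#' Per species, all its record percentiles are pooled across the size bins;
#' the summary is their median plus a two-sided one-sample t-test against
#' the overall median of 50. Species with fewer than `min_records` records
#' are excluded (`min_records = 1` keeps every species). A species with
#' zero variance in its percentiles gets `NA` test results.
#'
#' @param pt a [percentile_ranks()] table.
#' @param min_records minimum records per species (the reference analysis
#'   used 4 for its quality-weighted mode).
#' @return data frame of class `species_summary`: per species `n_records`,
#'   `family`, median and t-test columns for each of pLMF/pSMF/pRMF.
#' @export
species_summaries <- function(pt, min_records = 4) {
  stopifnot(inherits(pt, "percentile_table"))
  sp <- split(seq_len(nrow(pt)), pt$species)
  sp <- sp[vapply(sp, length, integer(1)) >= min_records]
  if (!length(sp)) stop("no species passes min_records = ", min_records)
  rows <- lapply(names(sp), function(s) {
    i <- sp[[s]]
    out <- data.frame(species = s,
                      family = pt$family[i[1]],
                      n_records = length(i),
                      stringsAsFactors = FALSE)
    for (fr in c("lmf", "smf", "rmf")) {
      p <- pt[[paste0("p_", fr)]][i]
      tt <- .t_vs_50(p)
      out[[paste0("median_p_", fr)]] <- stats::median(p)
      out[[paste0("t_p_", fr)]] <- tt[["statistic"]]
      out[[paste0("pval_p_", fr)]] <- tt[["p.value"]]
    }
    out
  })
  structure(do.call(rbind, rows),
            class = c("species_summary", "data.frame"))
}

#' Family-level percentile summaries
#'
#' Per family: the median over its species of the species-median
#' percentiles, with a t-test of the species medians against 50 (species
#' weighted equally). Two modes mirror the quality/quantity trade-off of
#' the reference analysis: `"min4"` requires at least 4 records per
#' species, `"min1"` admits every species. Families with fewer than
#' `min_species` qualifying species are excluded. Raw p-values are starred
#' (ns / + / * / ** / ***); a Holm-adjusted column is an added extension.
#'
#' @param pt a [percentile_ranks()] table.
#' @param mode `"min4"` or `"min1"`.
#' @param min_species minimum qualifying species per family.
#' @return data frame of class `family_summary`.
#' @export
family_summaries <- function(pt, mode = c("min4", "min1"),
                             min_species = 4) {
  mode <- match.arg(mode)
  ss <- species_summaries(pt, min_records = if (mode == "min4") 4 else 1)
  ss <- ss[ss$family != "", , drop = FALSE]
  fams <- split(seq_len(nrow(ss)), ss$family)
  fams <- fams[vapply(fams, length, integer(1)) >= min_species]
  if (!length(fams)) stop("no family has >= ", min_species,
                          " qualifying species in mode ", mode)
  rows <- lapply(names(fams), function(f) {
    i <- fams[[f]]
    out <- data.frame(family = f, n_species = length(i), mode = mode,
                      stringsAsFactors = FALSE)
    for (fr in c("lmf", "smf", "rmf")) {
      med <- ss[[paste0("median_p_", fr)]][i]
      tt <- .t_vs_50(med)
      out[[paste0("median_p_", fr)]] <- stats::median(med)
      out[[paste0("pval_p_", fr)]] <- tt[["p.value"]]
      out[[paste0("stars_p_", fr)]] <- significance_stars(tt[["p.value"]])
    }
    out
  })
  out <- do.call(rbind, rows)
  for (fr in c("lmf", "smf", "rmf")) {
    out[[paste0("pval_holm_p_", fr)]] <-
      stats::p.adjust(out[[paste0("pval_p_", fr)]], method = "holm")
  }
  structure(out[order(out$median_p_lmf), ],
            class = c("family_summary", "data.frame"))
}

#' Significance stars at the conventional thresholds
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `+` p < 0.10, else `ns`
#' (half-open intervals; `NA` p-values give `NA`).
#'
#' @param p numeric p-values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
    ifelse(p < 0.001, "***",
      ifelse(p < 0.01, "**",
        ifelse(p < 0.05, "*",
          ifelse(p < 0.10, "+", "ns")))))
}

#' Variance partitioning of percentile ranks over taxonomy
#'
#' Sequential (type I) sums of squares from the nested grouping, family
#' entered before species within family: proportions of total SS explained
#' by family, additionally by species, and residual.
#'
#' @param pt a [percentile_ranks()] table.
#' @param response `"p_lmf"`, `"p_smf"` or `"p_rmf"`.
#' @return list with `family`, `species`, `residual` proportions and `n`.
#' @export
variance_partition <- function(pt, response = "p_lmf") {
  stopifnot(inherits(pt, "percentile_table"),
            response %in% c("p_lmf", "p_smf", "p_rmf"))
  if (length(unique(pt$species)) < 2L) {
    stop("variance partition undefined with a single species")
  }
  df <- data.frame(y = pt[[response]],
                   family = factor(pt$family),
                   species = factor(pt$species))
  has_family <- nlevels(df$family) > 1L
  fml <- if (has_family) y ~ family + species else y ~ species
  an <- stats::anova(stats::lm(fml, data = df))
  ss <- an[["Sum Sq"]]
  total <- sum(ss)
  get_ss <- function(term) {
    i <- match(term, rownames(an))
    if (is.na(i)) 0 else ss[i]
  }
  list(family = get_ss("family") / total,
       species = get_ss("species") / total,
       residual = get_ss("Residuals") / total,
       n = nrow(df))
}

#' Map species to a functional-group label
#'
#' A species' group is the label from `labels` carried by its records
#' (majority vote when records disagree; `""` when none apply).
#'
#' @param ds `biomass_data`.
#' @param labels candidate labels (subset of [GROUP_VOCABULARY]).
#' @return data frame `species`, `group`.
#' @export
species_groups <- function(ds, labels) {
  parsed <- .parse_groups(ds$group_labels)
  rec_lab <- vapply(parsed, function(g) {
    hit <- intersect(labels, g)
    if (length(hit)) hit[1] else ""
  }, character(1))
  sp <- split(rec_lab, ds$species)
  data.frame(species = names(sp),
             group = vapply(sp, function(v) {
               tb <- sort(table(v), decreasing = TRUE)
               names(tb)[1]
             }, character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Contrast functional groups on species-median percentiles
#'
#' Welch's unequal-variance t-test between two groups of species (each
#' species contributes its median percentile), or Welch's one-way ANOVA
#' when more than two groups are compared. Significance is starred at the
#' conventional 0.10 / 0.05 / 0.01 / 0.001 thresholds.
#'
#' @param summaries a [species_summaries()] table.
#' @param group_map data frame `species`, `group` (see
#'   [species_groups()]); species with group `""` are dropped.
#' @param groups which groups to compare (default: all non-empty groups in
#'   `group_map`).
#' @param response summary column, e.g. `"median_p_lmf"`.
#' @return list with `groups`, per-group `n` and means, `method`,
#'   `statistic`, `p.value`, `stars`.
#' @export
group_contrast <- function(summaries, group_map, groups = NULL,
                           response = "median_p_lmf") {
  stopifnot(inherits(summaries, "species_summary"),
            response %in% names(summaries))
  m <- merge(as.data.frame(summaries), group_map, by = "species")
  m <- m[m$group != "", , drop = FALSE]
  if (is.null(groups)) groups <- sort(unique(m$group))
  m <- m[m$group %in% groups, , drop = FALSE]
  if (length(groups) < 2L) stop("need at least two groups to contrast")
  vals <- split(m[[response]], factor(m$group, levels = groups))
  ns <- vapply(vals, length, integer(1))
  if (any(ns < 2L)) {
    stop("group(s) with fewer than 2 species: ",
         paste(names(ns)[ns < 2L], collapse = ", "))
  }
  if (length(groups) == 2L) {
    tt <- stats::t.test(vals[[1]], vals[[2]], var.equal = FALSE)
    method <- "Welch two-sample t-test"
    statistic <- unname(tt$statistic); pval <- tt$p.value
  } else {
    ow <- stats::oneway.test(y ~ g,
                             data = data.frame(y = m[[response]],
                                               g = factor(m$group)),
                             var.equal = FALSE)
    method <- "Welch one-way ANOVA"
    statistic <- unname(ow$statistic); pval <- ow$p.value
  }
  list(groups = groups, n = ns,
       means = vapply(vals, mean, numeric(1)),
       medians = vapply(vals, stats::median, numeric(1)),
       method = method, statistic = statistic, p.value = pval,
       stars = significance_stars(pval), response = response)
}
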