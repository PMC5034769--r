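# End-to-end orchestration: read or simulate a data set, run the
# allometric fits, dynamic slope curves, fraction trends and percentile
# summaries, and write every result to a machine-readable report bundle.
# Fully deterministic given (input, config, seed): each stochastic stage
# draws from a sub-seed derived from the run seed and the stage name, so
# adding a stage never perturbs earlier stages' draws.

#' Stable sub-seed for a named pipeline stage
#'
#' @param seed integer run seed.
#' @param stage stage name.
#' @return integer in [0, 2^31).
#' @export
sub_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

#' Configuration of a full pipeline run
#'
#' Exactly one of `input` (a biomass table path) or `synth` (a
#' [synth_config()]) must be given.
#'
#' @param input path to a delimited biomass table, or `NULL`.
#' @param synth a [synth_config()], or `NULL`.
#' @param dialect reading dialect for `input`.
#' @param filters named list of [filter_records()] atoms.
#' @param n_bins,span,n_boot analysis settings.
#' @param seed integer run seed (mandatory).
#' @param out_dir output directory for the report bundle.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, synth = NULL,
                       dialect = biomass_dialect(), filters = list(),
                       n_bins = 50, span = 0.75, n_boot = 500, seed,
                       out_dir = tempfile("dynallo_run_")) {
  if (is.null(input) == is.null(synth)) {
    stop("exactly one of 'input' and 'synth' must be given")
  }
  if (missing(seed)) stop("seed is mandatory")
  structure(list(input = input, synth = synth, dialect = dialect,
                 filters = filters, n_bins = n_bins, span = span,
                 n_boot = n_boot, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

.organ_pairs <- list(c("leaf", "stem"), c("leaf", "root"),
                     c("stem", "root"))

.sma_as_list <- function(f) {
  list(a_log = f$a_log, b = f$b, ci_b = f$ci_b, r2 = f$r2, n = f$n)
}

.poly_as_list <- function(f) {
  list(degree = f$degree, a_log = f$a_log, b1 = f$b1, b2 = f$b2,
       b3 = f$b3, bic = f$bic, delta_bic_vs_linear = f$delta_bic_vs_linear,
       r2 = f$r2, term_pvalue = f$term_pvalue, n = f$n)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate -> filter -> SMA and polynomial fits
#' with stepwise selection (per organ pair) -> bootstrap slope curves ->
#' fraction trends -> percentile ranks, species/family summaries, variance
#' partition, and functional-group contrasts when group labels are
#' present. All tabular outputs are CSV, all parameter sets JSON; a single
#' `summary.json` collects the headline quantities. Re-running with the
#' same config and seed reproduces every output byte for byte.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) list with the in-memory results and `out_dir`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("dynallo run\n", file = log_path)
  logf("R ", as.character(getRversion()), ", dynallo ",
       as.character(utils::packageVersion("dynallo")))
  logf("seed = ", cfg$seed, ", n_bins = ", cfg$n_bins, ", span = ",
       cfg$span, ", n_boot = ", cfg$n_boot)

  ds <- if (!is.null(cfg$input)) {
    logf("stage read: ", cfg$input)
    read_biomass(cfg$input, cfg$dialect)
  } else {
    logf("stage simulate: regime ", cfg$synth$regime)
    generate_dataset(cfg$synth)
  }
  if (length(cfg$filters)) {
    ds <- do.call(filter_records, c(list(ds), cfg$filters))
    logf("stage filter: ", nrow(ds), " records kept; removed per atom: ",
         paste(names(attr(ds, "filter_counts")),
               attr(ds, "filter_counts"), sep = "=", collapse = ", "))
  }
  summary_out <- list(seed = cfg$seed, n_records = nrow(ds),
                      n_species = length(unique(ds$species)))

  binning <- make_bins(ds, cfg$n_bins)
  fits <- list(); curves <- list()
  for (pr in .organ_pairs) {
    key <- paste0(pr[1], "_vs_", pr[2])
    pair <- allometric_pair(ds, pr[1], pr[2])
    sma <- fit_sma(pair)
    polys <- fit_polynomial(pair, max_degree = 3)
    sel <- select_model(polys)
    jsonlite::write_json(
      list(operation = "fit_sma", pair = key, fit = .sma_as_list(sma)),
      file.path(cfg$out_dir, paste0("sma_", key, ".json")),
      auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(operation = "fit_polynomial", pair = key,
           fits = lapply(polys, .poly_as_list),
           selected_degree = sel$degree),
      file.path(cfg$out_dir, paste0("poly_", key, ".json")),
      auto_unbox = TRUE, digits = NA)
    curve <- bootstrap_slope_curve(ds, pr[1], pr[2], n_bins = cfg$n_bins,
                                   n_boot = cfg$n_boot, span = cfg$span,
                                   seed = sub_seed(cfg$seed,
                                                   paste0("slopes_", key)))
    utils::write.csv(as.data.frame(curve),
                     file.path(cfg$out_dir, paste0("slopes_", key, ".csv")),
                     row.names = FALSE)
    fits[[key]] <- list(sma = sma, polys = polys, selected = sel)
    curves[[key]] <- curve
    summary_out[[paste0("sma_", key)]] <- .sma_as_list(sma)
    summary_out[[paste0("poly_selected_degree_", key)]] <- sel$degree
    summary_out[[paste0("poly_delta_bic_", key)]] <-
      sel$delta_bic_vs_linear
    logf("stage allometry ", key, ": b = ", format(sma$b, digits = 4),
         " [fit_sma], selected degree ", sel$degree, " [select_model]")
  }

  fr <- compute_fractions(ds)
  utils::write.csv(cbind(as.data.frame(fr),
                         log10_total_mass = log10(total_mass(ds))),
                   file.path(cfg$out_dir, "fractions.csv"),
                   row.names = FALSE)
  trends <- list()
  for (f in c("lmf", "smf", "rmf")) {
    tr <- fraction_trend(ds, f, binning, span = cfg$span)
    utils::write.csv(data.frame(grid = tr$grid, value = tr$value),
                     file.path(cfg$out_dir, paste0("trend_", f, ".csv")),
                     row.names = FALSE)
    trends[[f]] <- tr
    summary_out[[paste0("trend_r2_", f)]] <- tr$r2
    logf("stage clasmometry ", f, ": r2 = ", format(tr$r2, digits = 3),
         " [fraction_trend]")
  }

  pt <- percentile_ranks(ds, binning)
  utils::write.csv(as.data.frame(pt),
                   file.path(cfg$out_dir, "percentiles_records.csv"),
                   row.names = FALSE)
  percent <- list(table = pt)
  sp_ok <- any(table(ds$species) >= 4)
  if (sp_ok) {
    ss <- species_summaries(pt, min_records = 4)
    utils::write.csv(as.data.frame(ss),
                     file.path(cfg$out_dir, "percentiles_species.csv"),
                     row.names = FALSE)
    percent$species <- ss
    for (mode in c("min4", "min1")) {
      fam <- tryCatch(family_summaries(pt, mode = mode),
                      error = function(e) NULL)
      if (!is.null(fam)) {
        utils::write.csv(as.data.frame(fam),
                         file.path(cfg$out_dir,
                                   paste0("percentiles_family_", mode,
                                          ".csv")),
                         row.names = FALSE)
        percent[[paste0("family_", mode)]] <- fam
      }
    }
    if (!is.null(percent$family_min4)) {
      fam4 <- percent$family_min4
      summary_out$family_median_p_lmf <-
        stats::setNames(as.list(fam4$median_p_lmf), fam4$family)
    }
    vp <- tryCatch(variance_partition(pt), error = function(e) NULL)
    if (!is.null(vp)) {
      summary_out$variance_partition_p_lmf <-
        vp[c("family", "species", "residual")]
      logf("stage percentiles: species share ",
           format(vp$species, digits = 3), " [variance_partition]")
    }
    present <- unique(unlist(.parse_groups(ds$group_labels)))
    contrast_sets <- Filter(function(g) sum(g %in% present) >= 2,
                            .exclusive_groups)
    if (length(contrast_sets)) {
      gc_out <- list()
      for (g in contrast_sets) {
        gm <- species_groups(ds, g)
        res <- tryCatch(group_contrast(ss, gm, groups = g),
                        error = function(e) NULL)
        if (!is.null(res)) gc_out[[paste(g, collapse = "_vs_")]] <- res
      }
      if (length(gc_out)) {
        jsonlite::write_json(gc_out,
                             file.path(cfg$out_dir, "group_contrasts.json"),
                             auto_unbox = TRUE, digits = NA, force = TRUE)
        percent$contrasts <- gc_out
      }
    }
  }

  jsonlite::write_json(summary_out,
                       file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("done; outputs in ", cfg$out_dir)
  invisible(list(dataset = ds, binning = binning, fits = fits,
                 curves = curves, trends = trends, percentiles = percent,
                 summary = summary_out, out_dir = cfg$out_dir))
}
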