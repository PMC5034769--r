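#' @keywords internal
BIOMASS_COLUMNS <- c("record_id", "species", "family", "growth_form",
                     "group_labels", "leaf_mass_g", "stem_mass_g",
                     "root_mass_g", "source_id")

#' Controlled vocabulary of functional-group labels
#'
#' Labels attachable to a record's `group_labels` field. At most one of
#' evergreen/deciduous, one of C3/C4 and one of annual/perennial may be
#' present on the same record.
#' @export
GROUP_VOCABULARY <- c("evergreen", "deciduous", "gymnosperm", "angiosperm",
                      "monocot", "eudicot", "graminoid", "C3", "C4",
                      "annual", "perennial", "palm")

.exclusive_groups <- list(c("evergreen", "deciduous"),
                          c("C3", "C4"),
                          c("annual", "perennial"))

#' Construct a biomass data set
#'
#' A `biomass_data` object is a data frame with one row per plant (or
#' per-harvest mean) holding leaf, stem and root dry mass in grams plus
#' taxonomic (`species`, `family`) and functional-group annotations.
#' All mass columns must be strictly positive: every downstream analysis
#' works on log10-transformed masses.
#'
#' @param df data frame with at least `species`, `leaf_mass_g`,
#'   `stem_mass_g`, `root_mass_g`. Missing optional columns
#'   (`record_id`, `family`, `growth_form`, `group_labels`, `source_id`)
#'   are filled with defaults.
#' @param provenance free-text metadata attached to the object.
#' @param validate check invariants (positive masses, unique ids, group
#'   label exclusivity).
#' @return data frame of class `biomass_data`.
#' @export
biomass_data <- function(df, provenance = "", validate = TRUE) {
  stopifnot(is.data.frame(df))
  mandatory <- c("species", "leaf_mass_g", "stem_mass_g", "root_mass_g")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(df)
  if (is.null(df$record_id)) df$record_id <- sprintf("r%06d", seq_len(n))
  if (is.null(df$family)) df$family <- ""
  if (is.null(df$growth_form)) df$growth_form <- ""
  if (is.null(df$group_labels)) df$group_labels <- ""
  if (is.null(df$source_id)) df$source_id <- ""
  df <- df[, BIOMASS_COLUMNS]
  df$record_id <- as.character(df$record_id)
  df$species <- as.character(df$species)
  df$family <- as.character(df$family)
  df$growth_form <- as.character(df$growth_form)
  df$group_labels <- as.character(df$group_labels)
  df$source_id <- as.character(df$source_id)
  for (m in c("leaf_mass_g", "stem_mass_g", "root_mass_g")) {
    df[[m]] <- as.numeric(df[[m]])
  }
  rownames(df) <- NULL
  if (validate) {
    if (anyDuplicated(df$record_id)) {
      stop("record_id values must be unique within a data set")
    }
    bad <- which(!is.finite(df$leaf_mass_g) | df$leaf_mass_g <= 0 |
                 !is.finite(df$stem_mass_g) | df$stem_mass_g <= 0 |
                 !is.finite(df$root_mass_g) | df$root_mass_g <= 0)
    if (length(bad)) {
      stop("nonpositive or non-numeric organ mass in row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "))
    }
    .check_group_labels(df$group_labels)
  }
  structure(df,
            provenance = provenance,
            class = c("biomass_data", "data.frame"))
}

.parse_groups <- function(x) {
  strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE)
}

.check_group_labels <- function(labels) {
  parsed <- .parse_groups(labels)
  for (i in seq_along(parsed)) {
    g <- parsed[[i]]
    if (!length(g)) next
    unknown <- setdiff(g, GROUP_VOCABULARY)
    if (length(unknown)) {
      stop("row ", i, ": unknown group label(s): ",
           paste(unknown, collapse = ", "))
    }
    for (ex in .exclusive_groups) {
      if (sum(ex %in% g) > 1L) {
        stop("row ", i, ": mutually exclusive group labels: ",
             paste(ex, collapse = "/"))
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.biomass_data <- function(x, ...) {
  cat("<biomass_data> ", nrow(x), " records, ",
      length(unique(x$species)), " species, ",
      length(unique(x$family[x$family != ""])), " families\n", sep = "")
  rng <- range(total_mass(x))
  cat("  total dry mass ", format(rng[1], digits = 3), " - ",
      format(rng[2], digits = 3), " g\n", sep = "")
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("  provenance: ", prov, "\n", sep = "")
  invisible(x)
}

#' Total plant dry mass per record
#'
#' @param ds `biomass_data`.
#' @return numeric vector, grams (leaf + stem + root).
#' @export
total_mass <- function(ds) {
  ds$leaf_mass_g + ds$stem_mass_g + ds$root_mass_g
}

#' Reading/writing dialect for the tabular biomass format
#'
#' Column-name mapping, delimiter and unit factor live in this config so an
#' external table layout can be adapted without code change.
#'
#' @param sep field delimiter (default comma; use `"\t"` for TSV).
#' @param col_map named character vector mapping internal names
#'   (`record_id`, `species`, ..., `root_mass_g`) to the column headers in
#'   the file.
#' @param unit_factor multiplicative factor converting file masses to grams.
#' @param strict if `TRUE`, a row failing validation is a fatal error; if
#'   `FALSE` the row is skipped and reported.
#' @return list of class `biomass_dialect`.
#' @export
biomass_dialect <- function(sep = ",",
                            col_map = stats::setNames(BIOMASS_COLUMNS,
                                                      BIOMASS_COLUMNS),
                            unit_factor = 1,
                            strict = FALSE) {
  stopifnot(is.character(sep), length(sep) == 1L,
            is.numeric(unit_factor), unit_factor > 0)
  structure(list(sep = sep, col_map = col_map, unit_factor = unit_factor,
                 strict = strict),
            class = "biomass_dialect")
}

#' Read a biomass table from delimited text
#'
#' Expects a header row naming at least the species and the three organ-mass
#' columns. Rows with nonpositive or non-numeric masses are fatal in strict
#' mode, otherwise skipped; either way they are reported with their row
#' numbers in the attached validation report (see [validation_report()]).
#'
#' @param path file path.
#' @param dialect a [biomass_dialect()].
#' @return `biomass_data` with a `"validation"` attribute.
#' @export
read_biomass <- function(path, dialect = biomass_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  cm <- dialect$col_map
  mandatory <- c("species", "leaf_mass_g", "stem_mass_g", "root_mass_g")
  for (internal in mandatory) {
    file_col <- if (internal %in% names(cm)) cm[[internal]] else internal
    if (!file_col %in% names(raw)) {
      stop("missing mandatory column '", file_col, "' (for ", internal, ")")
    }
  }
  cols <- lapply(BIOMASS_COLUMNS, function(internal) {
    file_col <- if (internal %in% names(cm)) cm[[internal]] else internal
    if (file_col %in% names(raw)) raw[[file_col]] else rep("", nrow(raw))
  })
  df <- as.data.frame(stats::setNames(cols, BIOMASS_COLUMNS),
                      stringsAsFactors = FALSE, check.names = FALSE)
  if (all(df$record_id == "")) df$record_id <- sprintf("r%06d", seq_len(nrow(raw)))
  errors <- list()
  masses <- c("leaf_mass_g", "stem_mass_g", "root_mass_g")
  num <- lapply(df[masses], function(v) suppressWarnings(as.numeric(v)))
  bad <- Reduce(`|`, lapply(num, function(v) !is.finite(v) | v <= 0))
  if (any(bad)) {
    rows <- which(bad)
    msg <- paste0("row ", rows, ": nonpositive or non-numeric mass")
    if (dialect$strict) {
      stop("validation failed (strict mode):\n  ",
           paste(utils::head(msg, 10L), collapse = "\n  "))
    }
    errors <- lapply(rows, function(r)
      list(row = r, message = "nonpositive or non-numeric mass"))
  }
  keep <- !bad
  for (m in masses) df[[m]] <- num[[m]] * dialect$unit_factor
  ds <- biomass_data(df[keep, , drop = FALSE],
                     provenance = paste0("read from ", path))
  attr(ds, "validation") <- list(
    n_rows = nrow(raw), n_accepted = sum(keep), n_rejected = sum(bad),
    errors = errors)
  ds
}

#' Validation report of a read data set
#'
#' @param ds `biomass_data` returned by [read_biomass()].
#' @param json_path optional path; if given, the machine-readable summary is
#'   written there as JSON.
#' @return list with row counts and per-row errors, invisibly if written.
#' @export
validation_report <- function(ds, json_path = NULL) {
  rep <- attr(ds, "validation")
  if (is.null(rep)) {
    rep <- list(n_rows = nrow(ds), n_accepted = nrow(ds), n_rejected = 0L,
                errors = list())
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}

#' Write a biomass table to delimited text
#'
#' Masses are written with 17 significant digits so that a
#' read-write-read round trip reproduces every field exactly.
#'
#' @param ds `biomass_data`.
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_biomass <- function(ds, path, sep = ",") {
  out <- as.data.frame(ds)[, BIOMASS_COLUMNS]
  for (m in c("leaf_mass_g", "stem_mass_g", "root_mass_g")) {
    out[[m]] <- sprintf("%.17g", out[[m]])
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = TRUE, qmethod = "double")
  invisible(path)
}

#' Filter records by the analysis inclusion rules
#'
#' Declarative filter built from the supported atoms, applied in the order
#' `mass_range`, `groups`, `min_records_per_species`,
#' `min_species_per_family`. When both species and family atoms are given,
#' only species passing the record-count threshold are counted towards a
#' family's species tally (e.g. "families with >= 4 species having >= 4
#' records each"). The number of records removed per atom is attached as the
#' `"filter_counts"` attribute. Applying the same filter twice removes
#' nothing the second time.
#'
#' @param ds `biomass_data`.
#' @param min_records_per_species keep species with at least this many records.
#' @param min_species_per_family keep families with at least this many
#'   qualifying species.
#' @param mass_range length-2 numeric, grams; keep records with total mass in
#'   `[lo, hi]`.
#' @param groups character vector of group labels; keep records carrying at
#'   least one of them.
#' @param ... unused; a named argument here is an unknown filter atom and an
#'   error.
#' @return filtered `biomass_data`.
#' @export
filter_records <- function(ds, min_records_per_species = NULL,
                           min_species_per_family = NULL,
                           mass_range = NULL, groups = NULL, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown filter atom(s): ", paste(names(extra), collapse = ", "))
  }
  counts <- c(mass_range = 0L, groups = 0L,
              min_records_per_species = 0L, min_species_per_family = 0L)
  keep <- rep(TRUE, nrow(ds))
  if (!is.null(mass_range)) {
    stopifnot(length(mass_range) == 2L, mass_range[1] <= mass_range[2])
    tm <- total_mass(ds)
    drop <- keep & !(tm >= mass_range[1] & tm <= mass_range[2])
    counts["mass_range"] <- sum(drop)
    keep <- keep & !drop
  }
  if (!is.null(groups)) {
    unknown <- setdiff(groups, GROUP_VOCABULARY)
    if (length(unknown)) {
      stop("unknown group label(s) in filter: ", paste(unknown, collapse = ", "))
    }
    parsed <- .parse_groups(ds$group_labels)
    has <- vapply(parsed, function(g) any(groups %in% g), logical(1))
    drop <- keep & !has
    counts["groups"] <- sum(drop)
    keep <- keep & !drop
  }
  if (!is.null(min_records_per_species)) {
    tab <- table(ds$species[keep])
    ok_species <- names(tab)[tab >= min_records_per_species]
    drop <- keep & !(ds$species %in% ok_species)
    counts["min_records_per_species"] <- sum(drop)
    keep <- keep & !drop
  }
  if (!is.null(min_species_per_family)) {
    sub <- ds[keep, c("family", "species")]
    sp_per_fam <- tapply(sub$species, sub$family,
                         function(s) length(unique(s)))
    ok_fam <- names(sp_per_fam)[sp_per_fam >= min_species_per_family]
    drop <- keep & !(ds$family %in% ok_fam)
    counts["min_species_per_family"] <- sum(drop)
    keep <- keep & !drop
  }
  out <- biomass_data(as.data.frame(ds)[keep, , drop = FALSE],
                      provenance = attr(ds, "provenance"), validate = FALSE)
  attr(out, "filter_counts") <- counts
  out
}

#' Flag records far from the overall SMA line
#'
#' Optional diagnostic for candidate outliers: records with an absolute
#' standardized SMA residual above `threshold` are flagged. Flagged records
#' are only reported, never removed automatically (no objective removal
#' criterion exists for the handful of strongly deviating records such data
#' sets typically contain).
#'
#' @param ds `biomass_data`.
#' @param y_organ,x_organ organ names (`"leaf"`, `"stem"`, `"root"`).
#' @param threshold flag when `|residual / sd(residual)| > threshold`.
#' @return data frame with `record_id`, `residual`, `std_residual`, `flagged`.
#' @export
flag_outlier_records <- function(ds, y_organ = "leaf", x_organ = "stem",
                                 threshold = 4) {
  pair <- allometric_pair(ds, y_organ, x_organ)
  fit <- fit_sma(pair)
  res <- pair$y - (fit$a_log + fit$b * pair$x)
  std <- res / stats::sd(res)
  data.frame(record_id = ds$record_id, residual = res, std_residual = std,
             flagged = abs(std) > threshold, stringsAsFactors = FALSE)
}
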