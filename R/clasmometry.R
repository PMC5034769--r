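# Clasmometry: analysing biomass as fractions of whole-plant mass
# (LMF/SMF/RMF) rather than through allometric fits. Fractions are
# computable per plant with no fitted model, and plotting them against
# size recovers the size dependence without the r2 inflation inherent to
# log-log regressions spanning orders of magnitude.

#' Per-record biomass fractions
#'
#' LMF = leaf / total, SMF = stem / total, RMF = root / total dry mass
#' (g per g). Fractions of each record sum to one by construction.
#'
#' @param ds `biomass_data`.
#' @return data frame of class `fraction_set`: `record_id`, `lmf`, `smf`,
#'   `rmf`.
#' @export
compute_fractions <- function(ds) {
  tot <- total_mass(ds)
  structure(data.frame(record_id = ds$record_id,
                       lmf = ds$leaf_mass_g / tot,
                       smf = ds$stem_mass_g / tot,
                       rmf = ds$root_mass_g / tot,
                       stringsAsFactors = FALSE),
            class = c("fraction_set", "data.frame"))
}

#' Size trend of a biomass fraction
#'
#' A Loess curve (tricube weights, local degree 1) fitted through the mean
#' fraction of the size classes against their mean log10 total mass. The
#' explained variance is reported two ways, since either convention is
#' defensible: `r2` over all records, using the curve's monotone
#' interpolation at each record's log10 total mass (extrapolation beyond
#' the outer bin means is clamped to the end values and counted), and
#' `r2_bins` over the bin means themselves.
#'
#' @param ds `biomass_data`.
#' @param fraction `"lmf"`, `"smf"` or `"rmf"`.
#' @param binning a [make_bins()] result built on `ds`.
#' @param span Loess span.
#' @return list of class `fraction_trend`: `fraction`, `grid` (bin mean
#'   log10 total mass), `value` (curve at grid), `r2`, `r2_bins`,
#'   `n_extrapolated`.
#' @export
fraction_trend <- function(ds, fraction = c("lmf", "smf", "rmf"),
                           binning, span = 0.75) {
  fraction <- match.arg(fraction)
  stopifnot(inherits(binning, "size_binning"))
  if (length(binning$assignment) != nrow(ds)) {
    stop("binning was not built on this data set")
  }
  grid <- binning$table$mean_log_total
  bin_mean <- binning$table[[paste0("mean_", fraction)]]
  curve <- smooth_slopes(bin_mean, grid, span = span)
  fr <- compute_fractions(ds)[[fraction]]
  logm <- log10(total_mass(ds))
  pred <- stats::approx(grid, curve, xout = logm, rule = 2)$y
  n_extrap <- sum(logm < min(grid) | logm > max(grid))
  ss_res <- sum((fr - pred)^2)
  ss_tot <- sum((fr - mean(fr))^2)
  r2 <- if (ss_tot == 0) 0 else max(0, 1 - ss_res / ss_tot)
  ssb_res <- sum((bin_mean - curve)^2)
  ssb_tot <- sum((bin_mean - mean(bin_mean))^2)
  r2_bins <- if (ssb_tot == 0) 0 else max(0, 1 - ssb_res / ssb_tot)
  structure(list(fraction = fraction, grid = grid, value = curve,
                 r2 = r2, r2_bins = r2_bins, n_extrapolated = n_extrap,
                 span = span),
            class = "fraction_trend")
}

#' @export
print.fraction_trend <- function(x, ...) {
  cat(sprintf("<fraction_trend> %s: %.3f -> %.3f over log10 mass %.2f..%.2f\n",
              toupper(x$fraction), x$value[1], x$value[length(x$value)],
              min(x$grid), max(x$grid)))
  cat(sprintf("  r2 (records) = %.3f, r2 (bin means) = %.3f\n",
              x$r2, x$r2_bins))
  invisible(x)
}
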