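# Log-log allometric fits: Y = a X^b becomes log10 Y = log10 a + b log10 X.
# Model 2 (standardized major axis) fits treat both organ masses as
# error-prone; model 1 (OLS) polynomial fits of increasing degree test
# whether the log-log relationship is actually curved.

#' Build a paired log10 organ-mass vector set
#'
#' @param ds `biomass_data`.
#' @param y_organ,x_organ `"leaf"`, `"stem"` or `"root"`.
#' @return list of class `allometric_pair` with log10 masses `x`, `y`.
#' @export
allometric_pair <- function(ds, y_organ = c("leaf", "stem", "root"),
                            x_organ = c("stem", "leaf", "root")) {
  y_organ <- match.arg(y_organ)
  x_organ <- match.arg(x_organ)
  if (y_organ == x_organ) stop("x and y organ must differ")
  get <- function(o) log10(ds[[paste0(o, "_mass_g")]])
  x <- get(x_organ); y <- get(y_organ)
  if (length(x) < 3L) stop("need at least 3 records")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite log10 mass; records must have positive organ masses")
  }
  structure(list(x = x, y = y, x_organ = x_organ, y_organ = y_organ,
                 n = length(x)),
            class = "allometric_pair")
}

#' Build an allometric pair from raw log10 vectors
#'
#' Escape hatch for fitting arbitrary paired log10 quantities with the
#' same machinery (e.g. constructed test relationships).
#'
#' @param x,y paired log10 values, equal length >= 3, all finite.
#' @param x_organ,y_organ labels carried through to fits.
#' @return an `allometric_pair`.
#' @export
as_allometric_pair <- function(x, y, x_organ = "x", y_organ = "y") {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 x_organ = x_organ, y_organ = y_organ, n = length(x)),
            class = "allometric_pair")
}

#' Standardized major axis (model 2) fit of a log-log organ relationship
#'
#' Slope `b = sign(r) * sd(y)/sd(x)`, intercept `a_log = mean(y) -
#' b*mean(x)`. The 95% CI uses the standard F-based construction: with
#' `B = qf(1-alpha, 1, n-2) * (1-r^2)/(n-2)`, the interval is
#' `b * (sqrt(B+1) -/+ sqrt(B))`. `r2` is the squared Pearson correlation
#' (identical to the OLS r-squared on the same pair).
#'
#' @param pair an [allometric_pair()].
#' @param alpha CI level is `1 - alpha`.
#' @return list of class `sma_fit`: `a_log`, `b`, `ci_b`, `r2`, `n`.
#' @export
fit_sma <- function(pair, alpha = 0.05) {
  stopifnot(inherits(pair, "allometric_pair"))
  x <- pair$x; y <- pair$y; n <- pair$n
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("degenerate input: zero variance in x or y")
  r <- stats::cor(x, y)
  if (r == 0) stop("correlation is exactly zero: SMA slope sign undefined")
  b <- sign(r) * sy / sx
  a_log <- mean(y) - b * mean(x)
  B <- stats::qf(1 - alpha, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- sort(b * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B)))
  structure(list(a_log = a_log, b = b, ci_b = ci, r2 = r^2, n = n,
                 alpha = alpha, x_organ = pair$x_organ,
                 y_organ = pair$y_organ),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA fit: log10(%s) = %.4f + %.4f * log10(%s)\n",
              x$y_organ, x$a_log, x$b, x$x_organ))
  cat(sprintf("  b = %.4f  [%.4f, %.4f] (%d%% CI),  r2 = %.4f,  n = %d\n",
              x$b, x$ci_b[1], x$ci_b[2], round(100 * (1 - x$alpha)),
              x$r2, x$n))
  invisible(x)
}

.poly_bic <- function(fit, n) {
  rss <- sum(stats::residuals(fit)^2)
  k <- length(stats::coef(fit))
  n * log(rss / n) + k * log(n)
}

#' OLS polynomial fits (model 1) of increasing degree
#'
#' Fits `y ~ x`, `y ~ x + x^2`, ... up to `max_degree`. For each degree the
#' BIC is `n*log(RSS/n) + k*log(n)` with `k` the number of coefficients
#' including the intercept (an internal convention; only differences are
#' meaningful), and the p-value of the added highest-order term comes from
#' the incremental F-test against the next-lower degree.
#'
#' @param pair an [allometric_pair()].
#' @param max_degree 1 to 3.
#' @return list of `poly_fit` objects, one per degree. Each holds `degree`,
#'   `a_log`, coefficients `b1`..`b3`, `bic`, `delta_bic_vs_linear`, `r2`,
#'   `n`, `term_pvalue` and the underlying `lm` object.
#' @export
fit_polynomial <- function(pair, max_degree = 3) {
  stopifnot(inherits(pair, "allometric_pair"),
            max_degree >= 1, max_degree <= 3)
  x <- pair$x; y <- pair$y; n <- pair$n
  if (n <= max_degree + 1) stop("need n > max_degree + 1 records")
  if (stats::sd(x) == 0) stop("degenerate input: x is constant")
  dat <- data.frame(y = y, x1 = x, x2 = x^2, x3 = x^3)
  fits <- vector("list", max_degree)
  lm_prev <- stats::lm(y ~ 1, data = dat)
  bic1 <- NA_real_
  for (d in seq_len(max_degree)) {
    fml <- stats::as.formula(paste("y ~", paste0("x", seq_len(d),
                                                 collapse = " + ")))
    lm_d <- stats::lm(fml, data = dat)
    bic <- .poly_bic(lm_d, n)
    if (d == 1L) bic1 <- bic
    pv <- stats::anova(lm_prev, lm_d)[["Pr(>F)"]][2]
    cf <- stats::coef(lm_d)
    fits[[d]] <- structure(list(
      degree = d, a_log = unname(cf[1]),
      b1 = unname(cf["x1"]),
      b2 = if (d >= 2) unname(cf["x2"]) else NULL,
      b3 = if (d >= 3) unname(cf["x3"]) else NULL,
      bic = bic, delta_bic_vs_linear = bic - bic1,
      r2 = summary(lm_d)$r.squared, n = n, term_pvalue = pv,
      x_organ = pair$x_organ, y_organ = pair$y_organ, lm = lm_d),
      class = "poly_fit")
    lm_prev <- lm_d
  }
  fits
}

#' @export
print.poly_fit <- function(x, ...) {
  co <- c(x$b1, x$b2, x$b3)
  cat(sprintf("Polynomial fit (degree %d): log10(%s) ~ log10(%s)\n",
              x$degree, x$y_organ, x$x_organ))
  cat("  a_log =", format(x$a_log, digits = 4),
      " coefs:", paste(format(co, digits = 4), collapse = ", "), "\n")
  cat(sprintf("  BIC = %.1f (delta vs linear %.1f), r2 = %.4f, term p = %.3g\n",
              x$bic, x$delta_bic_vs_linear, x$r2, x$term_pvalue))
  invisible(x)
}

#' Forward stepwise selection among polynomial degrees
#'
#' Starting from the linear fit, a higher degree is accepted while its
#' added term is significant at `alpha` AND its BIC is lower than that of
#' every lower degree. When the two criteria disagree at some step,
#' selection stops there; with `strict = TRUE` a disagreement instead
#' falls back to the linear fit with a conflict warning.
#'
#' @param fits list returned by [fit_polynomial()].
#' @param alpha significance level for the added term.
#' @param strict fall back to linear on any p/BIC conflict.
#' @return the selected `poly_fit`, with attribute `"conflict"`.
#' @export
select_model <- function(fits, alpha = 0.05, strict = FALSE) {
  if (!length(fits)) stop("empty fit list")
  chosen <- 1L
  conflict <- FALSE
  for (d in seq_along(fits)[-1]) {
    p_ok <- is.finite(fits[[d]]$term_pvalue) && fits[[d]]$term_pvalue < alpha
    bic_ok <- fits[[d]]$bic < min(vapply(fits[seq_len(d - 1L)],
                                         `[[`, numeric(1), "bic"))
    if (p_ok && bic_ok) {
      chosen <- d
    } else if (p_ok != bic_ok) {
      conflict <- TRUE
      break
    } else {
      break
    }
  }
  if (conflict && strict) {
    warning("stepwise p-value and BIC criteria disagree; ",
            "falling back to the linear fit (strict mode)")
    chosen <- 1L
  }
  out <- fits[[chosen]]
  attr(out, "conflict") <- conflict
  out
}

# Wald-Wolfowitz runs test on the signs of a sequence (normal approximation).
.runs_test <- function(v) {
  s <- sign(v)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0) {
    return(list(runs = ifelse(n > 0, 1L, 0L), statistic = NA_real_,
                p.value = NA_real_))
  }
  runs <- 1L + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(sigma2)
  list(runs = runs, statistic = z,
       p.value = 2 * stats::pnorm(-abs(z)))
}

#' Residual diagnostics for an allometric fit
#'
#' Residuals are ordered by `x`; systematic curvature left in the residuals
#' rejects the fitted (e.g. log-linear) form. Reports a Wald-Wolfowitz runs
#' test on the residual signs and the correlation of residuals with `x^2`
#' as curvature evidence.
#'
#' @param pair the [allometric_pair()] the fit was computed on.
#' @param fit an `sma_fit` or `poly_fit`.
#' @return list with `residuals` (data frame ordered by x), `runs`
#'   (`runs`, `statistic`, `p.value`) and `curvature` (`estimate`,
#'   `p.value`).
#' @export
residual_diagnostics <- function(pair, fit) {
  stopifnot(inherits(pair, "allometric_pair"))
  pred <- if (inherits(fit, "sma_fit")) {
    fit$a_log + fit$b * pair$x
  } else if (inherits(fit, "poly_fit")) {
    co <- c(fit$b1, fit$b2, fit$b3)
    fit$a_log + Reduce(`+`, lapply(seq_along(co),
                                   function(d) co[d] * pair$x^d))
  } else {
    stop("fit must be an sma_fit or poly_fit")
  }
  res <- pair$y - pred
  ord <- order(pair$x)
  runs <- .runs_test(res[ord])
  if (stats::sd(res) == 0 || stats::sd(pair$x^2) == 0) {
    curv <- list(estimate = 0, p.value = NA_real_)
  } else {
    ct <- stats::cor.test(res, pair$x^2)
    curv <- list(estimate = unname(ct$estimate), p.value = ct$p.value)
  }
  list(residuals = data.frame(x = pair$x[ord], residual = res[ord]),
       runs = runs, curvature = curv)
}
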