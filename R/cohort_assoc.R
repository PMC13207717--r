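## Cohort-level lipid-symptom association: outlier trimming, covariate
## residualization, Pearson correlation, ratio traits, and instrument-based
## polygenic scoring.

#' Trim values outside mean +/- k standard deviations
#'
#' Mean and sd are computed once on the input (single pass, no
#' re-iteration); exclusion is strict (`value < mean - k sd` or `value >
#' mean + k sd`), so a value exactly on the boundary is retained.  With zero
#' sd nothing is removed.
#'
#' @param values numeric vector (NAs ignored for the bounds, retained in
#'   output positions only if finite — non-finite values are removed).
#' @param k number of standard deviations (default 5).
#' @return trimmed values; the removed count is attached as the `n_removed`
#'   attribute and removed indices as `removed_idx`.
#' @export
trim_outliers <- function(values, k = 5) {
  finite <- is.finite(values)
  if (sum(finite) < 3) stop("trim_outliers: need >= 3 finite values")
  m <- mean(values[finite]); s <- stats::sd(values[finite])
  out_of_range <- finite & s > 0 &
    (values < m - k * s | values > m + k * s)
  removed <- which(out_of_range | !finite)
  kept <- if (length(removed)) values[-removed] else values
  attr(kept, "n_removed") <- length(removed)
  attr(kept, "removed_idx") <- removed
  kept
}

## Residuals of y on covariates (least squares with intercept; categorical
## covariates expanded to indicators; aliased columns dropped with warning).
.residualize <- function(y, covariates) {
  if (is.null(covariates) || (is.data.frame(covariates) && !ncol(covariates)))
    return(y - mean(y))
  covariates <- as.data.frame(covariates)
  X <- stats::model.matrix(~ ., data = covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    warning("residualize: dropping aliased covariate column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  qr.resid(qrX, y)
}

#' Covariate-adjusted Pearson correlation
#'
#' `x` is log-transformed (natural log) and residualized on its covariates;
#' `y` is residualized on its covariates; the Pearson correlation of the
#' residuals is tested with the t transform on `n - 2` degrees of freedom.
#' Only complete cases enter.  Outlier trimming ([trim_outliers()]) is the
#' caller's responsibility and should precede this call.
#'
#' @param x positive lipid values.
#' @param x_covariates data frame of covariates for `x` (or `NULL`).
#' @param y symptom scores.
#' @param y_covariates data frame of covariates for `y` (or `NULL`).
#' @param log_x log-transform `x` first (default `TRUE`).
#' @return list with `r`, `p`, `n`.
#' @export
adjusted_correlation <- function(x, x_covariates = NULL, y,
                                 y_covariates = NULL, log_x = TRUE) {
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(x_covariates))
    ok <- ok & stats::complete.cases(as.data.frame(x_covariates))
  if (!is.null(y_covariates))
    ok <- ok & stats::complete.cases(as.data.frame(y_covariates))
  if (sum(ok) < 10) stop("adjusted_correlation: fewer than 10 complete cases")
  xs <- x[ok]; ys <- y[ok]
  if (log_x) {
    if (any(xs <= 0)) stop("adjusted_correlation: x must be positive for log")
    xs <- log(xs)
  }
  xr <- .residualize(xs, if (is.null(x_covariates)) NULL else
    as.data.frame(x_covariates)[ok, , drop = FALSE])
  yr <- .residualize(ys, if (is.null(y_covariates)) NULL else
    as.data.frame(y_covariates)[ok, , drop = FALSE])
  ct <- stats::cor.test(xr, yr, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Fraction of a lipid relative to its class total
#'
#' @param lipid_value per-subject species concentration.
#' @param total_class_value per-subject class total (must be >= species
#'   value).
#' @return fractions in `(0, 1]`; subjects with non-positive totals get
#'   `NA` and are counted in the `n_excluded` attribute.
#' @export
ratio_trait <- function(lipid_value, total_class_value) {
  bad <- !is.finite(total_class_value) | total_class_value <= 0
  if (any(lipid_value[!bad] > total_class_value[!bad], na.rm = TRUE))
    stop("ratio_trait: lipid value exceeds class total")
  out <- ifelse(bad, NA_real_, lipid_value / total_class_value)
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Instrument-based polygenic score
#'
#' `score_i = sum_j dosage_ij * beta_j`; dosages must already be aligned to
#' the effect alleles of the betas (harmonize first).
#'
#' @param dosages subjects x SNPs matrix of effect-allele dosages in
#'   `[0, 2]`.
#' @param instrument_betas per-SNP weights, effect-allele aligned.
#' @return numeric vector of per-subject scores.
#' @export
polygenic_score <- function(dosages, instrument_betas) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != length(instrument_betas))
    stop("polygenic_score: dosage columns (", ncol(dosages),
         ") != instrument count (", length(instrument_betas), ")")
  drop(dosages %*% instrument_betas)
}
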