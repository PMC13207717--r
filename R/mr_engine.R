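## Correlated-instrument summary-data MR: GSMR-style GLS with HEIDI outlier
## filtering, fixed-effect IVW and MR-Egger sensitivity estimators, panel-wide
## BH FDR, and locus masking.

#' Assemble an instrument set
#'
#' @param data data frame with columns `snp`, `chr`, `pos`, `bzx`, `se_zx`,
#'   `p_zx`, `bzy`, `se_zy` (one row per instrument, harmonized orientation).
#' @param ld `ld_matrix` over the same variants, same order, signs on the
#'   instrument effect-allele orientation.
#' @return an `instrument_set`.
#' @export
instrument_set <- function(data, ld) {
  needed <- c("snp", "chr", "pos", "bzx", "se_zx", "p_zx", "bzy", "se_zy")
  stopifnot(all(needed %in% names(data)))
  if (!identical(as.character(data$snp), rownames(ld)))
    stop("instrument_set: LD matrix ids do not match instrument ids")
  if (any(data$se_zx <= 0) || any(data$se_zy <= 0))
    stop("instrument_set: standard errors must be > 0")
  structure(list(data = as.data.frame(data), ld = unclass(ld)),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %d variants on chromosome(s) %s\n",
              nrow(x$data), paste(unique(x$data$chr), collapse = ",")))
  invisible(x)
}

#' Per-instrument Wald ratio and delta-method variance
#'
#' `bxy_i = bzy/bzx`; `var_i = (bzy^2/bzx^2) * (se_zx^2/bzx^2 +
#' se_zy^2/bzy^2)`.  At `bzy = 0` the variance is taken as the continuity
#' limit `se_zy^2/bzx^2`, which keeps the weight finite and positive.
#'
#' @param bzx,se_zx exposure effect and standard error.
#' @param bzy,se_zy outcome effect and standard error.
#' @return list with `bxy` and `var` (vectorized).
#' @export
wald_ratio <- function(bzx, se_zx, bzy, se_zy) {
  if (any(bzx == 0)) stop("wald_ratio: null instrument (bzx = 0)")
  bxy <- bzy / bzx
  v <- (bzy^2 / bzx^2) * (se_zx^2 / bzx^2 + ifelse(bzy == 0, 0, se_zy^2 / bzy^2))
  v <- ifelse(bzy == 0, se_zy^2 / bzx^2, v)
  list(bxy = bxy, var = v)
}

## Inverse-variance-weighted median of ratio estimates (robust anchor used to
## pick the HEIDI reference instrument).
.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  x[which(cw >= 0.5)[1L]]
}

.mr_result <- function(exposure, outcome, method, bxy, se, n_snps,
                       removed_by_heidi = character(0), Q = NA_real_,
                       egger_intercept = NA_real_, intercept_se = NA_real_,
                       intercept_p = NA_real_) {
  structure(list(exposure = exposure, outcome = outcome, method = method,
                 bxy = bxy, se = se,
                 pval = 2 * stats::pnorm(-abs(bxy / se)),
                 n_snps_used = n_snps, removed_by_heidi = removed_by_heidi,
                 Q = Q, egger_intercept = egger_intercept,
                 intercept_se = intercept_se, intercept_p = intercept_p),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR (%s): %s -> %s\n", x$method, x$exposure, x$outcome))
  cat(sprintf("  bxy = %.4g (se %.4g), p = %.3g, instruments = %d\n",
              x$bxy, x$se, x$pval, x$n_snps_used))
  if (length(x$removed_by_heidi))
    cat("  HEIDI-removed:", paste(x$removed_by_heidi, collapse = ", "), "\n")
  if (x$method == "egger")
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n",
                x$egger_intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' @export
coef.mr_result <- function(object, ...) c(bxy = object$bxy)

## Greedy LD pruning of an instrument set by exposure p (ties: pos, then id),
## enforcing all pairwise r^2 < r2_max among survivors.
.prune_instruments <- function(ins, r2_max) {
  d <- ins$data
  ord <- order(d$p_zx, d$pos, d$snp)
  keep <- logical(nrow(d))
  r2 <- ins$ld^2
  for (i in ord) {
    if (!any(keep) || all(r2[i, keep] < r2_max)) keep[i] <- TRUE
  }
  instrument_set(d[keep, , drop = FALSE],
                 ins$ld[keep, keep, drop = FALSE])
}

#' GSMR-style fit: GLS over correlated Wald ratios with HEIDI filtering
#'
#' Steps: (1) greedily prune instruments until all pairwise `r^2 <
#' ld_prune_r2` (ordered by exposure p-value); (2) HEIDI outlier filtering —
#' the reference instrument is the one whose Wald ratio is closest to the
#' inverse-variance-weighted median ratio (robust to a pleiotropic top
#' instrument); every other instrument's ratio difference from the reference
#' is z-tested with covariance `var_i + var_ref - 2 r_{i,ref}
#' sqrt(var_i var_ref)` (delta-method variances), instruments with `p <
#' heidi_p` are removed and the filter iterates (reference recomputed) to
#' convergence, at most 10 rounds; (3) surviving ratios are combined by
#' generalized least squares with `V_ij = r_ij sqrt(v_i v_j)`, where the
#' `v_i` are iterated modified second-order weights (variance evaluated at
#' the predicted outcome effect), which avoids the attenuation that
#' observed-value weights induce.
#'
#' With identity LD the GLS estimate equals fixed-effect IVW.  `heidi_p = 0`
#' disables filtering.
#'
#' @param instruments an `instrument_set`.
#' @param heidi_p HEIDI removal threshold (default 0.01).
#' @param ld_prune_r2 pairwise `r^2` ceiling among instruments (default 0.1).
#' @param exposure,outcome trait labels carried into the result.
#' @return an `mr_result` (`method = "gsmr"`).
#' @export
gsmr_fit <- function(instruments, heidi_p = 0.01, ld_prune_r2 = 0.1,
                     exposure = "exposure", outcome = "outcome") {
  ins <- .prune_instruments(instruments, ld_prune_r2)
  d <- ins$data
  if (nrow(d) < 2) stop("gsmr_fit: insufficient instruments")
  ## covariance of Wald ratios follows the LD aligned to each instrument's
  ## exposure-increasing allele: r_eff = r * sign(bzx_i) * sign(bzx_j), which
  ## makes the fit invariant under simultaneous allele flips
  sgn <- ifelse(d$bzx < 0, -1, 1)
  ins$ld <- ins$ld * tcrossprod(sgn)
  diag(ins$ld) <- 1
  wr <- wald_ratio(d$bzx, d$se_zx, d$bzy, d$se_zy)
  ratio <- wr$bxy; v <- wr$var
  alive <- rep(TRUE, nrow(d))
  removed <- character(0)

  if (heidi_p > 0) {
    for (iter in seq_len(10L)) {
      idx <- which(alive)
      if (length(idx) <= 2) break
      anchor <- .weighted_median(ratio[idx], 1 / v[idx])
      ref_rel <- order(abs(ratio[idx] - anchor), d$p_zx[idx])[1L]
      ref <- idx[ref_rel]
      others <- setdiff(idx, ref)
      dvar <- v[others] + v[ref] -
        2 * ins$ld[others, ref] * sqrt(v[others] * v[ref])
      dvar <- pmax(dvar, .Machine$double.eps)
      z <- (ratio[others] - ratio[ref]) / sqrt(dvar)
      p <- 2 * stats::pnorm(-abs(z))
      bad <- others[p < heidi_p]
      bad <- bad[order(p[p < heidi_p])]  # most deviant first
      if (!length(bad)) break
      ## never drop below 2 survivors
      if (sum(alive) - length(bad) < 2)
        bad <- bad[seq_len(max(0L, sum(alive) - 2L))]
      if (!length(bad)) break
      alive[bad] <- FALSE
      removed <- c(removed, d$snp[bad])
    }
  }

  keep <- which(alive)
  fit <- .modified_gls(d[keep, , drop = FALSE],
                       ins$ld[keep, keep, drop = FALSE])
  res <- .mr_result(exposure, outcome, "gsmr", fit$bxy, fit$se,
                    n_snps = length(fit$used), removed_by_heidi = removed)
  res$snps_used <- fit$used
  res
}

## GLS over Wald ratios with iterated modified second-order weights: the
## per-instrument variance is evaluated at the predicted outcome effect
## (bzy -> b * bzx), v_i = b^2 se_zx,i^2/bzx,i^2 + se_zy,i^2/bzx,i^2, which
## decouples the weights from the estimation noise in bzy and removes the
## attenuation the observed-value weights induce.  Starts from IVW with the
## delta-method variances; three weight updates suffice for convergence at
## double precision in practice.
.modified_gls <- function(d, r) {
  ratio <- d$bzy / d$bzx
  wr <- wald_ratio(d$bzx, d$se_zx, d$bzy, d$se_zy)
  fit <- .gls_combine(ratio, wr$var, r, d$snp)
  ## fix the instrument set after any conditioning drops, then iterate
  keep <- match(fit$used, d$snp)
  d <- d[keep, , drop = FALSE]; r <- r[keep, keep, drop = FALSE]
  ratio <- ratio[keep]
  b <- fit$bxy
  for (it in 1:3) {
    v <- b^2 * d$se_zx^2 / d$bzx^2 + d$se_zy^2 / d$bzx^2
    fit2 <- .gls_combine(ratio, v, r, d$snp)
    b <- fit2$bxy
  }
  list(bxy = fit2$bxy, se = fit2$se, used = fit$used,
       weights = 1 / v)
}

## GLS combination of ratio estimates with covariance V_ij = r_ij sqrt(v_i v_j).
## If V is ill-conditioned (condition number > 1e10), the later member of the
## most-correlated pair is dropped (mirrors LD-pruning intent) with a warning.
.gls_combine <- function(ratio, v, r, ids) {
  repeat {
    if (length(ratio) < 2) stop("gsmr_fit: insufficient instruments")
    ## condition the scale-invariant correlation structure, not V itself:
    ## heterogeneous variances are harmless, near-collinear LD is not
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0 && max(ev) / min(ev) <= 1e10) break
    r2 <- r^2; diag(r2) <- -Inf
    worst <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
    drop_i <- max(worst)
    warning("gsmr_fit: near-collinear instrument pair (", ids[min(worst)],
            ", ", ids[drop_i], "); dropping ", ids[drop_i])
    keep <- setdiff(seq_along(ratio), drop_i)
    ratio <- ratio[keep]; v <- v[keep]; r <- r[keep, keep, drop = FALSE]
    ids <- ids[keep]
  }
  V <- r * sqrt(outer(v, v))
  ch <- chol(V)
  one <- rep(1, length(ratio))
  Vi1 <- backsolve(ch, forwardsolve(t(ch), one))
  Vib <- backsolve(ch, forwardsolve(t(ch), ratio))
  denom <- sum(one * Vi1)
  list(bxy = sum(one * Vib) / denom, se = 1 / sqrt(denom), used = ids)
}

#' Fixed-effect inverse-variance-weighted MR
#'
#' Inverse-variance-weighted mean of the Wald ratios with the same iterated
#' modified second-order weights as [gsmr_fit()]'s GLS (so GSMR with
#' identity LD reproduces IVW exactly).  Cochran's Q at the final weights is
#' reported as a heterogeneity diagnostic (a multiplicative random-effects
#' standard error can be derived from it by the caller).
#'
#' @inheritParams gsmr_fit
#' @return an `mr_result` (`method = "ivw_fixed"`) with a `Q` element.
#' @export
ivw_fit <- function(instruments, exposure = "exposure", outcome = "outcome") {
  d <- instruments$data
  if (nrow(d) < 2) stop("ivw_fit: insufficient instruments")
  fit <- .modified_gls(d, diag(nrow(d)))
  keep <- match(fit$used, d$snp)
  ratio <- d$bzy[keep] / d$bzx[keep]
  Q <- sum(fit$weights * (ratio - fit$bxy)^2)
  .mr_result(exposure, outcome, "ivw_fixed", fit$bxy, fit$se,
             length(fit$used), Q = Q)
}

#' MR-Egger regression
#'
#' Instruments are oriented so the exposure effect is non-negative (both
#' betas negated where `bzx < 0`), then `bzy` is regressed on `bzx` with an
#' intercept by weighted least squares, weights `1/se_zy^2` treated as known
#' inverse variances (no residual rescaling), so the intercept z-test is
#' exactly normal under the generative model.  The intercept estimates the
#' mean directional pleiotropic effect.
#'
#' @inheritParams gsmr_fit
#' @return an `mr_result` (`method = "egger"`) with intercept fields.
#' @export
egger_fit <- function(instruments, exposure = "exposure", outcome = "outcome") {
  d <- instruments$data
  if (nrow(d) < 3) stop("egger_fit: at least 3 instruments required")
  s <- ifelse(d$bzx < 0, -1, 1)
  x <- s * d$bzx; y <- s * d$bzy
  if (max(x) - min(x) < .Machine$double.eps * max(1, max(abs(x))))
    stop("egger_fit: degenerate design (all oriented bzx identical)")
  w <- 1 / d$se_zy^2
  X <- cbind(1, x)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * y)
  co <- solve(XtWX, XtWy)
  covb <- solve(XtWX)
  intercept <- co[1L]; slope <- co[2L]
  int_se <- sqrt(covb[1L, 1L]); slope_se <- sqrt(covb[2L, 2L])
  .mr_result(exposure, outcome, "egger", slope, slope_se, nrow(d),
             egger_intercept = intercept, intercept_se = int_se,
             intercept_p = 2 * stats::pnorm(-abs(intercept / int_se)))
}

#' Select MR instruments for one exposure
#'
#' Harmonizes exposure and outcome, drops palindromic variants, clumps on the
#' exposure p-values against the reference panel, and assembles the surviving
#' quadruples with their LD matrix.  Returns the string
#' `"skipped: <n> instruments"` when fewer than `min_snps` survive.
#'
#' LD signs are aligned to the harmonized effect-allele orientation: where an
#' instrument's effect allele is the panel's other allele, that variant's LD
#' row/column changes sign.
#'
#' @param exposure,outcome `gwas_table`s.
#' @param panel an `ld_panel`.
#' @param p_threshold instrument association threshold (default `1e-6`).
#' @param clump_r2,clump_window clumping parameters (defaults `0.1`, 10 Mb).
#' @param min_snps minimum surviving instruments (default 10; 3 in relaxed
#'   mode).
#' @return an `instrument_set`, or a `"skipped: ..."` character scalar.
#' @export
select_instruments <- function(exposure, outcome, panel,
                               p_threshold = 1e-6, clump_r2 = 0.1,
                               clump_window = 1e7, min_snps = 10) {
  h <- harmonize(exposure, outcome, drop_palindromic = TRUE)
  d <- h$data
  in_panel <- d$snp %in% panel$map$snp
  d <- d[in_panel, , drop = FALSE]
  d$p <- d$p_zx
  if (!nrow(d) || !any(d$p < p_threshold, na.rm = TRUE))
    return("skipped: 0 instruments")
  idx <- clump(d, panel, p_threshold = p_threshold,
               r2_threshold = clump_r2, window_bp = clump_window)
  if (length(idx) < min_snps)
    return(sprintf("skipped: %d instruments", length(idx)))
  d <- d[match(idx, d$snp), , drop = FALSE]
  ld <- compute_ld(panel, idx)
  ## align LD signs with harmonized orientation
  pm <- panel$map[match(idx, panel$map$snp), ]
  sgn <- ifelse(d$ea == pm$ea, 1,
                ifelse(d$ea == pm$oa, -1,
                       ifelse(d$ea == unname(.complement[pm$ea]), 1, -1)))
  ld <- ld * tcrossprod(sgn)
  diag(ld) <- 1
  dimnames(ld) <- list(idx, idx)
  instrument_set(d[, c("snp", "chr", "pos", "bzx", "se_zx", "p_zx",
                       "bzy", "se_zy")],
                 structure(ld, class = c("ld_matrix", "matrix", "array")))
}

#' Remove variants in a genomic interval
#'
#' Inclusive 1-based interval removal (e.g. masking the chromosome-11 fatty
#' acid desaturase cluster, chr11:61,067,099-62,134,286, for sensitivity
#' reruns).  Works on a `gwas_table` or an `instrument_set`.
#'
#' @param x `gwas_table` or `instrument_set`.
#' @param chrom chromosome.
#' @param start,end interval bounds (1-based, both inclusive).
#' @return object of the same type; the count removed is attached as the
#'   `n_masked` attribute.
#' @export
mask_locus <- function(x, chrom, start, end) {
  stopifnot(start <= end)
  if (inherits(x, "gwas_table")) {
    hit <- x$chr == as.character(chrom) & x$pos >= start & x$pos <= end
    out <- gwas_table(as.data.frame(x)[!hit, , drop = FALSE],
                      trait_name = attr(x, "trait_name"),
                      trait_type = attr(x, "trait_type"))
  } else if (inherits(x, "instrument_set")) {
    d <- x$data
    hit <- d$chr == as.character(chrom) & d$pos >= start & d$pos <= end
    out <- instrument_set(d[!hit, , drop = FALSE],
                          x$ld[!hit, !hit, drop = FALSE])
  } else stop("mask_locus: unsupported type")
  attr(out, "n_masked") <- sum(hit)
  out
}

#' Run an exposure panel against one outcome
#'
#' For each exposure: instrument selection, GSMR fit, and IVW / MR-Egger
#' sensitivity fits on the GSMR-surviving instruments.  Benjamini-Hochberg
#' FDR is applied over the GSMR p-values of the exposures actually tested
#' (skipped exposures do not enter `m`).
#'
#' @param exposures named list of `gwas_table`s (names = exposure labels).
#' @param outcome a `gwas_table`.
#' @param panel an `ld_panel`.
#' @param p_threshold,clump_r2,clump_window,min_snps see
#'   [select_instruments()].
#' @param heidi_p HEIDI threshold (default 0.01).
#' @param mask optional `list(chrom =, start =, end =)` interval removed from
#'   every exposure and the outcome before instrument selection.
#' @return data frame of class `mr_panel_result`, one row per tested
#'   exposure: `exposure`, `bxy`, `se`, `pval`, `q_fdr`, `n_snps`,
#'   `n_heidi_removed`, `bxy_ivw`, `se_ivw`, `p_ivw`, `Q_ivw`, `bxy_egger`,
#'   `se_egger`, `p_egger`, `egger_intercept`, `intercept_p`.  Skipped
#'   exposures are recorded in the `skipped` attribute.
#' @export
run_panel <- function(exposures, outcome, panel,
                      p_threshold = 1e-6, clump_r2 = 0.1, clump_window = 1e7,
                      min_snps = 10, heidi_p = 0.01, mask = NULL) {
  stopifnot(length(exposures) >= 1)
  if (is.null(names(exposures)))
    names(exposures) <- paste0("exposure_", seq_along(exposures))
  if (!is.null(mask))
    outcome <- mask_locus(outcome, mask$chrom, mask$start, mask$end)
  rows <- list(); skipped <- list()
  for (nm in names(exposures)) {
    ex <- exposures[[nm]]
    if (!is.null(mask)) ex <- mask_locus(ex, mask$chrom, mask$start, mask$end)
    ins <- tryCatch(
      select_instruments(ex, outcome, panel, p_threshold = p_threshold,
                         clump_r2 = clump_r2, clump_window = clump_window,
                         min_snps = min_snps),
      error = function(e) sprintf("skipped: %s", conditionMessage(e)))
    if (is.character(ins)) { skipped[[nm]] <- ins; next }
    g <- tryCatch(gsmr_fit(ins, heidi_p = heidi_p, ld_prune_r2 = clump_r2,
                           exposure = nm,
                           outcome = attr(outcome, "trait_name")),
                  error = function(e) NULL)
    if (is.null(g)) { skipped[[nm]] <- "skipped: gsmr failed"; next }
    surv <- ins$data$snp %in% g$snps_used
    sens_ins <- instrument_set(ins$data[surv, , drop = FALSE],
                               ins$ld[surv, surv, drop = FALSE])
    iv <- tryCatch(ivw_fit(sens_ins, nm), error = function(e) NULL)
    eg <- tryCatch(egger_fit(sens_ins, nm), error = function(e) NULL)
    rows[[nm]] <- data.frame(
      exposure = nm, bxy = g$bxy, se = g$se, pval = g$pval,
      n_snps = g$n_snps_used, n_heidi_removed = length(g$removed_by_heidi),
      bxy_ivw = if (is.null(iv)) NA_real_ else iv$bxy,
      se_ivw = if (is.null(iv)) NA_real_ else iv$se,
      p_ivw = if (is.null(iv)) NA_real_ else iv$pval,
      Q_ivw = if (is.null(iv)) NA_real_ else iv$Q,
      bxy_egger = if (is.null(eg)) NA_real_ else eg$bxy,
      se_egger = if (is.null(eg)) NA_real_ else eg$se,
      p_egger = if (is.null(eg)) NA_real_ else eg$pval,
      egger_intercept = if (is.null(eg)) NA_real_ else eg$egger_intercept,
      intercept_p = if (is.null(eg)) NA_real_ else eg$intercept_p,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(exposure = character(0), bxy = numeric(0), se = numeric(0),
               pval = numeric(0), n_snps = integer(0))
  rownames(out) <- NULL
  if (nrow(out)) out$q_fdr <- stats::p.adjust(out$pval, method = "BH")
  attr(out, "skipped") <- skipped
  class(out) <- c("mr_panel_result", "data.frame")
  out
}

#' @export
print.mr_panel_result <- function(x, ...) {
  cat(sprintf("MR panel: %d exposures tested, %d skipped, %d with q < 0.05\n",
              nrow(x), length(attr(x, "skipped")),
              if (nrow(x)) sum(x$q_fdr < 0.05) else 0L))
  print(utils::head(as.data.frame(x)[, c("exposure", "bxy", "se", "pval",
                                         "q_fdr", "n_snps")], 10L))
  invisible(x)
}

#' Concordance of causal estimates across two outcome panels
#'
#' Joins two panel result tables on exposure name and reports the number of
#' shared exposures, the fraction with agreeing effect sign, and the Pearson
#' correlation of the estimates.
#'
#' @param results_a,results_b `mr_panel_result` data frames.
#' @return list with `n_shared`, `direction_agreement`, `pearson_r`.
#' @export
concordance <- function(results_a, results_b) {
  shared <- intersect(results_a$exposure, results_b$exposure)
  if (length(shared) < 3)
    stop("concordance: fewer than 3 shared exposures")
  a <- results_a$bxy[match(shared, results_a$exposure)]
  b <- results_b$bxy[match(shared, results_b$exposure)]
  list(n_shared = length(shared),
       direction_agreement = mean(sign(a) == sign(b)),
       pearson_r = stats::cor(a, b))
}
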