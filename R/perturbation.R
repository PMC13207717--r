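## Differential lipid abundance for the cell-stress experiment (condition
## contrasts with a batch covariate), cortisol-reversal summary, and the
## within-batch permutation overlap test against MR hits.

#' Construct a samples x lipid-features abundance matrix
#'
#' @param abundances numeric matrix, samples x features (absolute
#'   quantification, pmol; `NA` = missing).
#' @param condition factor/character per sample (e.g. `control`, `cortisol`,
#'   `cortisol_ze10`, `cortisol_ze25`, `cortisol_ze50`).
#' @param batch batch id per sample.
#' @param feature_names lipid species names (defaults to column names).
#' @return a `lipid_matrix`.
#' @export
lipid_matrix <- function(abundances, condition, batch,
                         feature_names = colnames(abundances)) {
  stopifnot(is.matrix(abundances),
            length(condition) == nrow(abundances),
            length(batch) == nrow(abundances))
  if (is.null(feature_names))
    feature_names <- paste0("feature_", seq_len(ncol(abundances)))
  if (any(abundances < 0, na.rm = TRUE))
    stop("lipid_matrix: abundances must be non-negative where present")
  colnames(abundances) <- feature_names
  structure(list(abundances = abundances,
                 condition = as.character(condition),
                 batch = as.character(batch),
                 feature_names = feature_names),
            class = "lipid_matrix")
}

#' @export
print.lipid_matrix <- function(x, ...) {
  cat(sprintf("Lipid matrix: %d samples x %d features; conditions: %s; %d batch(es)\n",
              nrow(x$abundances), ncol(x$abundances),
              paste(sort(unique(x$condition)), collapse = ", "),
              length(unique(x$batch))))
  invisible(x)
}

#' Missingness filter and zero imputation
#'
#' Features missing in more than `max_missing` of samples (strictly greater)
#' are dropped; remaining missing values are imputed as zero (levels below
#' detection).
#'
#' @param matrix a `lipid_matrix`.
#' @param max_missing maximum tolerated missing fraction (default 0.5).
#' @return filtered `lipid_matrix`; dropped feature names in the
#'   `dropped_features` attribute.
#' @export
filter_and_impute <- function(matrix, max_missing = 0.5) {
  A <- matrix$abundances
  frac <- colMeans(is.na(A))
  drop <- frac > max_missing
  A <- A[, !drop, drop = FALSE]
  A[is.na(A)] <- 0
  out <- lipid_matrix(A, matrix$condition, matrix$batch,
                      matrix$feature_names[!drop])
  attr(out, "dropped_features") <- matrix$feature_names[drop]
  out
}

## One weighted-none least-squares fit of all features at once on the design
## intercept + condition dummies + batch dummies; returns contrast estimate,
## se and t-based p per feature for condition a minus condition b.
.fit_contrast <- function(A, condition, batch, cond_a, cond_b) {
  condition <- factor(condition)
  batch <- factor(batch)
  if (!all(c(cond_a, cond_b) %in% levels(condition)))
    stop("differential: contrast level(s) absent: ",
         paste(setdiff(c(cond_a, cond_b), levels(condition)), collapse = ", "))
  X <- stats::model.matrix(~ condition + batch)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    ## the design only holds condition and batch terms, so any rank
    ## deficiency means the two are aliased (confounded design)
    alias <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("differential: confounded design, condition aliased with batch: ",
         paste(alias, collapse = ", "))
  }
  cvec <- numeric(ncol(X))
  names(cvec) <- colnames(X)
  term_a <- paste0("condition", cond_a)
  term_b <- paste0("condition", cond_b)
  if (term_a %in% names(cvec)) cvec[term_a] <- 1
  if (term_b %in% names(cvec)) cvec[term_b] <- -1
  coefs <- qr.coef(qrX, A)                       # p x features
  res <- A - X %*% coefs
  df <- nrow(X) - qrX$rank
  if (df < 1) stop("differential: no residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  cvar <- drop(t(cvec) %*% XtXinv %*% cvec)
  est <- drop(crossprod(cvec, coefs))
  se <- sqrt(cvar * sigma2)
  tt <- est / se
  p <- 2 * stats::pt(-abs(tt), df)
  data.frame(feature = colnames(A), estimate = est, se = se, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential lipid abundance with a batch covariate
#'
#' Per feature, least squares of abundance (analysis on the raw
#' quantification scale) on condition indicators plus batch indicators; each
#' requested contrast (condition a minus condition b) gets an estimate,
#' standard error, t-based p-value and a Benjamini-Hochberg q-value computed
#' within that contrast across all features.  A log2 fold-change of
#' condition means is attached for reporting.
#'
#' @param matrix a `lipid_matrix` (complete; run [filter_and_impute()]
#'   first).
#' @param contrasts list of length-2 character vectors `c(cond_a, cond_b)`.
#' @return data frame: `contrast`, `feature`, `estimate`, `se`, `p`, `q`,
#'   `direction`, `log2fc`.
#' @export
differential <- function(matrix, contrasts) {
  A <- matrix$abundances
  if (anyNA(A)) stop("differential: missing values present; run filter_and_impute()")
  for (ct in contrasts) {
    n_a <- sum(matrix$condition == ct[1L]); n_b <- sum(matrix$condition == ct[2L])
    if (n_a < 2 || n_b < 2)
      stop("differential: contrast ", ct[1L], ":", ct[2L],
           " needs >= 2 samples per condition")
  }
  out <- lapply(contrasts, function(ct) {
    r <- .fit_contrast(A, matrix$condition, matrix$batch, ct[1L], ct[2L])
    r$q <- stats::p.adjust(r$p, method = "BH")
    r$direction <- sign(r$estimate)
    mu_a <- colMeans(A[matrix$condition == ct[1L], , drop = FALSE])
    mu_b <- colMeans(A[matrix$condition == ct[2L], , drop = FALSE])
    r$log2fc <- log2(mu_a / mu_b)
    cbind(contrast = paste(ct[1L], ct[2L], sep = ":"), r,
          stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cortisol-reversal summary
#'
#' Counts features significantly down under the cortisol contrast and, among
#' them, those significantly changed in the opposite (positive) direction in
#' the co-treatment contrast.
#'
#' @param diff_cortisol,diff_ze single-contrast slices of [differential()]
#'   output over the same feature set.
#' @param q_threshold significance threshold (default 0.05).
#' @return list `n_down_cortisol`, `n_reversed`, `fraction` (`NA` when no
#'   feature is down).
#' @export
reversal_summary <- function(diff_cortisol, diff_ze, q_threshold = 0.05) {
  stopifnot(setequal(diff_cortisol$feature, diff_ze$feature))
  down <- diff_cortisol$feature[diff_cortisol$q < q_threshold &
                                  diff_cortisol$estimate < 0]
  ze <- diff_ze[match(down, diff_ze$feature), , drop = FALSE]
  rev <- down[ze$q < q_threshold & ze$estimate > 0]
  list(n_down_cortisol = length(down), n_reversed = length(rev),
       fraction = if (length(down)) length(rev) / length(down) else NA_real_)
}

## Shuffle condition labels independently within each batch.
.shuffle_within_batch <- function(condition, batch) {
  out <- condition
  for (b in unique(batch)) {
    i <- which(batch == b)
    out[i] <- condition[i][sample.int(length(i))]
  }
  out
}

#' Permutation overlap test between differential lipids and MR hits
#'
#' Observed statistic: the features significant (`q < q_threshold`) in the
#' real contrast are mapped to the GWAS panel's species names
#' ([map_species()], sum-composition matching enabled) and intersected with
#' the MR hit list.  Each permutation shuffles condition labels
#' independently within each batch, refits all features, ranks by contrast
#' p-value ascending (ties: larger `|estimate|` first, then feature name),
#' takes the top N (N = the observed significant count), maps, and counts
#' the overlap.  The empirical p-value is the fraction of permutations with
#' overlap greater than or equal to the observed one (`count/n_perm`;
#' `add_one = TRUE` gives `(count+1)/(n_perm+1)`).
#'
#' @param matrix a complete `lipid_matrix` with at least 2 conditions per
#'   batch.
#' @param contrast length-2 character vector `c(cond_a, cond_b)`.
#' @param gsmr_hits character vector of MR hit species names (GWAS panel
#'   naming).
#' @param gwas_panel_names species names of the GWAS exposure panel.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutation stream.
#' @param q_threshold significance threshold for the observed N.
#' @param add_one report `(count+1)/(n_perm+1)` instead of `count/n_perm`.
#' @return list: `observed_n_significant`, `observed_overlap`,
#'   `empirical_p`, `perm_overlaps`.
#' @export
overlap_permutation <- function(matrix, contrast, gsmr_hits, gwas_panel_names,
                                n_perm = 1000, seed = 1, q_threshold = 0.05,
                                add_one = FALSE) {
  A <- matrix$abundances
  if (anyNA(A)) stop("overlap_permutation: run filter_and_impute() first")
  for (b in unique(matrix$batch)) {
    if (length(unique(matrix$condition[matrix$batch == b])) < 2)
      stop("overlap_permutation: batch ", b, " has a single condition")
  }
  obs <- .fit_contrast(A, matrix$condition, matrix$batch,
                       contrast[1L], contrast[2L])
  obs$q <- stats::p.adjust(obs$p, method = "BH")
  sig <- obs$feature[obs$q < q_threshold]
  N <- length(sig)

  ## species mapping is label-independent, so map every feature once
  mp_all <- map_species(matrix$feature_names, gwas_panel_names,
                        allow_sum_composition = TRUE)
  mp_hit <- mp_all[mp_all$name_b %in% gsmr_hits, , drop = FALSE]
  hits_by_feature <- split(mp_hit$name_b, mp_hit$name_a)
  count_hits <- function(features) {
    length(unique(unlist(hits_by_feature[intersect(features,
                                                   names(hits_by_feature))],
                         use.names = FALSE)))
  }
  observed_overlap <- count_hits(sig)

  perm_overlaps <- integer(n_perm)
  if (N > 0) {
    set.seed(seed)
    for (k in seq_len(n_perm)) {
      cond_k <- .shuffle_within_batch(matrix$condition, matrix$batch)
      pr <- .fit_contrast(A, cond_k, matrix$batch, contrast[1L], contrast[2L])
      top <- pr$feature[order(pr$p, -abs(pr$estimate), pr$feature)][seq_len(N)]
      perm_overlaps[k] <- count_hits(top)
    }
  }
  count <- sum(perm_overlaps >= observed_overlap)
  p <- if (N == 0) 1 else if (add_one) (count + 1) / (n_perm + 1) else count / n_perm
  list(observed_n_significant = N, observed_overlap = observed_overlap,
       empirical_p = p, perm_overlaps = perm_overlaps)
}
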