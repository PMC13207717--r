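## Bayesian colocalization via approximate Bayes factors: per-region
## posteriors over the five sharing hypotheses, region construction around
## exposure index SNPs, interval merging, and 95% credible sets.

#' Colocalization priors
#'
#' `p1`/`p2` are the per-variant prior probabilities of causality for trait
#' 1 / trait 2, `p12` the prior of joint causality; `W1`/`W2` the prior
#' effect-size variances (0.15^2 for a quantitative trait, 0.2^2 for a
#' binary trait on the log-odds scale).
#'
#' @param p1,p2,p12 prior probabilities.
#' @param W1,W2 prior effect variances.
#' @return a `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         W1 = 0.15^2, W2 = 0.2^2) {
  stopifnot(p12 > 0, p12 <= min(p1, p2), p1 + p2 + p12 < 1, W1 > 0, W2 > 0)
  structure(list(p1 = p1, p2 = p2, p12 = p12, W1 = W1, W2 = W2),
            class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' `r = W/(W + se^2)`; `lABF = 0.5 * (log(1 - r) + r z^2)` with `z =
#' beta/se`.  Vectorized.
#'
#' @param beta,se effect estimate and standard error (`se > 0`).
#' @param W prior effect variance.
#' @return numeric vector of log ABFs.
#' @export
labf <- function(beta, se, W) {
  stopifnot(all(se > 0), W > 0)
  r <- W / (W + se^2)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Colocalization posteriors for one region
#'
#' Computes PPH0-PPH4 from per-variant approximate Bayes factors for the two
#' traits over the variants shared in the region (intersection analysis;
#' one-sided variants are dropped and counted).  All sums are done in log
#' space; the H3 mass `S1*S2 - S12` is evaluated via a log-space complement
#' and clamped at zero (with a warning) if cancellation makes it negative.
#'
#' @param trait1,trait2 `gwas_table` slices over one region, harmonized to a
#'   common allele orientation.
#' @param priors a [coloc_priors()]; `W1`/`W2` default from each table's
#'   `trait_type` when `priors` is `NULL`.
#' @param pph4_strong,pph4_suggestive evidence-tier thresholds.
#' @param candidate_threshold per-SNP H4 posterior threshold for candidate
#'   variants (default 0.01).
#' @return a `coloc_region` list: `pph` (named 5-vector summing to 1),
#'   `snp_posteriors` (per-variant H4 posterior, sums to 1), `credible_set`,
#'   `candidate_variants`, `evidence_tier`, `n_snps`, `n_dropped`.
#' @export
coloc_abf <- function(trait1, trait2, priors = NULL,
                      pph4_strong = 0.8, pph4_suggestive = 0.5,
                      candidate_threshold = 0.01) {
  if (is.null(priors)) {
    Wof <- function(tab) if (identical(attr(tab, "trait_type"), "binary"))
      0.2^2 else 0.15^2
    priors <- coloc_priors(W1 = Wof(trait1), W2 = Wof(trait2))
  }
  shared <- intersect(trait1$snp, trait2$snp)
  n_dropped <- length(union(trait1$snp, trait2$snp)) - length(shared)
  if (length(shared) < 2) stop("coloc_abf: fewer than 2 shared variants")
  t1 <- as.data.frame(trait1)[match(shared, trait1$snp), ]
  t2 <- as.data.frame(trait2)[match(shared, trait2$snp), ]
  l1 <- labf(t1$beta, t1$se, priors$W1)
  l2 <- labf(t2$beta, t2$se, priors$W2)

  ls1 <- .logsumexp(l1)          # log S1
  ls2 <- .logsumexp(l2)          # log S2
  ls12 <- .logsumexp(l1 + l2)    # log S12
  ## log(S1*S2 - S12) via complement
  dd <- ls12 - (ls1 + ls2)
  if (dd >= 0) {
    if (dd > 1e-12) warning("coloc_abf: negative H3 mass clamped to 0")
    lh3 <- -Inf
  } else lh3 <- ls1 + ls2 + log1p(-exp(dd))

  lL <- c(h0 = 0,
          h1 = log(priors$p1) + ls1,
          h2 = log(priors$p2) + ls2,
          h3 = log(priors$p1) + log(priors$p2) + lh3,
          h4 = log(priors$p12) + ls12)
  lden <- .logsumexp(lL)
  pph <- exp(lL - lden)
  names(pph) <- paste0("PPH", 0:4)

  snp_post <- exp(l1 + l2 - ls12)
  names(snp_post) <- shared
  cs <- credible_set(snp_post, pos = t1$pos, mass = 0.95)
  tier <- if (pph[["PPH4"]] > pph4_strong) "strong"
          else if (pph[["PPH4"]] > pph4_suggestive) "suggestive" else "none"
  structure(list(pph = pph, snp_posteriors = snp_post,
                 credible_set = cs,
                 candidate_variants = shared[snp_post > candidate_threshold],
                 evidence_tier = tier, n_snps = length(shared),
                 n_dropped = n_dropped, priors = priors),
            class = "coloc_region")
}

#' @export
print.coloc_region <- function(x, ...) {
  cat(sprintf("Colocalization over %d shared variants (tier: %s)\n",
              x$n_snps, x$evidence_tier))
  print(round(x$pph, 4))
  cat(sprintf("95%% credible set: %d variant(s)\n", length(x$credible_set)))
  invisible(x)
}

#' Define colocalization regions around exposure index SNPs
#'
#' Index SNPs come from clumping the exposure associations (`p <
#' p_threshold`, `r^2 < clump_r2` within `clump_window`); each yields the
#' region `[pos - flank, pos + flank]` clipped at 1 (1-based, inclusive).
#'
#' @param exposure a `gwas_table`.
#' @param panel an `ld_panel`.
#' @param p_threshold,clump_r2,clump_window clumping parameters (defaults
#'   `1e-6`, `0.1`, 500 kb).
#' @param flank half-width of each region (default 250 kb).
#' @return data frame with `chrom`, `start`, `end`, `index`.
#' @export
define_regions <- function(exposure, panel, p_threshold = 1e-6,
                           clump_r2 = 0.1, clump_window = 5e5, flank = 2.5e5) {
  d <- as.data.frame(exposure)
  d <- d[d$snp %in% panel$map$snp, , drop = FALSE]
  if (!nrow(d)) return(data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0), index = character(0)))
  idx <- clump(d, panel, p_threshold = p_threshold, r2_threshold = clump_r2,
               window_bp = clump_window)
  if (!length(idx)) return(data.frame(chrom = character(0), start = numeric(0),
                                      end = numeric(0), index = character(0)))
  pos <- d$pos[match(idx, d$snp)]
  data.frame(chrom = d$chr[match(idx, d$snp)],
             start = pmax(1, pos - flank), end = pos + flank,
             index = idx, stringsAsFactors = FALSE)
}

#' Merge overlapping regions into loci
#'
#' Standard interval union on 1-based inclusive intervals over the integer
#' line: overlapping, touching, or integer-adjacent intervals (no uncovered
#' base between them) merge.  Each merged locus records its contributing members
#' and, when members carry a `pph4` column, the locus tier is the best
#' member tier.
#'
#' @param regions data frame with `chrom`, `start`, `end` and optionally
#'   `exposure` and `pph4`.
#' @param pph4_strong,pph4_suggestive tier thresholds.
#' @return data frame of merged loci with a `members` list-column and
#'   `n_members`; plus `best_pph4` and `tier` when `pph4` was supplied.
#' @export
merge_regions <- function(regions, pph4_strong = 0.8, pph4_suggestive = 0.5) {
  if (!nrow(regions)) return(regions)
  out <- list()
  for (ch in unique(regions$chrom)) {
    rr <- regions[regions$chrom == ch, , drop = FALSE]
    rr <- rr[order(rr$start, rr$end), , drop = FALSE]
    cur_start <- rr$start[1L]; cur_end <- rr$end[1L]; cur_members <- list(rr[1L, ])
    flush <- function() {
      mem <- do.call(rbind, cur_members)
      loc <- data.frame(chrom = ch, start = cur_start, end = cur_end,
                        n_members = nrow(mem), stringsAsFactors = FALSE)
      if ("pph4" %in% names(mem)) {
        loc$best_pph4 <- max(mem$pph4)
        loc$tier <- if (loc$best_pph4 > pph4_strong) "strong"
                    else if (loc$best_pph4 > pph4_suggestive) "suggestive"
                    else "none"
      }
      loc$members <- I(list(mem))
      loc
    }
    for (i in seq_len(nrow(rr))[-1L]) {
      if (rr$start[i] <= cur_end + 1) {  # touching or integer-adjacent merges
        cur_end <- max(cur_end, rr$end[i])
        cur_members <- c(cur_members, list(rr[i, ]))
      } else {
        out[[length(out) + 1L]] <- flush()
        cur_start <- rr$start[i]; cur_end <- rr$end[i]
        cur_members <- list(rr[i, ])
      }
    }
    out[[length(out) + 1L]] <- flush()
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' 95% credible set from per-SNP posteriors
#'
#' Sorts posteriors descending (ties broken by ascending position) and takes
#' the minimal prefix whose cumulative mass reaches `mass`.
#'
#' @param snp_posteriors named numeric vector summing to 1.
#' @param pos positions for tie-breaking (same order); optional.
#' @param mass target cumulative mass (default 0.95).
#' @return character vector of variant ids.
#' @export
credible_set <- function(snp_posteriors, pos = seq_along(snp_posteriors),
                         mass = 0.95) {
  stopifnot(abs(sum(snp_posteriors) - 1) < 1e-6)
  if (is.null(names(snp_posteriors)))
    names(snp_posteriors) <- as.character(seq_along(snp_posteriors))
  o <- order(-snp_posteriors, pos)
  cum <- cumsum(snp_posteriors[o])
  k <- which(cum >= mass - 1e-12)[1L]
  names(snp_posteriors)[o[seq_len(k)]]
}

#' Convert 1-based inclusive intervals to BED (0-based half-open)
#' @param regions data frame with `chrom`, `start`, `end` (1-based inclusive).
#' @return data frame with BED `chrom`, `start`, `end`.
#' @export
to_bed <- function(regions) {
  data.frame(chrom = regions$chrom, start = regions$start - 1L,
             end = regions$end, stringsAsFactors = FALSE)
}
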