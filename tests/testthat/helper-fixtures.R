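# Small in-code fixtures and independent oracles shared across tests.

# Minimal gwas_table from parallel vectors (defaults fill the rest).
mk_gwas <- function(snp, beta, se, chr = "1", pos = seq_along(snp) * 1000,
                    ea = "A", oa = "G", eaf = 0.3, p = NA_real_,
                    n = 1e4, trait_name = "t", trait_type = "quantitative") {
  gwas_table(data.frame(snp = snp, chr = chr, pos = pos, ea = ea, oa = oa,
                        eaf = eaf, beta = beta, se = se, p = p, n = n,
                        stringsAsFactors = FALSE),
             trait_name = trait_name, trait_type = trait_type)
}

# Instrument set with identity LD unless an LD matrix is supplied.
mk_instruments <- function(bzx, se_zx, bzy, se_zy, ld = NULL,
                           pos = seq_along(bzx) * 1000) {
  k <- length(bzx)
  ids <- sprintf("v%02d", seq_len(k))
  if (is.null(ld)) ld <- diag(k)
  dimnames(ld) <- list(ids, ids)
  instrument_set(data.frame(snp = ids, chr = "1", pos = pos,
                            bzx = bzx, se_zx = se_zx,
                            p_zx = 2 * pnorm(-abs(bzx / se_zx)),
                            bzy = bzy, se_zy = se_zy,
                            stringsAsFactors = FALSE),
                 ld)
}

# Brute-force greedy clumping oracle: identical rule, explicit set operations.
clump_oracle <- function(d, r2, p_threshold, r2_threshold, window_bp) {
  cand <- d[!is.na(d$p) & d$p < p_threshold, , drop = FALSE]
  cand <- cand[order(cand$p, cand$pos, cand$snp), , drop = FALSE]
  remaining <- cand$snp
  selected <- character(0)
  while (length(remaining)) {
    idx <- remaining[1L]
    selected <- c(selected, idx)
    remaining <- setdiff(remaining, idx)
    i <- match(idx, cand$snp)
    drop <- vapply(remaining, function(s) {
      j <- match(s, cand$snp)
      cand$chr[j] == cand$chr[i] &&
        abs(cand$pos[j] - cand$pos[i]) <= window_bp &&
        r2[cand$snp[j], idx] >= r2_threshold
    }, logical(1))
    remaining <- remaining[!drop]
  }
  selected
}

# Benjamini-Hochberg oracle: over all 2^m candidate rejection sets, the
# largest set R satisfying the BH inequality max(p[R]) <= alpha * |R| / m
# (every rejected p must sit below the step-up line for the attained size).
bh_reject_oracle <- function(p, alpha) {
  m <- length(p)
  best <- integer(0)
  for (mask in 0:(2^m - 1)) {
    set <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    k <- length(set)
    if (k <= length(best)) next
    if (max(p[set]) <= alpha * k / m) best <- set
  }
  best
}

# Exact two-sided Fisher p by full enumeration of tables with the observed
# margins: sum of hypergeometric probabilities <= the observed one.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, n - r1, c1)
  obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Interval union oracle over the integer line (1-based inclusive).
merge_oracle <- function(start, end) {
  covered <- sort(unique(unlist(mapply(seq, start, end, SIMPLIFY = FALSE))))
  breaks <- which(diff(covered) > 1)
  starts <- covered[c(1, breaks + 1)]
  ends <- covered[c(breaks, length(covered))]
  data.frame(start = starts, end = ends)
}
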