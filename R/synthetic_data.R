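## Synthetic-data generators with known ground truth for every pipeline
## input: block-LD reference panels, exposure/outcome GWAS summary-statistic
## pairs under configurable causal and pleiotropic architectures, PBMC-style
## lipid matrices, and cohort tables.
##
## Summary statistics are simulated directly at the marginal level (in
## standardized-genotype space, then converted to per-allele scale), with
## estimation noise correlated within LD blocks exactly as LD induces in
## reality; the reference panel doubles as the population, so the LD used by
## the estimators is the LD that generated the data.

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' A deterministic universe of valid lipid species names
#'
#' Roughly 600 names spanning the classes CE, DAG, DE, LPC, LPE, PC, PE, PI,
#' SM and TAG, mixing fully chain-resolved, sum-composition, ether (O-/P-)
#' and hydroxylated (`;O2`) forms, all parsable by [parse_species()].
#'
#' @param n optionally truncate to the first `n` names.
#' @return character vector of species names.
#' @export
lipid_name_universe <- function(n = NULL) {
  fa <- c("14:0", "15:0", "16:0", "16:1", "17:0", "18:0", "18:1", "18:2",
          "18:3", "20:3", "20:4", "20:5", "22:4", "22:5", "22:6")
  sn1 <- c("16:0", "16:1", "17:0", "18:0", "18:1", "18:2")
  out <- character(0)
  for (f in fa) out <- c(out, sprintf("CE(%s)", f), sprintf("DE(%s)", f),
                         sprintf("LPC(%s)", f), sprintf("LPE(%s)", f))
  for (a in sn1) for (f in fa)
    out <- c(out, sprintf("PC(%s/%s)", a, f), sprintf("PE(%s/%s)", a, f),
             sprintf("PI(%s/%s)", a, f), sprintf("DAG(%s/%s)", a, f))
  for (a in c("O-16:0", "O-18:1", "P-16:0", "P-18:0"))
    for (f in c("18:2", "20:3", "20:4", "22:5"))
      out <- c(out, sprintf("PC(%s/%s)", a, f), sprintf("PE(%s/%s)", a, f))
  for (tot in seq(30, 44, 2)) for (db in 0:4)
    out <- c(out, sprintf("SM %d:%d;O2", tot, db))
  for (tot in seq(44, 58, 2)) for (db in 0:4)
    out <- c(out, sprintf("TAG %d:%d", tot, db))
  out <- unique(out)
  if (!is.null(n)) out <- out[seq_len(min(n, length(out)))]
  out
}

#' Simulate a block-LD reference panel
#'
#' Per block, latent Gaussians with AR-1 correlation `rho^|i-j|`; each
#' haplotype is an independent draw thresholded at the variant's MAF
#' quantile, and the dosage is the sum of two haplotypes.  Blocks are
#' mutually independent.  Variants sit on one chromosome at fixed spacing
#' with a configurable gap between blocks.
#'
#' @param n_blocks number of LD blocks.
#' @param block_size variants per block.
#' @param within_block_rho AR-1 latent correlation in `[0, 1)`.
#' @param n_individuals diploid sample size.
#' @param maf_range minor-allele-frequency range, within `(0, 0.5]`.
#' @param seed RNG seed.
#' @param chrom chromosome label (default `"1"`).
#' @param spacing_bp within-block variant spacing (default 5 kb).
#' @param gap_bp gap between blocks (default 1 Mb).
#' @return an `ld_panel`; the `block` assignment is kept in the map.
#' @export
make_ld_panel <- function(n_blocks, block_size, within_block_rho = 0.8,
                          n_individuals = 2000, maf_range = c(0.1, 0.5),
                          seed = 1, chrom = "1", spacing_bp = 5000,
                          gap_bp = 1e6) {
  stopifnot(within_block_rho >= 0, within_block_rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  .with_seed(seed, {
    m <- n_blocks * block_size
    maf <- stats::runif(m, maf_range[1], maf_range[2])
    ## AR-1 latent draw: x_1 ~ N(0,1); x_j = rho x_{j-1} + sqrt(1-rho^2) e_j
    draw_block_latent <- function(n, k, rho) {
      x <- matrix(stats::rnorm(n * k), n, k)
      if (rho > 0 && k > 1) {
        for (j in 2:k) x[, j] <- rho * x[, j - 1] + sqrt(1 - rho^2) * x[, j]
      }
      x
    }
    dos <- matrix(0L, n_individuals, m)
    for (b in seq_len(n_blocks)) {
      cols <- ((b - 1) * block_size + 1):(b * block_size)
      thr <- stats::qnorm(maf[cols])
      h1 <- draw_block_latent(n_individuals, block_size, within_block_rho)
      h2 <- draw_block_latent(n_individuals, block_size, within_block_rho)
      dos[, cols] <- (sweep(h1, 2, thr, "<") + sweep(h2, 2, thr, "<"))
    }
    block <- rep(seq_len(n_blocks), each = block_size)
    within <- rep(seq_len(block_size), n_blocks)
    pos <- (block - 1) * (block_size * spacing_bp + gap_bp) +
      within * spacing_bp
    map <- data.frame(snp = sprintf("snp_%05d", seq_len(m)),
                      chr = chrom, pos = pos,
                      ea = "A", oa = "G", block = block,
                      stringsAsFactors = FALSE)
    storage.mode(dos) <- "double"
    panel <- ld_panel(map, dos)
    panel$blocks <- .panel_block_info(ld_panel(map, dos))
    panel
  })
}

## Per-block empirical correlation matrices (ridge-stabilized cholesky),
## cached on the panel after first computation.
.panel_block_info <- function(panel) {
  if (!is.null(panel$blocks)) return(panel$blocks)
  stopifnot("block" %in% names(panel$map))
  blocks <- unique(panel$map$block)
  lapply(blocks, function(b) {
    idx <- which(panel$map$block == b)
    R <- stats::cor(panel$dosages[, idx, drop = FALSE])
    R <- (R + t(R)) / 2
    ch <- tryCatch(chol(R), error = function(e)
      chol(R + diag(1e-6, nrow(R))))
    list(idx = idx, R = R, chol = ch)
  })
}

#' Simulate a two-sample GWAS pair with known causal effect
#'
#' Exposure causal effects are planted one per block (cycling) with equal
#' per-variant explained variance summing to `h2_exposure`; marginal effects
#' follow the block LD, and estimation noise is drawn with the same
#' within-block correlation at standard errors `1/sqrt(2 n maf (1-maf))`.
#' The outcome's marginal effects are `bxy_true` times the exposure
#' marginals plus LD-propagated direct (pleiotropic) effects on a subset of
#' the causal variants, observed with noise at `n_outcome`.
#'
#' Pleiotropic direct effects are `Normal(0, alpha_sd)` per-allele, or of
#' fixed magnitude `alpha_mag` with random sign when `alpha_mag` is given
#' (guaranteeing every planted effect is a genuine outlier).
#'
#' @param panel an `ld_panel` from [make_ld_panel()].
#' @param n_causal causal variant count (at most `n_blocks`).
#' @param h2_exposure exposure variance explained by the causal set.
#' @param bxy_true causal effect of exposure on outcome (log-odds per SD).
#' @param n_pleiotropic how many causal variants also get direct outcome
#'   effects (default 0).
#' @param alpha_sd sd of Gaussian direct effects (per-allele scale).
#' @param alpha_mag fixed direct-effect magnitude (overrides `alpha_sd`).
#' @param alpha_sign `"random"` (balanced on average) or `"positive"`
#'   (directional pleiotropy, all direct effects `+alpha_mag`).
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param seed RNG seed.
#' @param exposure_name,outcome_name trait labels.
#' @return list: `exposure` (`gwas_table`), `outcome` (`gwas_table`,
#'   binary), `truth` (causal ids/effects, pleiotropic ids/effects,
#'   `bxy_true`, seed).
#' @export
simulate_gwas_pair <- function(panel, n_causal = 30, h2_exposure = 0.05,
                               bxy_true = 0.1, n_pleiotropic = 0,
                               alpha_sd = 0, alpha_mag = NULL,
                               alpha_sign = c("random", "positive"),
                               n_exposure = 50000, n_outcome = 200000,
                               seed = 1,
                               exposure_name = "lipid",
                               outcome_name = "disease") {
  info <- .panel_block_info(panel)
  if (n_causal > length(info))
    stop("simulate_gwas_pair: n_causal exceeds the number of LD blocks")
  .with_seed(seed, {
    m <- nrow(panel$map)
    maf <- pmin(pmax(colMeans(panel$dosages) / 2, 1e-3), 1 - 1e-3)
    vscale <- sqrt(2 * maf * (1 - maf))  # per-allele -> standardized

    ## causal variants: middle of each of the first n_causal blocks
    causal <- vapply(info[seq_len(n_causal)],
                     function(bi) bi$idx[ceiling(length(bi$idx) / 2)],
                     integer(1))
    bstar <- numeric(m)  # standardized true effects
    bstar[causal] <- sample(c(-1, 1), n_causal, replace = TRUE) *
      sqrt(h2_exposure / n_causal)

    pleio <- integer(0); alpha <- numeric(m)
    alpha_sign <- match.arg(alpha_sign)
    if (n_pleiotropic > 0) {
      pleio <- sort(sample(causal, n_pleiotropic))
      a <- if (!is.null(alpha_mag)) {
        ## "positive" = directional pleiotropy: the direct effect has a
        ## consistent sign on the exposure-increasing allele
        sgn <- if (alpha_sign == "positive") sign(bstar[pleio])
               else sample(c(-1, 1), n_pleiotropic, replace = TRUE)
        alpha_mag * sgn
      } else stats::rnorm(n_pleiotropic, 0, alpha_sd)
      alpha[pleio] <- a  # per-allele direct outcome effects
    }
    astar <- alpha * vscale

    margx <- numeric(m); margy <- numeric(m)
    ex_noise <- numeric(m); ou_noise <- numeric(m)
    for (bi in info) {
      i <- bi$idx
      margx[i] <- bi$R %*% bstar[i]
      margy[i] <- bxy_true * margx[i] + bi$R %*% astar[i]
      k <- length(i)
      ex_noise[i] <- crossprod(bi$chol, stats::rnorm(k)) / sqrt(n_exposure)
      ou_noise[i] <- crossprod(bi$chol, stats::rnorm(k)) / sqrt(n_outcome)
    }
    bzx_star <- margx + ex_noise
    bzy_star <- margy + ou_noise
    se_x <- 1 / (sqrt(n_exposure) * vscale)
    se_y <- 1 / (sqrt(n_outcome) * vscale)

    base <- data.frame(snp = panel$map$snp, chr = panel$map$chr,
                       pos = panel$map$pos, ea = panel$map$ea,
                       oa = panel$map$oa, eaf = maf,
                       stringsAsFactors = FALSE)
    exposure <- gwas_table(cbind(base,
                                 beta = bzx_star / vscale, se = se_x,
                                 p = 2 * stats::pnorm(-abs(bzx_star) * sqrt(n_exposure)),
                                 n = n_exposure),
                           trait_name = exposure_name,
                           trait_type = "quantitative")
    outcome <- gwas_table(cbind(base,
                                beta = bzy_star / vscale, se = se_y,
                                p = 2 * stats::pnorm(-abs(bzy_star) * sqrt(n_outcome)),
                                n = n_outcome),
                          trait_name = outcome_name, trait_type = "binary")
    truth <- list(bxy_true = bxy_true,
                  causal_variants = panel$map$snp[causal],
                  causal_effects = bstar[causal] / vscale[causal],
                  pleiotropic_variants = panel$map$snp[pleio],
                  pleiotropic_effects = alpha[pleio],
                  h2_exposure = h2_exposure, master_seed = seed)
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Simulate a multi-exposure panel sharing one (or two) outcomes
#'
#' LD blocks are partitioned across exposures (disjoint causal
#' architectures); each exposure gets `n_causal_per_exposure` causal
#' variants and its own `bxy`.  The single outcome's marginals accumulate
#' every exposure's contribution.  When `bxy_b` is supplied a second outcome
#' is generated from the same exposure marginals (sharing the causal
#' component), for concordance analyses.
#'
#' @param panel `ld_panel` with at least
#'   `n_exposures * n_causal_per_exposure` blocks.
#' @param bxy named numeric vector: causal effect per exposure (names become
#'   exposure labels).
#' @param bxy_b optional second-outcome effects (same names).
#' @param n_causal_per_exposure causal variants per exposure.
#' @param h2_per_exposure variance explained per exposure.
#' @param n_exposure,n_outcome sample sizes.
#' @param seed RNG seed.
#' @return list: `exposures` (named list of `gwas_table`), `outcome`,
#'   optionally `outcome_b`, `truth`.
#' @export
simulate_mr_panel <- function(panel, bxy, bxy_b = NULL,
                              n_causal_per_exposure = 3,
                              h2_per_exposure = 0.02,
                              n_exposure = 50000, n_outcome = 200000,
                              seed = 1) {
  info <- .panel_block_info(panel)
  K <- length(bxy)
  if (is.null(names(bxy))) names(bxy) <- paste0("exposure_", seq_len(K))
  need <- K * n_causal_per_exposure
  if (need > length(info))
    stop("simulate_mr_panel: need ", need, " blocks, panel has ", length(info))
  .with_seed(seed, {
    m <- nrow(panel$map)
    maf <- pmin(pmax(colMeans(panel$dosages) / 2, 1e-3), 1 - 1e-3)
    vscale <- sqrt(2 * maf * (1 - maf))
    se_x <- 1 / (sqrt(n_exposure) * vscale)
    se_y <- 1 / (sqrt(n_outcome) * vscale)
    base <- data.frame(snp = panel$map$snp, chr = panel$map$chr,
                       pos = panel$map$pos, ea = panel$map$ea,
                       oa = panel$map$oa, eaf = maf,
                       stringsAsFactors = FALSE)
    block_noise <- function(n_eff) {
      e <- numeric(m)
      for (bi in info)
        e[bi$idx] <- crossprod(bi$chol, stats::rnorm(length(bi$idx))) /
          sqrt(n_eff)
      e
    }
    margx_list <- vector("list", K); names(margx_list) <- names(bxy)
    causal_ids <- vector("list", K); names(causal_ids) <- names(bxy)
    margy <- numeric(m); margy_b <- numeric(m)
    exposures <- list()
    for (k in seq_len(K)) {
      blocks_k <- info[((k - 1) * n_causal_per_exposure + 1):
                         (k * n_causal_per_exposure)]
      bstar <- numeric(m)
      cidx <- vapply(blocks_k,
                     function(bi) bi$idx[ceiling(length(bi$idx) / 2)],
                     integer(1))
      bstar[cidx] <- sample(c(-1, 1), length(cidx), replace = TRUE) *
        sqrt(h2_per_exposure / n_causal_per_exposure)
      margx <- numeric(m)
      for (bi in blocks_k) margx[bi$idx] <- bi$R %*% bstar[bi$idx]
      margx_list[[k]] <- margx
      causal_ids[[k]] <- panel$map$snp[cidx]
      margy <- margy + bxy[k] * margx
      if (!is.null(bxy_b)) margy_b <- margy_b + bxy_b[k] * margx
      bzx_star <- margx + block_noise(n_exposure)
      exposures[[names(bxy)[k]]] <-
        gwas_table(cbind(base, beta = bzx_star / vscale, se = se_x,
                         p = 2 * stats::pnorm(-abs(bzx_star) * sqrt(n_exposure)),
                         n = n_exposure),
                   trait_name = names(bxy)[k], trait_type = "quantitative")
    }
    make_outcome <- function(margy, nm) {
      bzy_star <- margy + block_noise(n_outcome)
      gwas_table(cbind(base, beta = bzy_star / vscale, se = se_y,
                       p = 2 * stats::pnorm(-abs(bzy_star) * sqrt(n_outcome)),
                       n = n_outcome),
                 trait_name = nm, trait_type = "binary")
    }
    out <- list(exposures = exposures,
                outcome = make_outcome(margy, "disease"),
                truth = list(bxy = bxy, bxy_b = bxy_b,
                             causal_variants = causal_ids,
                             master_seed = seed))
    if (!is.null(bxy_b)) out$outcome_b <- make_outcome(margy_b, "disease_b")
    out
  })
}

#' Simulate a colocalization region pair
#'
#' Two traits over one region.  Under `shared = TRUE` both traits have the
#' same causal variant; otherwise trait 2's causal variant sits in a
#' different, LD-independent block.  Marginal z-scores at the causal variant
#' are drawn uniformly from `z_range` (both traits), LD-propagated within
#' the block, and observed with LD-correlated noise.
#'
#' @param panel an `ld_panel` with `>= 2` blocks.
#' @param shared single shared causal variant (`TRUE`) or distinct variants
#'   (`FALSE`).
#' @param z_range range of the causal-variant |z| (default `c(8, 12)`).
#' @param n1,n2 effective sample sizes for the two traits.
#' @param seed RNG seed.
#' @return list: `trait1`, `trait2` (`gwas_table`s over the full panel),
#'   `causal1`, `causal2` (variant ids).
#' @export
simulate_coloc_pair <- function(panel, shared = TRUE, z_range = c(8, 12),
                                n1 = 50000, n2 = 200000, seed = 1) {
  info <- .panel_block_info(panel)
  stopifnot(length(info) >= 2)
  .with_seed(seed, {
    m <- nrow(panel$map)
    maf <- pmin(pmax(colMeans(panel$dosages) / 2, 1e-3), 1 - 1e-3)
    vscale <- sqrt(2 * maf * (1 - maf))
    c1 <- info[[1L]]$idx[ceiling(length(info[[1L]]$idx) / 2)]
    c2 <- if (shared) c1 else
      info[[2L]]$idx[ceiling(length(info[[2L]]$idx) / 2)]
    mk <- function(cidx, n_eff, nm, type) {
      z <- stats::runif(1, z_range[1], z_range[2]) * sample(c(-1, 1), 1)
      bstar <- numeric(m)
      bstar[cidx] <- z / sqrt(n_eff)
      marg <- numeric(m)
      noise <- numeric(m)
      for (bi in info) {
        marg[bi$idx] <- bi$R %*% bstar[bi$idx]
        noise[bi$idx] <- crossprod(bi$chol, stats::rnorm(length(bi$idx))) /
          sqrt(n_eff)
      }
      bhat <- marg + noise
      se <- 1 / (sqrt(n_eff) * vscale)
      gwas_table(data.frame(snp = panel$map$snp, chr = panel$map$chr,
                            pos = panel$map$pos, ea = panel$map$ea,
                            oa = panel$map$oa, eaf = maf,
                            beta = bhat / vscale, se = se,
                            p = 2 * stats::pnorm(-abs(bhat) * sqrt(n_eff)),
                            n = n_eff, stringsAsFactors = FALSE),
                 trait_name = nm, trait_type = type)
    }
    list(trait1 = mk(c1, n1, "lipid", "quantitative"),
         trait2 = mk(c2, n2, "disease", "binary"),
         causal1 = panel$map$snp[c1], causal2 = panel$map$snp[c2])
  })
}

#' Simulate a PBMC-style lipid perturbation experiment
#'
#' Five conditions (`control`, `cortisol`, `cortisol_ze10`, `cortisol_ze25`,
#' `cortisol_ze50`) across `n_batches` batches.  Baseline abundances are
#' log-normal per feature; additive per-feature batch offsets are
#' `Normal(0, batch_sd)`.  The first `n_down_cortisol` features get a
#' negative cortisol effect (applied to every cortisol-containing
#' condition), and the first `n_reversed` of those additionally get a
#' positive effect under `cortisol_ze50`.  Missingness is injected on a
#' random non-planted feature subset with an exact per-feature missing count
#' of `round(frac_missing * n_samples)` (so the `> max_missing` filter rule
#' is exercised deterministically).  Feature names come from
#' [lipid_name_universe()].
#'
#' @param n_batches batches (default 4).
#' @param samples_per_condition_per_batch default 1 (20 samples total).
#' @param n_features lipid features (default 500).
#' @param frac_missing per-feature missing fraction on the affected subset.
#' @param missing_feature_frac fraction of features affected by missingness.
#' @param n_down_cortisol features downregulated by cortisol (default 132).
#' @param n_reversed of those, features reversed by Ze 117 50 ug (default
#'   75).
#' @param effect_size mean absolute planted effect (pmol; default 4).
#' @param batch_sd sd of batch offsets (default 2).
#' @param noise_sd residual sd (default 1).
#' @param seed RNG seed.
#' @param feature_names optional explicit feature names (first
#'   `n_down_cortisol` of them receive the planted cortisol effects);
#'   defaults to a random draw from [lipid_name_universe()].
#' @return list: `matrix` (`lipid_matrix`), `truth` (planted feature names
#'   per effect, effect sizes, missing features, seed).
#' @export
simulate_pbmc <- function(n_batches = 4, samples_per_condition_per_batch = 1,
                          n_features = 500, frac_missing = 0.3,
                          missing_feature_frac = 0.2,
                          n_down_cortisol = 132, n_reversed = 75,
                          effect_size = 4, batch_sd = 2, noise_sd = 1,
                          seed = 1, feature_names = NULL) {
  stopifnot(n_reversed <= n_down_cortisol, n_down_cortisol <= n_features)
  conds <- c("control", "cortisol", "cortisol_ze10", "cortisol_ze25",
             "cortisol_ze50")
  .with_seed(seed, {
    condition <- rep(rep(conds, each = samples_per_condition_per_batch),
                     n_batches)
    batch <- rep(paste0("batch", seq_len(n_batches)),
                 each = length(conds) * samples_per_condition_per_batch)
    n_samples <- length(condition)
    features <- if (is.null(feature_names)) {
      universe <- lipid_name_universe()
      sample(universe, min(n_features, length(universe)))
    } else unique(feature_names)
    n_features <- length(features)
    stopifnot(n_down_cortisol <= n_features)

    baseline <- exp(stats::rnorm(n_features, 3, 0.5))
    A <- matrix(rep(baseline, each = n_samples), n_samples, n_features)
    ## per-feature, per-batch additive offsets (absorbed by the batch terms)
    for (b in unique(batch)) {
      off <- stats::rnorm(n_features, 0, batch_sd)
      A[batch == b, ] <- sweep(A[batch == b, , drop = FALSE], 2, off, "+")
    }
    down_idx <- seq_len(n_down_cortisol)
    rev_idx <- seq_len(n_reversed)
    eff_down <- -effect_size * stats::runif(n_down_cortisol, 0.8, 1.2)
    eff_rev <- effect_size * stats::runif(n_reversed, 0.8, 1.2)
    cort_rows <- condition != "control"
    A[cort_rows, down_idx] <- sweep(A[cort_rows, down_idx, drop = FALSE],
                                    2, eff_down, "+")
    ze_rows <- condition == "cortisol_ze50"
    A[ze_rows, rev_idx] <- sweep(A[ze_rows, rev_idx, drop = FALSE],
                                 2, eff_rev, "+")
    A <- A + matrix(stats::rnorm(n_samples * n_features, 0, noise_sd),
                    n_samples, n_features)
    A <- pmax(A, 0)

    ## exact-count MCAR missingness on a random non-planted feature subset
    n_missing_features <- round(missing_feature_frac * n_features)
    eligible <- setdiff(seq_len(n_features), down_idx)
    miss_feats <- sort(sample(eligible,
                              min(n_missing_features, length(eligible))))
    n_miss <- round(frac_missing * n_samples)
    for (j in miss_feats)
      A[sample.int(n_samples, n_miss), j] <- NA_real_

    mat <- lipid_matrix(A, condition, batch, features)
    truth <- list(down_features = features[down_idx],
                  reversed_features = features[rev_idx],
                  down_effects = eff_down, reversal_effects = eff_rev,
                  missing_features = features[miss_feats],
                  frac_missing = frac_missing, master_seed = seed)
    list(matrix = mat, truth = truth)
  })
}

#' Simulate a cohort table with lipid, symptoms, covariates and dosages
#'
#' Instrument-SNP dosages are independent binomials at `instrument_mafs`.
#' The lipid's non-covariate component `u` (unit variance on the log scale)
#' carries a genetic fraction `h2_score` through the polygenic score of the
#' instruments; the symptom score is a rounded non-negative transform of a
#' latent Gaussian with correlation `rho_lipid_symptom` to `u`, plus its own
#' covariate effects.  Lipid covariates: age, sex, center, batch, BMI;
#' symptom covariates: age, sex, wave.
#'
#' @param n_subjects cohort size (default 970).
#' @param rho_lipid_symptom planted partial correlation (default -0.08).
#' @param h2_score lipid variance explained by the polygenic score (default
#'   0.02).
#' @param instrument_betas per-SNP score weights.
#' @param instrument_mafs per-SNP allele frequencies (recycled).
#' @param seed RNG seed.
#' @return list: `table` (data frame), `dosages` (subjects x SNPs matrix),
#'   `truth`.
#' @export
simulate_cohort <- function(n_subjects = 970, rho_lipid_symptom = -0.08,
                            h2_score = 0.02,
                            instrument_betas = rep(0.1, 10),
                            instrument_mafs = 0.3, seed = 1) {
  stopifnot(abs(rho_lipid_symptom) < 1, h2_score >= 0, h2_score < 1)
  .with_seed(seed, {
    J <- length(instrument_betas)
    mafs <- rep_len(instrument_mafs, J)
    dos <- vapply(mafs, function(f) stats::rbinom(n_subjects, 2, f),
                  numeric(n_subjects))
    colnames(dos) <- paste0("snp_", seq_len(J))
    g <- polygenic_score(dos, instrument_betas)
    g_std <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else g * 0

    age <- stats::rnorm(n_subjects, 22, 2.5)
    sex <- stats::rbinom(n_subjects, 1, 0.64)
    center <- sample(paste0("center", 1:3), n_subjects, replace = TRUE)
    lbatch <- sample(paste0("batch", 1:4), n_subjects, replace = TRUE)
    bmi <- stats::rnorm(n_subjects, 23, 3)
    wave <- sample(paste0("wave", 1:2), n_subjects, replace = TRUE)

    u <- sqrt(h2_score) * g_std +
      sqrt(1 - h2_score) * stats::rnorm(n_subjects)
    center_eff <- c(center1 = 0, center2 = 0.1, center3 = -0.05)[center]
    batch_eff <- stats::setNames(c(0, 0.05, -0.05, 0.1),
                                 paste0("batch", 1:4))[lbatch]
    log_lipid <- 1.5 + 0.01 * (age - 22) + 0.1 * sex + center_eff +
      batch_eff + 0.02 * (bmi - 23) + 0.3 * u
    lipid <- exp(log_lipid)

    z <- rho_lipid_symptom * u +
      sqrt(1 - rho_lipid_symptom^2) * stats::rnorm(n_subjects)
    wave_eff <- c(wave1 = 0, wave2 = 0.5)[wave]
    latent <- 8 + 0.2 * (age - 22) + 1.0 * sex + wave_eff + 7 * z
    score <- as.integer(round(pmax(0, latent)))

    other_ce <- exp(stats::rnorm(n_subjects, 3, 0.3))
    tab <- data.frame(lipid_value = lipid,
                      total_class_value = lipid + other_ce,
                      symptom_score = score,
                      age = age, sex = sex, center = center,
                      batch = lbatch, bmi = bmi, wave = wave,
                      stringsAsFactors = FALSE)
    truth <- list(rho = rho_lipid_symptom, h2_score = h2_score,
                  instrument_betas = instrument_betas, master_seed = seed)
    list(table = tab, dosages = dos, truth = truth)
  })
}
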