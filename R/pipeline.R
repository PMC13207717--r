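## End-to-end orchestration on synthetic data: simulate -> MR panel -> masked
## rerun -> class enrichment -> colocalization -> PBMC differential + overlap
## -> cohort association, with a reproducibility manifest.

#' Default analysis thresholds
#'
#' The pipeline defaults: instrument threshold `p < 1e-6`, clumping
#' `r^2 < 0.1` within 10 Mb (500 kb for colocalization regions, with 250 kb
#' flanks), HEIDI `p < 0.01`, minimum 10 instruments (3 in relaxed mode),
#' FDR 0.05, colocalization tiers PPH4 > 0.8 (strong) / > 0.5 (suggestive),
#' outlier trim at 5 sd, 1000 permutations.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(p_threshold = 1e-6, clump_r2 = 0.1, clump_window = 1e7,
       coloc_clump_window = 5e5, coloc_flank = 2.5e5,
       heidi_p = 0.01, min_snps = 10, min_snps_relaxed = 3,
       fdr = 0.05, pph4_strong = 0.8, pph4_suggestive = 0.5,
       trim_sd = 5, n_perm = 1000)
}

#' Run the full demonstration pipeline on synthetic data
#'
#' Generates a block-LD reference panel, a multi-exposure lipid GWAS panel
#' with a shared disease outcome (phosphatidylcholines enriched among the
#' truly causal exposures), and runs: the MR panel with BH FDR; a rerun with
#' a locus mask over the first exposure's causal blocks; lipid-class
#' enrichment of the MR hits; colocalization over the top exposure's
#' regions; a PBMC-style perturbation experiment with differential analysis,
#' reversal summary and the within-batch permutation overlap test against
#' the MR hits; and a cohort lipid-symptom association with polygenic
#' scoring.
#'
#' @param seed master seed; every stage derives its stream from it.
#' @param out_dir optional directory: stage tables are written as
#'   tab-delimited files plus a `manifest.txt`.
#' @param n_exposures exposures in the GWAS panel (default 16, half PCs).
#' @param n_perm permutations for the overlap test (default 200 in the
#'   demo; 1000 in [default_thresholds()]).
#' @param n_pbmc_features lipid features in the PBMC simulation.
#' @return list with `mr_panel`, `mr_panel_masked`, `enrichment`, `coloc`,
#'   `pbmc`, `cohort`, and `manifest`.
#' @export
run_demo_pipeline <- function(seed = 1, out_dir = NULL, n_exposures = 16,
                              n_perm = 200, n_pbmc_features = 120) {
  th <- default_thresholds()
  stopifnot(n_exposures >= 6, n_exposures %% 2 == 0)
  universe <- lipid_name_universe()
  pc_names <- grep("^PC\\(1", universe, value = TRUE)
  other_names <- grep("^(CE|TAG|SM|LPE)", universe, value = TRUE)
  half <- n_exposures / 2
  exposure_names <- c(pc_names[seq_len(half)], other_names[seq_len(half)])
  ## PCs enriched among truly causal exposures
  n_pc_causal <- max(2, round(0.75 * half))
  bxy <- stats::setNames(rep(0, n_exposures), exposure_names)
  bxy[seq_len(n_pc_causal)] <- 0.15
  bxy[half + seq_len(2)] <- 0.15

  n_causal_per_exposure <- 3
  panel <- make_ld_panel(n_blocks = n_exposures * n_causal_per_exposure,
                         block_size = 5, within_block_rho = 0.8,
                         n_individuals = 800, seed = seed + 11)
  sim <- simulate_mr_panel(panel, bxy,
                           n_causal_per_exposure = n_causal_per_exposure,
                           h2_per_exposure = 0.02, seed = seed + 23)

  mr <- run_panel(sim$exposures, sim$outcome, panel,
                  p_threshold = th$p_threshold, clump_r2 = th$clump_r2,
                  clump_window = th$clump_window,
                  min_snps = th$min_snps_relaxed, heidi_p = th$heidi_p)
  hits <- mr$exposure[mr$q_fdr < th$fdr]

  ## mask the first exposure's causal region and rerun
  mask_snps <- sim$truth$causal_variants[[1L]]
  mpos <- panel$map$pos[panel$map$snp %in% mask_snps]
  mask <- list(chrom = panel$map$chr[1L],
               start = min(mpos) - 2e4, end = max(mpos) + 2e4)
  mr_masked <- run_panel(sim$exposures, sim$outcome, panel,
                         p_threshold = th$p_threshold,
                         clump_r2 = th$clump_r2,
                         clump_window = th$clump_window,
                         min_snps = th$min_snps_relaxed,
                         heidi_p = th$heidi_p, mask = mask)
  hits_masked <- mr_masked$exposure[mr_masked$q_fdr < th$fdr]

  enrichment <- if (length(hits))
    class_enrichment(hits, exposure_names, "PC") else NULL

  ## colocalization over the top exposure's regions
  top <- mr$exposure[which.min(mr$pval)]
  regions <- define_regions(sim$exposures[[top]], panel,
                            p_threshold = th$p_threshold,
                            clump_r2 = th$clump_r2,
                            clump_window = th$coloc_clump_window,
                            flank = th$coloc_flank)
  coloc <- lapply(seq_len(nrow(regions)), function(i) {
    rg <- regions[i, ]
    in_rg <- function(tab) {
      d <- as.data.frame(tab)
      d <- d[d$chr == rg$chrom & d$pos >= rg$start & d$pos <= rg$end, ]
      gwas_table(d, attr(tab, "trait_name"), attr(tab, "trait_type"))
    }
    cr <- coloc_abf(in_rg(sim$exposures[[top]]), in_rg(sim$outcome),
                    pph4_strong = th$pph4_strong,
                    pph4_suggestive = th$pph4_suggestive)
    data.frame(chrom = rg$chrom, start = rg$start, end = rg$end,
               exposure = top, index = rg$index,
               pph4 = cr$pph[["PPH4"]], tier = cr$evidence_tier,
               n_credible = length(cr$credible_set),
               stringsAsFactors = FALSE)
  })
  coloc <- if (length(coloc)) do.call(rbind, coloc) else NULL
  loci <- if (!is.null(coloc))
    merge_regions(coloc, th$pph4_strong, th$pph4_suggestive) else NULL

  ## PBMC perturbation stage: plant the MR-hit species among the
  ## cortisol-downregulated features so the overlap test has signal
  pbmc_feats <- unique(c(hits,
                         setdiff(universe, exposure_names)))[
                           seq_len(n_pbmc_features)]
  pb <- simulate_pbmc(n_features = n_pbmc_features, n_down_cortisol = 30,
                      n_reversed = 18, seed = seed + 31,
                      feature_names = pbmc_feats)
  flt <- filter_and_impute(pb$matrix)
  diffs <- differential(flt, list(c("cortisol", "control"),
                                  c("cortisol_ze50", "cortisol")))
  d_cort <- diffs[diffs$contrast == "cortisol:control", ]
  d_ze <- diffs[diffs$contrast == "cortisol_ze50:cortisol", ]
  reversal <- reversal_summary(d_cort, d_ze, q_threshold = th$fdr)
  overlap <- overlap_permutation(flt, c("cortisol", "control"),
                                 gsmr_hits = hits,
                                 gwas_panel_names = exposure_names,
                                 n_perm = n_perm, seed = seed + 41,
                                 q_threshold = th$fdr)

  ## cohort stage
  co <- simulate_cohort(seed = seed + 53)
  keep <- trim_outliers(co$table$lipid_value, k = th$trim_sd)
  idx <- setdiff(seq_len(nrow(co$table)), attr(keep, "removed_idx"))
  ct <- co$table[idx, , drop = FALSE]
  assoc <- adjusted_correlation(
    ct$lipid_value, ct[, c("age", "sex", "center", "batch", "bmi")],
    ct$symptom_score, ct[, c("age", "sex", "wave")])
  pgs <- polygenic_score(co$dosages[idx, , drop = FALSE],
                         co$truth$instrument_betas)
  pgs_r <- stats::cor(pgs, log(ct$lipid_value))

  manifest <- list(
    seed = seed, thresholds = th,
    stage_counts = c(exposures = n_exposures,
                     panel_variants = nrow(panel$map),
                     mr_tested = nrow(mr), mr_hits = length(hits),
                     mr_hits_masked = length(hits_masked),
                     coloc_regions = if (is.null(coloc)) 0L else nrow(coloc),
                     pbmc_features = ncol(flt$abundances),
                     cohort_n = assoc$n,
                     cohort_trimmed = attr(keep, "n_removed")))

  res <- list(mr_panel = mr, mr_panel_masked = mr_masked, hits = hits,
              hits_masked = hits_masked, enrichment = enrichment,
              coloc = coloc, loci = loci,
              pbmc = list(differential = diffs, reversal = reversal,
                          overlap = overlap),
              cohort = list(association = assoc, pgs_lipid_r = pgs_r,
                            n_trimmed = attr(keep, "n_removed")),
              manifest = manifest)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(as.data.frame(res$mr_panel), "mr_panel.tsv")
  wt(as.data.frame(res$mr_panel_masked), "mr_panel_masked.tsv")
  if (!is.null(res$coloc))
    wt(res$coloc, "coloc_regions.tsv")
  wt(res$pbmc$differential, "pbmc_differential.tsv")
  mf <- res$manifest
  lines <- c(sprintf("seed: %d", mf$seed),
             sprintf("threshold %s: %s", names(mf$thresholds),
                     vapply(mf$thresholds, format, character(1))),
             sprintf("count %s: %s", names(mf$stage_counts),
                     format(mf$stage_counts)))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
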