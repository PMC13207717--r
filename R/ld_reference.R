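## Reference-panel LD and p-value-ordered greedy clumping.

#' Construct an LD reference panel
#'
#' @param variant_map data frame with columns `snp`, `chr`, `pos`, `ea`, `oa`,
#'   ordered as the dosage columns.
#' @param dosages numeric matrix, individuals x variants, effect-allele
#'   dosages in `[0, 2]`; column order matches `variant_map` rows.
#' @return an `ld_panel` object.
#' @export
ld_panel <- function(variant_map, dosages) {
  stopifnot(is.data.frame(variant_map),
            all(c("snp", "chr", "pos", "ea", "oa") %in% names(variant_map)),
            is.matrix(dosages), ncol(dosages) == nrow(variant_map))
  variant_map$snp <- as.character(variant_map$snp)
  variant_map$chr <- as.character(variant_map$chr)
  colnames(dosages) <- variant_map$snp
  structure(list(map = variant_map, dosages = dosages), class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("LD reference panel: %d individuals x %d variants (%d chromosome(s))\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chr))))
  invisible(x)
}

#' Read an LD panel from tab-delimited files
#'
#' @param map_path variant map, tab-delimited with header `ID CHR POS EA OA`.
#' @param dosage_path numeric matrix (individuals x variants, header row of
#'   variant ids), tab-delimited.
#' @return an `ld_panel`.
#' @export
read_ld_panel <- function(map_path, dosage_path) {
  map <- utils::read.table(map_path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  names(map) <- tolower(names(map))
  names(map)[names(map) == "id"] <- "snp"
  dos <- as.matrix(utils::read.table(dosage_path, header = TRUE, sep = "",
                                     check.names = FALSE))
  ld_panel(map[, c("snp", "chr", "pos", "ea", "oa")], dos)
}

#' Write an LD panel as tab-delimited files
#' @param panel an `ld_panel`.
#' @param map_path,dosage_path output paths.
#' @export
write_ld_panel <- function(panel, map_path, dosage_path) {
  map <- panel$map[, c("snp", "chr", "pos", "ea", "oa")]
  names(map) <- c("ID", "CHR", "POS", "EA", "OA")
  utils::write.table(map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(panel$dosages), dosage_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(panel)
}

#' Pairwise LD (Pearson genotype correlation) for selected variants
#'
#' Correlations are computed between effect-allele dosage columns, so signs
#' refer to each variant's effect allele as recorded in the panel map.
#'
#' @param panel an `ld_panel`.
#' @param variant_ids variants to include (order preserved).
#' @return an `ld_matrix`: correlation matrix with variant ids as dimnames.
#' @export
compute_ld <- function(panel, variant_ids) {
  idx <- match(variant_ids, panel$map$snp)
  if (anyNA(idx))
    stop("compute_ld: variant not in panel: ", variant_ids[which(is.na(idx))[1L]])
  d <- panel$dosages[, idx, drop = FALSE]
  v <- apply(d, 2L, stats::var)
  if (any(v == 0))
    stop("compute_ld: zero dosage variance for ", variant_ids[which(v == 0)[1L]])
  r <- stats::cor(d)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(r, class = c("ld_matrix", class(r)))
}

#' Greedy p-value-ordered LD clumping
#'
#' Variants with `p < p_threshold` are sorted by ascending p (ties broken by
#' ascending position, then variant id).  The best remaining variant becomes
#' an index; all remaining variants on the same chromosome within `window_bp`
#' (pairwise distance `<= window_bp`) with `r^2 >= r2_threshold` against it
#' are removed.  Repeats until exhausted.  LD is evaluated lazily per
#' chromosome against the reference panel.
#'
#' @param assoc a `gwas_table` (or data frame with `snp`, `chr`, `pos`, `p`).
#' @param ld an `ld_panel`, or a precomputed `ld_matrix` covering the
#'   candidate variants.
#' @param p_threshold significance threshold for candidacy.
#' @param r2_threshold squared-correlation threshold for removal.
#' @param window_bp window (pairwise base-pair distance, inclusive).
#' @return character vector of index variant ids in selection order.
#' @export
clump <- function(assoc, ld, p_threshold = 1e-6, r2_threshold = 0.1,
                  window_bp = 1e7) {
  stopifnot(nrow(assoc) > 0, p_threshold > 0, r2_threshold >= 0, window_bp >= 0)
  cand <- as.data.frame(assoc)[, c("snp", "chr", "pos", "p")]
  cand <- cand[!is.na(cand$p) & cand$p < p_threshold, , drop = FALSE]
  if (!nrow(cand)) return(character(0))
  cand <- cand[order(cand$p, cand$pos, cand$snp), , drop = FALSE]

  r2_of <- local({
    cache <- list()
    function(chr, ids_needed) {
      if (is.null(cache[[chr]])) {
        on_chr <- cand$snp[cand$chr == chr]
        r <- if (inherits(ld, "ld_panel")) compute_ld(ld, on_chr)
             else ld[on_chr, on_chr, drop = FALSE]
        cache[[chr]] <<- r^2
      }
      cache[[chr]]
    }
  })

  selected <- character(0)
  alive <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    idx <- cand[i, ]
    selected <- c(selected, idx$snp)
    alive[i] <- FALSE
    later <- which(alive & cand$chr == idx$chr &
                     abs(cand$pos - idx$pos) <= window_bp)
    if (length(later)) {
      r2 <- r2_of(idx$chr)
      kill <- later[r2[cand$snp[later], idx$snp] >= r2_threshold]
      alive[kill] <- FALSE
    }
  }
  selected
}
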