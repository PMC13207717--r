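## GWAS summary-statistic tables: construction, I/O, allele harmonization.

#' Canonical GWAS summary-statistic columns
#'
#' A `gwas_table` is a data frame with one row per variant and the canonical
#' columns `snp`, `chr`, `pos`, `ea` (effect allele), `oa` (other allele),
#' `eaf`, `beta`, `se`, `p`, `n`, plus `trait_name` and `trait_type`
#' attributes.  For binary outcomes `beta` is on the log-odds scale.
#'
#' @param data data frame carrying the canonical columns.
#' @param trait_name character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param validate validate invariants (unique ids, positive se, p in (0,1]).
#' @return a `gwas_table` object.
#' @export
gwas_table <- function(data, trait_name = "trait",
                       trait_type = c("quantitative", "binary"),
                       validate = TRUE) {
  trait_type <- match.arg(trait_type)
  needed <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("gwas_table: missing column(s): ", paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data)[needed]
  data$chr <- as.character(data$chr)
  data$snp <- as.character(data$snp)
  data$ea <- toupper(as.character(data$ea))
  data$oa <- toupper(as.character(data$oa))
  if (validate) {
    dup <- data$snp[duplicated(data$snp)]
    if (length(dup))
      stop("gwas_table: duplicate variant_id: ", dup[1L])
    if (any(!is.na(data$se) & data$se <= 0))
      stop("gwas_table: se must be > 0")
    if (any(!is.na(data$p) & (data$p <= 0 | data$p > 1)))
      stop("gwas_table: p must lie in (0, 1]")
    if (any(data$ea == data$oa))
      stop("gwas_table: effect_allele equals other_allele for ",
           data$snp[which(data$ea == data$oa)[1L]])
  }
  ## missing p recomputed from the normal approximation (clamped above zero
  ## so extreme z-scores cannot underflow out of (0, 1]); supplied p trusted
  fill <- is.na(data$p) & !is.na(data$beta) & !is.na(data$se)
  data$p[fill] <- pmax(2 * stats::pnorm(-abs(data$beta[fill] / data$se[fill])),
                       .Machine$double.xmin)
  rownames(data) <- NULL
  structure(data,
            trait_name = trait_name, trait_type = trait_type,
            class = c("gwas_table", "data.frame"))
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d variants\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab- or whitespace-delimited table with a header row
#' (gzip-transparent via [base::connections]).  `column_map` maps canonical
#' field names to the file's header names; the default expects the headers
#' `SNP CHR POS EA OA EAF BETA SE P N`.  Rows whose beta, se or p do not parse
#' as numbers are dropped and counted; rows with indel or multi-allelic allele
#' codes (anything but a single A/C/G/T per allele) are likewise dropped.
#' Alleles are upper-cased.  The drop accounting is attached as the
#' `load_report` attribute (a data frame of reason/count).
#'
#' @param path file path.
#' @param column_map named character vector, canonical name -> file header.
#' @param trait_name,trait_type passed to [gwas_table()].
#' @return a `gwas_table` with a `load_report` attribute.
#' @export
read_gwas_table <- function(path,
                            column_map = c(snp = "SNP", chr = "CHR", pos = "POS",
                                           ea = "EA", oa = "OA", eaf = "EAF",
                                           beta = "BETA", se = "SE", p = "P",
                                           n = "N"),
                            trait_name = "trait",
                            trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  mandatory <- c("snp", "chr", "pos", "ea", "oa", "beta", "se")
  for (fld in mandatory) {
    hdr <- column_map[[fld]]
    if (is.null(hdr) || !hdr %in% names(raw))
      stop("read_gwas_table: mandatory column '", fld, "' (header '",
           if (is.null(hdr)) "?" else hdr, "') not found in ", path)
  }
  get_col <- function(fld) {
    hdr <- column_map[[fld]]
    if (!is.null(hdr) && hdr %in% names(raw)) raw[[hdr]] else rep(NA_character_, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  d <- data.frame(snp = get_col("snp"), chr = get_col("chr"),
                  pos = num(get_col("pos")),
                  ea = toupper(get_col("ea")), oa = toupper(get_col("oa")),
                  eaf = num(get_col("eaf")), beta = num(get_col("beta")),
                  se = num(get_col("se")), p = num(get_col("p")),
                  n = num(get_col("n")),
                  stringsAsFactors = FALSE)
  bad_numeric <- is.na(d$beta) | is.na(d$se) | d$se <= 0 |
    (!is.na(d$p) & (d$p <= 0 | d$p > 1))
  snv <- d$ea %in% c("A", "C", "G", "T") & d$oa %in% c("A", "C", "G", "T") &
    d$ea != d$oa
  report <- data.frame(
    reason = c("non_parsable_numeric", "non_snv_or_degenerate_alleles"),
    count = c(sum(bad_numeric, na.rm = TRUE),
              sum(!snv & !bad_numeric, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  keep <- !bad_numeric & snv
  d <- d[keep, , drop = FALSE]
  dup <- d$snp[duplicated(d$snp)]
  if (length(dup))
    stop("read_gwas_table: duplicate variant_id: ", dup[1L])
  out <- gwas_table(d, trait_name = trait_name, trait_type = trait_type)
  attr(out, "load_report") <- report
  out
}

#' Write a GWAS table as tab-delimited text
#'
#' Inverse of [read_gwas_table()] with the default header mapping; full
#' precision (17 significant digits) so a read-back round trip reproduces all
#' finite fields.
#'
#' @param x a `gwas_table`.
#' @param path output path.
#' @export
write_gwas_table <- function(x, path) {
  stopifnot(inherits(x, "gwas_table"))
  d <- as.data.frame(x)
  for (cc in c("pos", "eaf", "beta", "se", "p", "n"))
    d[[cc]] <- formatC(d[[cc]], digits = 17, format = "g")
  names(d) <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Is a variant palindromic (A/T or C/G)?
#' @param ea,oa allele vectors.
#' @return logical vector.
#' @export
is_palindromic <- function(ea, oa) unname(.complement[toupper(ea)] == toupper(oa))

#' Harmonize outcome alleles to the exposure orientation
#'
#' For every variant shared between the two tables the outcome record is
#' re-expressed on the exposure's effect-allele orientation:
#' * identical allele pair: kept as-is;
#' * strand flip of both alleles (A<->T, C<->G): outcome alleles renamed;
#' * effect/other swapped (directly or after a strand flip): outcome beta
#'   negated, eaf mapped to 1 - eaf;
#' * irreconcilable pairs excluded.
#' Palindromic variants (A/T or C/G pairs) are excluded when
#' `drop_palindromic = TRUE` because strand and swap are indistinguishable
#' for them.
#'
#' @param exposure,outcome `gwas_table`s.
#' @param drop_palindromic drop palindromic variants (default `TRUE`).
#' @return a list of class `harmonized_pair`: `data` (joined data frame with
#'   `bzx`, `se_zx`, `p_zx`, `bzy`, `se_zy`, `p_zy`, positions and the
#'   exposure allele orientation), `outcome` (the aligned outcome
#'   `gwas_table`, shared kept variants only) and `exclusions`
#'   (variant/reason data frame).
#' @export
harmonize <- function(exposure, outcome, drop_palindromic = TRUE) {
  stopifnot(inherits(exposure, "gwas_table"), inherits(outcome, "gwas_table"))
  shared <- intersect(exposure$snp, outcome$snp)
  if (!length(shared)) stop("harmonize: no shared variants")
  ex <- as.data.frame(exposure)[match(shared, exposure$snp), ]
  ou <- as.data.frame(outcome)[match(shared, outcome$snp), ]

  excl_reason <- rep(NA_character_, length(shared))
  pal <- is_palindromic(ex$ea, ex$oa) | is_palindromic(ou$ea, ou$oa)
  if (drop_palindromic) excl_reason[pal] <- "palindromic"

  flip_ea <- unname(.complement[ou$ea]); flip_oa <- unname(.complement[ou$oa])
  same    <- ou$ea == ex$ea & ou$oa == ex$oa
  swapped <- ou$ea == ex$oa & ou$oa == ex$ea
  flipped <- flip_ea == ex$ea & flip_oa == ex$oa
  flipswp <- flip_ea == ex$oa & flip_oa == ex$ea
  reconcilable <- same | swapped | flipped | flipswp
  excl_reason[!reconcilable & is.na(excl_reason)] <- "irreconcilable_alleles"

  keep <- is.na(excl_reason)
  negate <- (swapped | (flipswp & !flipped)) & keep  # pure swap, or swap after strand flip
  ou$beta[negate] <- -ou$beta[negate]
  ou$eaf[negate] <- 1 - ou$eaf[negate]
  ou$ea <- ex$ea; ou$oa <- ex$oa  # aligned orientation for kept rows

  exclusions <- data.frame(snp = shared[!keep], reason = excl_reason[!keep],
                           stringsAsFactors = FALSE)
  exk <- ex[keep, , drop = FALSE]; ouk <- ou[keep, , drop = FALSE]
  data <- data.frame(snp = exk$snp, chr = exk$chr, pos = exk$pos,
                     ea = exk$ea, oa = exk$oa, eaf = exk$eaf,
                     bzx = exk$beta, se_zx = exk$se, p_zx = exk$p, n_zx = exk$n,
                     bzy = ouk$beta, se_zy = ouk$se, p_zy = ouk$p, n_zy = ouk$n,
                     stringsAsFactors = FALSE)
  out_tab <- gwas_table(ouk, trait_name = attr(outcome, "trait_name"),
                        trait_type = attr(outcome, "trait_type"))
  structure(list(data = data, outcome = out_tab, exclusions = exclusions,
                 n_shared = length(shared)),
            class = "harmonized_pair")
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf("Harmonized pair: %d shared, %d kept, %d excluded\n",
              x$n_shared, nrow(x$data), nrow(x$exclusions)))
  if (nrow(x$exclusions))
    print(table(x$exclusions$reason))
  invisible(x)
}
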