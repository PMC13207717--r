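## Lipid-species nomenclature: a deterministic local grammar for names like
## "PC(16:0/20:4)", "SM 40:2;O2", "PC(O-16:0/20:3)", cross-panel species
## mapping, and lipid-class enrichment among MR hits.

.class_synonyms <- c(DG = "DAG", TG = "TAG")

#' Parse a lipid species name
#'
#' Grammar: `CLASS["("][O-|P-]CC:DB[/CC:DB...][")"][;MOD]` or
#' `CLASS CC:DB[;MOD]` (space-separated).  Class tokens are normalized
#' (`DG` = `DAG`, `TG` = `TAG`).  A single chain given at the class level
#' without `/` separators is treated as a sum composition (total
#' carbons:double bonds) when the class typically carries more than one acyl
#' chain (PC, PE, PI, SM, DAG, TAG, ...); chains listed with `/` are
#' individually resolved.
#'
#' @param name character scalar, e.g. `"PC(16:0/20:4)"`.
#' @return a `lipid_species` list: `raw_name`, `lipid_class`, `chains`
#'   (matrix with columns `carbons`, `double_bonds`), `ether_prefix`
#'   (`"none"`, `"O-"`, `"P-"`), `modifiers` (character), and
#'   `is_sum_composition`.
#' @export
parse_species <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  s <- trimws(name)
  ## split trailing ;modifiers (possibly "; O2" with space)
  mods <- character(0)
  while (grepl(";", s, fixed = TRUE)) {
    parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
    mods <- c(trimws(parts[-1L]), mods)
    s <- trimws(parts[1L])
    break
  }
  m <- regmatches(s, regexec("^([A-Za-z]+)\\s*\\(\\s*(.*?)\\s*\\)$", s))[[1L]]
  if (length(m)) {
    cls <- m[2L]; body <- m[3L]
  } else {
    m <- regmatches(s, regexec("^([A-Za-z]+)\\s+(.+)$", s))[[1L]]
    if (!length(m)) stop("parse_species: cannot parse '", name, "'")
    cls <- m[2L]; body <- trimws(m[3L])
  }
  cls <- toupper(cls)
  if (cls %in% names(.class_synonyms)) cls <- .class_synonyms[[cls]]
  ether <- "none"
  if (grepl("^O-", body)) { ether <- "O-"; body <- sub("^O-", "", body) }
  else if (grepl("^P-", body)) { ether <- "P-"; body <- sub("^P-", "", body) }
  chain_tok <- strsplit(body, "/", fixed = TRUE)[[1L]]
  chain_re <- "^([0-9]+):([0-9]+)$"
  bad <- !grepl(chain_re, trimws(chain_tok))
  if (any(bad))
    stop("parse_species: cannot parse chain token '", chain_tok[bad][1L],
         "' in '", name, "'")
  carbons <- as.integer(sub(chain_re, "\\1", trimws(chain_tok)))
  dbl <- as.integer(sub(chain_re, "\\2", trimws(chain_tok)))
  if (any(carbons <= 0) || any(dbl < 0))
    stop("parse_species: invalid chain in '", name, "'")
  multi_chain_classes <- c("PC", "PE", "PI", "PS", "PG", "SM", "DAG", "TAG",
                           "CER", "HEXCER", "LACCER")
  is_sum <- length(chain_tok) == 1L && cls %in% multi_chain_classes
  structure(list(raw_name = name, lipid_class = cls,
                 chains = cbind(carbons = carbons, double_bonds = dbl),
                 ether_prefix = ether, modifiers = mods,
                 is_sum_composition = is_sum),
            class = "lipid_species")
}

#' Format a parsed species back to a canonical name
#' @param x a `lipid_species`.
#' @return character scalar, `CLASS(prefixCC:DB/...)` with `;MOD` suffix.
#' @export
format_species <- function(x) {
  stopifnot(inherits(x, "lipid_species"))
  pre <- if (x$ether_prefix == "none") "" else x$ether_prefix
  chains <- paste(sprintf("%d:%d", x$chains[, "carbons"],
                          x$chains[, "double_bonds"]), collapse = "/")
  out <- if (x$is_sum_composition)
    sprintf("%s %s%s", x$lipid_class, pre, chains)
  else sprintf("%s(%s%s)", x$lipid_class, pre, chains)
  if (length(x$modifiers)) out <- paste0(out, ";", paste(x$modifiers, collapse = ";"))
  out
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("%s [class %s%s, %s]\n", x$raw_name, x$lipid_class,
              if (x$ether_prefix != "none") paste0(", ether ", x$ether_prefix) else "",
              if (x$is_sum_composition) "sum composition" else
                paste(nrow(x$chains), "chain(s)")))
  invisible(x)
}

.species_key <- function(sp) {
  ch <- sp$chains[order(sp$chains[, "carbons"], sp$chains[, "double_bonds"]),
                  , drop = FALSE]
  paste(sp$lipid_class, sp$ether_prefix,
        paste(sprintf("%d:%d", ch[, "carbons"], ch[, "double_bonds"]),
              collapse = "/"),
        paste(sort(sp$modifiers), collapse = ";"), sep = "|")
}

.species_sum_key <- function(sp) {
  paste(sp$lipid_class, sp$ether_prefix,
        sprintf("%d:%d", sum(sp$chains[, "carbons"]),
                sum(sp$chains[, "double_bonds"])),
        paste(sort(sp$modifiers), collapse = ";"), sep = "|")
}

#' Map lipid species between two panels
#'
#' Exact matching on (class, ether prefix, chain multiset, modifiers); chain
#' order (sn-position) is ignored.  With `allow_sum_composition = TRUE`,
#' a fully resolved species additionally matches a sum-composition species
#' whose totals equal its chain sums (flagged in the result).  One-to-many
#' matches are all reported, never silently resolved.
#'
#' @param names_a,names_b character vectors of species names.
#' @param allow_sum_composition also match on chain totals (default `FALSE`).
#' @param synonyms optional two-column data frame (`from`, `to`) of
#'   name-level synonyms applied to both sides before parsing, to patch
#'   residual nomenclature mismatches.  The reported names stay the
#'   originals.
#' @return data frame with `name_a`, `name_b`, `match_type`
#'   (`"exact"`/`"sum_composition"`); unparsable names are skipped and
#'   recorded in the `unparsed` attribute.
#' @export
map_species <- function(names_a, names_b, allow_sum_composition = FALSE,
                        synonyms = NULL) {
  subst <- function(nn) {
    if (is.null(synonyms)) return(nn)
    hit <- match(nn, synonyms[[1L]])
    ifelse(is.na(hit), nn, synonyms[[2L]][hit])
  }
  names_a0 <- names_a; names_b0 <- names_b
  names_a <- subst(names_a); names_b <- subst(names_b)
  parse_all <- function(nn) {
    lapply(nn, function(x) tryCatch(parse_species(x), error = function(e) NULL))
  }
  pa <- parse_all(names_a); pb <- parse_all(names_b)
  unparsed <- c(names_a0[vapply(pa, is.null, logical(1))],
                names_b0[vapply(pb, is.null, logical(1))])
  oka <- !vapply(pa, is.null, logical(1)); okb <- !vapply(pb, is.null, logical(1))
  ka <- vapply(pa[oka], .species_key, character(1))
  kb <- vapply(pb[okb], .species_key, character(1))
  sa <- vapply(pa[oka], .species_sum_key, character(1))
  sb <- vapply(pb[okb], .species_sum_key, character(1))
  na <- names_a0[oka]; nb <- names_b0[okb]
  pairs <- list()
  for (i in seq_along(na)) {
    hit <- which(kb == ka[i])
    type <- rep("exact", length(hit))
    if (allow_sum_composition) {
      extra <- which(sb == sa[i])
      extra <- setdiff(extra, hit)
      hit <- c(hit, extra)
      type <- c(type, rep("sum_composition", length(extra)))
    }
    if (length(hit))
      pairs[[length(pairs) + 1L]] <-
        data.frame(name_a = na[i], name_b = nb[hit], match_type = type,
                   stringsAsFactors = FALSE)
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(name_a = character(0), name_b = character(0),
               match_type = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unparsed") <- unparsed
  out
}

#' Lipid-class enrichment among hits (Fisher's exact test)
#'
#' Builds the 2x2 table `[[class & hit, class & non-hit], [other & hit,
#' other & non-hit]]` and tests it with a two-sided Fisher exact test.
#'
#' @param hits character vector of hit species names (subset of `universe`).
#' @param universe all tested species names.
#' @param target_class class token (e.g. `"PC"`), compared after parsing.
#' @return list with `table` (2x2), `odds_ratio` (sample cross-product
#'   ratio) and `p` (two-sided Fisher).
#' @export
class_enrichment <- function(hits, universe, target_class) {
  if (!all(hits %in% universe))
    stop("class_enrichment: hits must be a subset of the universe")
  stopifnot(length(hits) > 0, length(universe) > 0)
  cls_of <- function(nm) tryCatch(parse_species(nm)$lipid_class,
                                  error = function(e) NA_character_)
  cls <- vapply(universe, cls_of, character(1))
  is_target <- !is.na(cls) & cls == toupper(target_class)
  is_hit <- universe %in% hits
  tab <- matrix(c(sum(is_target & is_hit), sum(is_target & !is_hit),
                  sum(!is_target & is_hit), sum(!is_target & !is_hit)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("class", "other"), c("hit", "non_hit")))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, odds_ratio = or,
       p = stats::fisher.test(tab)$p.value)
}
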