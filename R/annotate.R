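# Dictionary and rule-based entity annotation.
#
# Token boundary contract: a surface matches only where the neighbouring
# characters are not alphanumeric. Hyphens inside a surface are matched
# literally ("B-RAF1"), and a hyphen in the text counts as a boundary, so
# "nab-paclitaxel" contains a boundary-aligned "paclitaxel"; the
# longest-match-first overlap rule then keeps only the full compound when
# both are in the lexicon.

boundary_regex <- function(surface) {
  paste0("(?<![A-Za-z0-9])", stringr::str_replace_all(surface, "(\\W)", "\\\\\\1"),
         "(?![A-Za-z0-9])")
}

# all matches of one surface in one text; returns start/end 0-based half-open
surface_matches <- function(text, surface, ignore_case) {
  m <- gregexpr(boundary_regex(surface), text, perl = TRUE, ignore.case = ignore_case)[[1]]
  if (m[1] == -1) return(NULL)
  start <- as.integer(m) - 1L
  tibble(start = start, end = start + attr(m, "match.length"))
}

# longest-match-first, leftmost on ties; input tibble with start/end
resolve_overlaps <- function(cand) {
  if (nrow(cand) <= 1) return(cand)
  cand <- cand[order(-(cand$end - cand$start), cand$start), ]
  keep <- logical(nrow(cand))
  taken_start <- integer(0); taken_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (!any(s < taken_end & e > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
    }
  }
  out <- cand[keep, ]
  out[order(out$start), ]
}

match_lexicon <- function(text, lexicon, etype) {
  if (nrow(lexicon) == 0) return(empty_mentions())
  kind <- attr(lexicon, "kind")
  cands <- purrr::map2(lexicon$synonym, lexicon$id, function(surf, id) {
    ignore_case <- if (identical(kind, "gene")) nchar(surf) > 4 else TRUE
    hits <- surface_matches(text, surf, ignore_case)
    if (is.null(hits)) return(NULL)
    hits$norm_id <- id
    hits
  })
  cands <- bind_rows(cands)
  if (nrow(cands) == 0) return(empty_mentions())
  res <- resolve_overlaps(cands)
  tibble(etype = etype, start = as.integer(res$start), end = as.integer(res$end),
         surface = slice_text(text, res$start, res$end), norm_id = res$norm_id)
}

set_mentions <- function(docs, etype, new_mentions) {
  docs$mentions <- purrr::map2(docs$mentions, new_mentions, function(old, new) {
    old <- old[old$etype != etype, , drop = FALSE]
    out <- bind_rows(old, new)
    out[order(out$start, out$etype), ]
  })
  docs
}

#' Annotate gene mentions with a lexicon
#'
#' Detects every maximal token-boundary-aligned occurrence of any lexicon
#' synonym in each document's annotated text and normalizes it to the gene id.
#' Matching is case-sensitive for symbols of at most 4 characters (short gene
#' symbols collide with ordinary words) and case-insensitive for longer ones.
#' Overlapping candidates are resolved longest-match-first, leftmost on ties.
#' Existing gene mentions on the documents are replaced, so the operation is
#' idempotent.
#'
#' @param docs A document tibble.
#' @param lexicon A gene lexicon (see [read_lexicon_tsv()]).
#' @return `docs` with the `mentions` list-column updated.
#' @export
annotate_genes <- function(docs, lexicon) {
  stopifnot(identical(attr(lexicon, "kind"), "gene"))
  txt <- annotated_text(docs$title, docs$abstract)
  set_mentions(docs, "gene", map(txt, match_lexicon, lexicon = lexicon, etype = "gene"))
}

#' Annotate drug mentions with a lexicon
#'
#' As [annotate_genes()] but case-insensitive throughout, which suits drug
#' nomenclature.
#'
#' @inheritParams annotate_genes
#' @param lexicon A drug lexicon.
#' @return `docs` with updated drug mentions.
#' @export
annotate_drugs <- function(docs, lexicon) {
  stopifnot(identical(attr(lexicon, "kind"), "drug"))
  txt <- annotated_text(docs$title, docs$abstract)
  set_mentions(docs, "drug", map(txt, match_lexicon, lexicon = lexicon, etype = "drug"))
}

#' Variant mention grammar
#'
#' Ordered rule set covering the variant classes that dominate abstract-level
#' text: protein substitutions in short form (V600E), HGVS-like protein "p."
#' forms with one- or three-letter amino-acid codes, HGVS-like coding "c."
#' substitutions and small indels, and dbSNP rsIDs. Fusions, CNVs and complex
#' rearrangements are out of scope.
#'
#' @return A tibble of named patterns applied in order; overlaps are resolved
#'   longest-match-first, leftmost on ties.
#' @export
variant_grammar <- function() {
  tibble(
    name = c("rsid", "hgvs_protein", "hgvs_coding", "protein_short"),
    pattern = c(
      "(?<![A-Za-z0-9])rs\\d+(?![A-Za-z0-9])",
      "(?<![A-Za-z0-9])p\\.\\s?(?:[A-Z][a-z]{2}\\d+(?:[A-Z][a-z]{2}|\\*|fs\\*?\\d*)|[A-Z]\\d+(?:[A-Z*]|fs\\*?\\d*))(?![A-Za-z0-9])",
      "(?<![A-Za-z0-9])c\\.\\s?\\d+(?:[_+-]\\d+)?\\s?(?:[ACGT]\\s?>\\s?[ACGT]|delins[ACGT]+|del[ACGT]*|ins[ACGT]+|dup[ACGT]*)(?![A-Za-z0-9])",
      "(?<![A-Za-z0-9])[A-Z]\\d{2,4}[A-Z*](?![A-Za-z0-9])"
    )
  )
}

AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
         Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
         Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
         Tyr = "Y", Val = "V", Ter = "*")

#' Canonicalize a variant string
#'
#' Short protein forms are uppercased; "p." and "c." forms are kept verbatim
#' with internal whitespace removed; rsIDs are lowercased. With
#' `fold_aa = TRUE`, three-letter amino-acid codes in "p." forms are folded to
#' one-letter codes and the "p." prefix on a plain substitution is dropped, so
#' "p.Val600Glu" and "V600E" compare equal.
#'
#' @param x Character vector of variant surfaces.
#' @param fold_aa Fold 3-letter amino-acid codes to 1-letter and strip the
#'   "p." prefix from plain substitutions. Default `FALSE`.
#' @return Character vector of canonical forms.
#' @export
canonical_variant <- function(x, fold_aa = FALSE) {
  out <- stringr::str_remove_all(x, "\\s+")
  is_rs <- stringr::str_detect(out, stringr::regex("^rs\\d+$", ignore_case = TRUE))
  out[is_rs] <- tolower(out[is_rs])
  plain <- !is_rs & !stringr::str_detect(out, "^[pc]\\.")
  out[plain] <- toupper(out[plain])
  if (fold_aa) {
    fold1 <- function(v) {
      for (code in names(AA3)) v <- gsub(code, AA3[[code]], v, fixed = TRUE)
      v
    }
    isp <- stringr::str_detect(out, "^p\\.")
    out[isp] <- fold1(out[isp])
    sub1 <- isp & stringr::str_detect(out, "^p\\.[A-Z]\\d+[A-Z*]$")
    out[sub1] <- stringr::str_remove(out[sub1], "^p\\.")
  }
  out
}

#' Annotate variant mentions with the rule grammar
#'
#' Applies the ordered grammar patterns to each document's annotated text and
#' emits one mention per match, normalized with [canonical_variant()].
#' Duplicate matches at identical spans (patterns can coincide) are
#' deduplicated; overlaps are resolved longest-match-first.
#'
#' @param docs A document tibble.
#' @param grammar Pattern table, defaults to [variant_grammar()].
#' @param fold_aa Passed to [canonical_variant()].
#' @return `docs` with updated variant mentions.
#' @export
annotate_variants <- function(docs, grammar = variant_grammar(), fold_aa = FALSE) {
  txt <- annotated_text(docs$title, docs$abstract)
  news <- map(txt, function(tx) {
    cands <- map(grammar$pattern, function(p) {
      m <- gregexpr(p, tx, perl = TRUE)[[1]]
      if (m[1] == -1) return(NULL)
      start <- as.integer(m) - 1L
      tibble(start = start, end = start + attr(m, "match.length"))
    })
    cands <- bind_rows(cands)
    if (nrow(cands) == 0) return(empty_mentions())
    cands <- distinct(cands, .data$start, .data$end)
    res <- resolve_overlaps(cands)
    surf <- slice_text(tx, res$start, res$end)
    tibble(etype = "variant", start = as.integer(res$start), end = as.integer(res$end),
           surface = surf, norm_id = canonical_variant(surf, fold_aa = fold_aa))
  })
  set_mentions(docs, "variant", news)
}

#' Annotate genes, variants and drugs in one pass
#'
#' @param docs Document tibble.
#' @param gene_lexicon,drug_lexicon Optional lexicons; skipped when `NULL`.
#' @param grammar Variant grammar.
#' @param fold_aa Passed to [annotate_variants()].
#' @return Annotated document tibble.
#' @export
annotate_entities <- function(docs, gene_lexicon = NULL, drug_lexicon = NULL,
                              grammar = variant_grammar(), fold_aa = FALSE) {
  if (!is.null(gene_lexicon)) docs <- annotate_genes(docs, gene_lexicon)
  docs <- annotate_variants(docs, grammar, fold_aa = fold_aa)
  if (!is.null(drug_lexicon)) docs <- annotate_drugs(docs, drug_lexicon)
  docs
}

#' Expand gene query symbols with lexicon synonyms
#'
#' Resolves each input symbol against the lexicon (same case policy as
#' [annotate_genes()]) and returns the union of the synonym sets of every
#' resolvable symbol. Unresolvable symbols are passed through verbatim and
#' listed in the `unresolved` attribute.
#'
#' @param symbols Character vector of gene symbols.
#' @param lexicon Gene lexicon.
#' @return Character vector of surfaces with attributes `ids` (resolved gene
#'   ids) and `unresolved`.
#' @export
expand_gene_query <- function(symbols, lexicon) {
  symbols <- unique(symbols)
  if (length(symbols) == 0) {
    return(structure(character(), ids = character(), unresolved = character()))
  }
  resolve_one <- function(sym) {
    exact <- lexicon$id[lexicon$synonym == sym]
    if (length(exact) > 0) return(exact[1])
    long <- lexicon$synonym[nchar(lexicon$synonym) > 4]
    ci <- lexicon$id[nchar(lexicon$synonym) > 4][tolower(long) == tolower(sym)]
    if (length(ci) > 0) ci[1] else NA_character_
  }
  ids <- map_chr(symbols, resolve_one)
  unresolved <- symbols[is.na(ids)]
  surfaces <- unique(c(lexicon$synonym[lexicon$id %in% ids[!is.na(ids)]], unresolved))
  structure(surfaces, ids = unique(ids[!is.na(ids)]), unresolved = unresolved)
}
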