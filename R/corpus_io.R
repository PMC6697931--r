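#' Read a PubMed article-set XML file
#'
#' Parses the `PubmedArticleSet/PubmedArticle` dialect and returns one row per
#' article that carries a PMID and a non-empty title. Multi-section abstracts
#' (structured abstracts with several `AbstractText` nodes) are concatenated in
#' document order with a single space; a missing `Abstract` element yields an
#' empty abstract. The publication year is the earliest complete year found
#' among `PubDate/Year` and `ArticleDate/Year`; articles without any usable
#' year get the unknown sentinel 0.
#'
#' @param path Path to a PubMed XML file.
#' @return A document tibble (see [document_tibble()]). Articles lacking a
#'   PMID are skipped; their count is reported with a warning.
#' @export
read_pubmed_xml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) abort(paste0("malformed XML in '", path, "': ", conditionMessage(e)))
  )
  articles <- xml2::xml_find_all(doc, "//PubmedArticle")
  skipped <- 0L
  rows <- list()
  for (art in articles) {
    pmid <- xml2::xml_text(xml2::xml_find_first(art, ".//MedlineCitation/PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(art, ".//Article/ArticleTitle"))
    if (is.na(pmid) || pmid == "" || is.na(title) || title == "") {
      skipped <- skipped + 1L
      next
    }
    abst_nodes <- xml2::xml_find_all(art, ".//Article/Abstract/AbstractText")
    abstract <- if (length(abst_nodes) == 0) "" else
      paste(trimws(xml2::xml_text(abst_nodes)), collapse = " ")
    journal <- xml2::xml_text(xml2::xml_find_first(art, ".//Article/Journal/Title"))
    years <- xml2::xml_text(xml2::xml_find_all(
      art, ".//Article/Journal/JournalIssue/PubDate/Year | .//Article/ArticleDate/Year"))
    years <- suppressWarnings(as.integer(years))
    years <- years[!is.na(years) & years >= 1000 & years <= 9999]
    rows[[length(rows) + 1L]] <- tibble(
      doc_id = pmid, title = title, abstract = abstract,
      pub_year = if (length(years) > 0) min(years) else YEAR_UNKNOWN,
      journal = ifelse(is.na(journal), "", journal)
    )
  }
  if (skipped > 0) warn(paste0(skipped, " article(s) without PMID or title skipped"))
  out <- if (length(rows) == 0) {
    document_tibble(character(), character())
  } else {
    docs <- bind_rows(rows)
    document_tibble(docs$doc_id, docs$title, docs$abstract, docs$pub_year, docs$journal)
  }
  out
}

#' Read and write documents as JSON lines
#'
#' One JSON object per line with the document fields; the `mentions` field is
#' an array of objects with `etype`, `start`, `end`, `surface`, `norm_id`.
#' The round trip `read_documents_jsonl(write_documents_jsonl(docs))` is
#' lossless, including mention offsets, which makes the JSONL store the
#' vehicle for ingesting precomputed annotations from external NER services.
#'
#' @param docs A document tibble.
#' @param path File path.
#' @return `read_documents_jsonl()` returns a document tibble;
#'   `write_documents_jsonl()` returns `path` invisibly.
#' @export
write_documents_jsonl <- function(docs, path) {
  validate_documents(docs)
  lines <- map_chr(seq_len(nrow(docs)), function(i) {
    m <- docs$mentions[[i]]
    obj <- list(
      doc_id = docs$doc_id[i], title = docs$title[i], abstract = docs$abstract[i],
      pub_year = docs$pub_year[i], journal = docs$journal[i],
      mentions = lapply(seq_len(nrow(m)), function(j) {
        list(etype = m$etype[j], start = m$start[j], end = m$end[j],
             surface = m$surface[j], norm_id = m$norm_id[j])
      })
    )
    if (!is.na(docs$ctype_label[i])) obj$ctype_label <- docs$ctype_label[i]
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_documents_jsonl
#' @export
read_documents_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(document_tibble(character(), character()))
  rows <- imap(lines, function(ln, i) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    for (key in c("doc_id", "title")) {
      if (is.null(obj[[key]])) abort(paste0("line ", i, ": missing required key '", key, "'"))
    }
    ments <- obj$mentions %||% list()
    m <- if (length(ments) == 0) empty_mentions() else tibble(
      etype = map_chr(ments, "etype"),
      start = map_int(ments, function(x) as.integer(x$start)),
      end = map_int(ments, function(x) as.integer(x$end)),
      surface = map_chr(ments, "surface"),
      norm_id = map_chr(ments, "norm_id")
    )
    tibble(
      doc_id = obj$doc_id, title = obj$title,
      abstract = obj$abstract %||% "",
      pub_year = as.integer(obj$pub_year %||% YEAR_UNKNOWN),
      journal = obj$journal %||% "",
      mentions = list(m),
      ctype_label = obj$ctype_label %||% NA_character_
    )
  })
  docs <- bind_rows(rows)
  validate_documents(docs)
  docs
}

#' Read relevance judgments from TSV
#'
#' Expects a header row and columns `query_id`, `doc_id`, `label` with
#' `label` one of `relevant` / `irrelevant` — the consolidated triple format
#' used for ranking evaluation.
#'
#' @param path TSV file path.
#' @return A tibble with columns `query_id`, `doc_id`, `relevant` (logical),
#'   one row per judged pair.
#' @export
read_judgments_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("query_id", "doc_id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) abort(paste0("judgments TSV lacks column(s): ", paste(miss, collapse = ", ")))
  bad <- which(!df$label %in% c("relevant", "irrelevant"))
  if (length(bad) > 0) {
    abort(paste0("unknown label '", df$label[bad[1]], "' at row ", bad[1]))
  }
  dup <- df |>
    distinct(.data$query_id, .data$doc_id, .data$label) |>
    count(.data$query_id, .data$doc_id) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("conflicting labels for (", dup$query_id[1], ", ", dup$doc_id[1], ")"))
  }
  df |>
    distinct(.data$query_id, .data$doc_id, .data$label) |>
    mutate(relevant = .data$label == "relevant") |>
    select("query_id", "doc_id", "relevant")
}

#' Read raw Likert assessments from TSV
#'
#' Columns `query_id`, `doc_id`, `rater_id`, `score`, with `score` on the
#' 5-point scale (1 = not relevant at all ... 5 = highly relevant).
#'
#' @param path TSV file path.
#' @return Tibble of raw assessments.
#' @export
read_assessments_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("query_id", "doc_id", "rater_id", "score")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) abort(paste0("assessments TSV lacks column(s): ", paste(miss, collapse = ", ")))
  df$score <- suppressWarnings(as.integer(df$score))
  bad <- which(is.na(df$score) | !df$score %in% 1:5)
  if (length(bad) > 0) abort(paste0("score outside 1..5 at row ", bad[1]))
  as_tibble(df[need])
}

#' Consolidate multi-rater assessments by majority vote
#'
#' Mirrors the construction of an expert evaluation set from raw 5-point
#' ratings. A (query, document) pair rated "highly relevant" (5) by at least
#' one rater and "not relevant at all" (1) by at least one other is contested
#' and removed. Remaining pairs are binarized per rater (`score >= threshold`
#' counts as relevant) and labeled by majority; exact ties are discarded.
#'
#' @param raw Tibble of raw assessments (see [read_assessments_tsv()]).
#' @param threshold Binarization cut on the 5-point scale; scores at or above
#'   it count as a relevant vote. Default 4.
#' @param keep_all If `TRUE`, return every pair with a `status` column in
#'   `relevant` / `irrelevant` / `removed` / `tie`; otherwise only the
#'   labeled pairs, with a logical `relevant` column.
#' @return A judgment tibble (or full status tibble when `keep_all`).
#' @export
consolidate_assessments <- function(raw, threshold = 4, keep_all = FALSE) {
  if (nrow(raw) == 0) {
    out <- tibble(query_id = character(), doc_id = character(), relevant = logical())
    if (keep_all) out <- tibble(query_id = character(), doc_id = character(), status = character())
    return(out)
  }
  stopifnot(all(raw$score %in% 1:5))
  status <- raw |>
    group_by(.data$query_id, .data$doc_id) |>
    summarise(
      contested = any(.data$score == 5) && any(.data$score == 1),
      pos = sum(.data$score >= threshold),
      neg = sum(.data$score < threshold),
      .groups = "drop"
    ) |>
    mutate(status = dplyr::case_when(
      .data$contested ~ "removed",
      .data$pos > .data$neg ~ "relevant",
      .data$pos < .data$neg ~ "irrelevant",
      TRUE ~ "tie"
    )) |>
    select("query_id", "doc_id", "status") |>
    arrange(.data$query_id, .data$doc_id)
  if (keep_all) return(status)
  status |>
    filter(.data$status %in% c("relevant", "irrelevant")) |>
    mutate(relevant = .data$status == "relevant") |>
    select("query_id", "doc_id", "relevant")
}

#' Read an entity lexicon from TSV
#'
#' Three tab-separated columns without a header:
#' `id`, `canonical`, `synonym1|synonym2|...`. The canonical name is always a
#' member of its own synonym set. A synonym occurring under two different ids
#' is a load-time error (homonyms cannot be resolved by a dictionary matcher).
#'
#' @param path TSV file path.
#' @param kind `"gene"` or `"drug"`; recorded on the result and used by the
#'   annotators to pick the matching policy.
#' @return A lexicon tibble with columns `id`, `canonical`, `synonym`
#'   (one row per synonym) and attribute `kind`.
#' @export
read_lexicon_tsv <- function(path, kind = c("gene", "drug")) {
  kind <- match.arg(kind)
  df <- readr::read_tsv(path, col_names = c("id", "canonical", "synonyms"),
                        col_types = "ccc", progress = FALSE)
  if (nrow(df) == 0) return(lexicon_tibble(character(), character(), list(), kind))
  syns <- stringr::str_split(ifelse(is.na(df$synonyms), "", df$synonyms), stringr::fixed("|"))
  lexicon_tibble(df$id, df$canonical, syns, kind)
}

#' Build a lexicon tibble from vectors
#'
#' @param id,canonical Character vectors, one element per entry.
#' @param synonyms List of character vectors of synonyms per entry.
#' @param kind `"gene"` or `"drug"`.
#' @return Long lexicon tibble, one row per (id, synonym).
#' @export
lexicon_tibble <- function(id, canonical, synonyms, kind = c("gene", "drug")) {
  kind <- match.arg(kind)
  entries <- tibble(id = as.character(id), canonical = as.character(canonical),
                    synonym = map2(synonyms, canonical,
                                   function(s, cn) unique(c(cn, s[nzchar(s)])))) |>
    tidyr::unnest("synonym")
  if (anyDuplicated(entries$id[!duplicated(paste(entries$id, entries$canonical))])) {
    abort("duplicate lexicon id")
  }
  dup <- entries |> distinct(.data$id, .data$synonym) |> count(.data$synonym) |> filter(n > 1)
  if (nrow(dup) > 0) {
    ids <- entries$id[entries$synonym == dup$synonym[1]]
    abort(paste0("synonym '", dup$synonym[1], "' maps to multiple ids: ",
                 paste(unique(ids), collapse = ", ")))
  }
  structure(entries, kind = kind, class = c("clinrank_lexicon", class(entries)))
}

#' Write a lexicon to TSV
#'
#' @param lexicon A lexicon tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon_tsv <- function(lexicon, path) {
  wide <- lexicon |>
    group_by(.data$id, .data$canonical) |>
    summarise(synonyms = paste(.data$synonym, collapse = "|"), .groups = "drop")
  readr::write_tsv(wide, path, col_names = FALSE)
  invisible(path)
}
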