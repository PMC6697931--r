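# Query semantics and the learning-free ranking function: entity/keyword
# candidate filtering, corpus-wide min-max normalization of the classifier
# scores, RankScore = cancer_score * clinical_score, and the candidate sort
# keys compared in the ranking-function study.

SORT_KEYS <- c("rank_score", "pubdate_x_rankscore", "cancer_score", "keyword_score")

#' Construct a search query
#'
#' A query consists of gene symbols (expanded with lexicon synonyms at filter
#' time), variant strings, free-text keywords and an optional cancer type.
#' At least one of genes, variants or keywords must be non-empty; the cancer
#' type only narrows the candidate set.
#'
#' @param genes,variants,keywords Character vectors (possibly empty).
#' @param cancer_type Optional type tag (one of `melanoma`, `head_and_neck`,
#'   `colorectal`, `general_cancer`).
#' @return A `clinrank_query` object.
#' @export
query_spec <- function(genes = character(), variants = character(),
                       keywords = character(), cancer_type = NULL) {
  genes <- unique(as.character(genes)); variants <- unique(as.character(variants))
  keywords <- unique(as.character(keywords))
  if (length(genes) + length(variants) + length(keywords) == 0) {
    abort("a query needs at least one gene, variant or keyword")
  }
  if (!is.null(cancer_type) &&
      !cancer_type %in% setdiff(CTYPE_LEVELS, "none")) {
    abort(paste0("unknown cancer_type '", cancer_type, "'"))
  }
  structure(list(genes = genes, variants = variants, keywords = keywords,
                 cancer_type = cancer_type), class = "clinrank_query")
}

#' Score an indexed corpus with the task models
#'
#' Computes raw cancer and clinical scores for every document, min-max
#' normalizes each score type over the whole corpus to \[0, 1\], multiplies
#' them into the rank score, casts the publication year to an integer sort
#' component and attaches the predicted cancer type. Normalization is
#' corpus-wide because the scores are query-independent and precomputed at
#' indexing time.
#'
#' @param docs Document tibble (the indexed corpus).
#' @param models Model list from [train_models()].
#' @return `docs` with columns `cancer_score`, `clinical_score`, `rank_score`
#'   (all in \[0, 1\]), `pub_year_int` and `ctype_label` filled.
#' @export
score_corpus <- function(docs, models) {
  raw <- predict_scores(models, docs)
  docs$cancer_score <- normalize_scores(raw$cancer_raw)
  docs$clinical_score <- normalize_scores(raw$clinical_raw)
  docs$rank_score <- docs$cancer_score * docs$clinical_score
  docs$pub_year_int <- as.integer(docs$pub_year)
  if (!all(is.na(raw$ctype_label))) docs$ctype_label <- raw$ctype_label
  docs
}

#' Fit corpus statistics for the vector-space keyword score
#'
#' Computes the unigram vocabulary and smoothed idf weights over the indexed
#' corpus, the statistics the keyword score's tf-idf cosine uses. Unlike the
#' supervised feature model there is no label and no feature selection.
#'
#' @param docs Document tibble.
#' @param cfg A [feature_config()]; defaults to unigrams with no minimum
#'   document frequency.
#' @return A `clinrank_features` object.
#' @export
fit_vsm <- function(docs, cfg = feature_config(ngram_range = c(1, 1),
                                               min_doc_freq = 1,
                                               max_features_chi2 = .Machine$integer.max)) {
  terms <- tokenize_terms(annotated_text(docs$title, docs$abstract), cfg)
  df_tab <- table(unlist(lapply(terms, unique)))
  vocab <- sort(names(df_tab[df_tab >= cfg$min_doc_freq]))
  if (length(vocab) == 0) abort("empty vocabulary")
  n <- nrow(docs)
  structure(list(cfg = cfg, vocab = vocab,
                 idf = log((1 + n) / (1 + as.numeric(df_tab[vocab]))) + 1,
                 chi2 = rep(NA_real_, length(vocab)), n_train = n),
            class = "clinrank_features")
}

query_terms <- function(query, lexicon = NULL) {
  genes <- if (!is.null(lexicon) && length(query$genes) > 0) {
    as.character(expand_gene_query(query$genes, lexicon))
  } else {
    query$genes
  }
  c(genes, query$variants, query$keywords)
}

#' Vector-space keyword score
#'
#' Cosine similarity between the tf-idf vector of the concatenated query
#' terms (synonym-expanded genes, variants, keywords) and each document's
#' tf-idf vector, both L2-normalized, so the score lies in \[0, 1\].
#'
#' @param docs Document tibble.
#' @param query A [query_spec()].
#' @param stats Corpus statistics from [fit_vsm()].
#' @param lexicon Optional gene lexicon for synonym expansion.
#' @return Tibble with `doc_id` and `keyword_score`.
#' @export
keyword_score <- function(docs, query, stats, lexicon = NULL) {
  terms <- query_terms(query, lexicon)
  qdoc <- tibble(doc_id = "query", title = paste(terms, collapse = " "),
                 abstract = "")
  qvec <- transform_features(stats, qdoc)
  x <- transform_features(stats, docs)
  tibble(doc_id = docs$doc_id,
         keyword_score = as.numeric(x %*% Matrix::t(qvec)))
}

doc_has_gene <- function(mentions, ids) {
  if (length(ids) == 0) return(FALSE)
  any(mentions$etype == "gene" & mentions$norm_id %in% ids)
}

doc_has_variant <- function(mentions, canon) {
  if (length(canon) == 0) return(FALSE)
  any(mentions$etype == "variant" & mentions$norm_id %in% canon)
}

#' Filter the candidate set of a query
#'
#' First, if the query names a cancer type, only documents classified as that
#' type are considered. Then a document is a candidate if it contains at
#' least one queried gene (matched on normalized gene id after synonym
#' expansion) OR one queried variant (matched on canonical form) OR one
#' keyword (case-insensitive token match in title and abstract) — disjunctive
#' semantics across the three slots.
#'
#' @param docs Annotated (and typically scored) document tibble.
#' @param query A [query_spec()].
#' @param lexicon Gene lexicon for symbol resolution (required when the query
#'   has genes).
#' @param fold_aa Fold 3-letter protein codes when canonicalizing query
#'   variants.
#' @return The candidate subset of `docs` (possibly empty).
#' @export
filter_candidates <- function(docs, query, lexicon = NULL, fold_aa = FALSE) {
  stopifnot(inherits(query, "clinrank_query"))
  if (!is.null(query$cancer_type)) {
    docs <- docs[!is.na(docs$ctype_label) & docs$ctype_label == query$cancer_type, ,
                 drop = FALSE]
  }
  if (nrow(docs) == 0) return(docs)
  gene_ids <- character()
  if (length(query$genes) > 0) {
    if (is.null(lexicon)) abort("gene queries need a lexicon")
    gene_ids <- attr(expand_gene_query(query$genes, lexicon), "ids")
  }
  canon <- canonical_variant(query$variants, fold_aa = fold_aa)
  keep_gene <- map_lgl(docs$mentions, doc_has_gene, ids = gene_ids)
  keep_var <- map_lgl(docs$mentions, doc_has_variant, canon = canon)
  keep_kw <- if (length(query$keywords) > 0) {
    contains_any_term(annotated_text(docs$title, docs$abstract), query$keywords)
  } else {
    rep(FALSE, nrow(docs))
  }
  docs[keep_gene | keep_var | keep_kw, , drop = FALSE]
}

#' Sort value of a scored document under a sort key
#'
#' `rank_score` and `cancer_score` are used as-is, `pubdate_x_rankscore`
#' multiplies the integer publication year into the rank score (recent
#' clinically relevant work first), and `keyword_score` is the query-specific
#' vector-space score.
#'
#' @param scored Scored document tibble (columns per [score_corpus()], plus
#'   `keyword_score` when that key is requested).
#' @param key One of `r paste(SORT_KEYS, collapse = ", ")`.
#' @return Numeric vector of sort values.
#' @export
compose_sort_value <- function(scored, key = SORT_KEYS) {
  key <- match.arg(key)
  switch(key,
    rank_score = scored$rank_score,
    pubdate_x_rankscore = scored$pub_year_int * scored$rank_score,
    cancer_score = scored$cancer_score,
    keyword_score = scored$keyword_score
  )
}

#' Rank candidate documents
#'
#' Stable descending sort by the composed sort value; ties are broken by
#' ascending document id so rankings are a deterministic total order.
#'
#' @inheritParams compose_sort_value
#' @return `scored` ordered by rank with `sort_value` and `rank` columns.
#' @export
rank_documents <- function(scored, key = SORT_KEYS) {
  key <- match.arg(key)
  scored |>
    mutate(sort_value = compose_sort_value(scored, key)) |>
    arrange(desc(.data$sort_value), .data$doc_id) |>
    mutate(rank = row_number())
}

#' Execute a query end to end
#'
#' Filters candidates, computes the keyword score, ranks by the requested
#' key and returns the result table.
#'
#' @param scored_docs Corpus tibble from [score_corpus()] with mentions.
#' @param query A [query_spec()].
#' @param lexicon Gene lexicon.
#' @param stats [fit_vsm()] statistics (needed for `keyword_score`).
#' @param sort_key Sort key, default the production `rank_score`.
#' @param fold_aa Passed to [filter_candidates()].
#' @return Result tibble: `rank`, `doc_id`, `sort_value`, `rank_score`,
#'   `cancer_score`, `clinical_score`, `keyword_score`, `pub_year`, `title`.
#' @export
search_documents <- function(scored_docs, query, lexicon = NULL, stats = NULL,
                             sort_key = "rank_score", fold_aa = FALSE) {
  cand <- filter_candidates(scored_docs, query, lexicon, fold_aa = fold_aa)
  if (nrow(cand) == 0) {
    return(tibble(rank = integer(), doc_id = character(), sort_value = numeric(),
                  rank_score = numeric(), cancer_score = numeric(),
                  clinical_score = numeric(), keyword_score = numeric(),
                  pub_year = integer(), title = character()))
  }
  cand$keyword_score <- if (!is.null(stats)) {
    keyword_score(cand, query, stats, lexicon)$keyword_score
  } else {
    rep(NA_real_, nrow(cand))
  }
  if (sort_key == "keyword_score" && is.null(stats)) {
    abort("sort key 'keyword_score' needs corpus statistics (fit_vsm)")
  }
  rank_documents(cand, sort_key) |>
    select("rank", "doc_id", "sort_value", "rank_score", "cancer_score",
           "clinical_score", "keyword_score", "pub_year", "title")
}
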