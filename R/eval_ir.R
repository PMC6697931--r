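# Ranked-retrieval evaluation: AP, RR, nDCG, the restricted P@k / R@k
# variant for small judged sets, the relevant-vs-irrelevant mean-rank ratio,
# the per-gene gold-standard protocol and the ranker comparison table.

#' Average precision of a ranking
#'
#' Mean over all relevant documents of the precision at their rank; relevant
#' documents missing from the ranking contribute zero (the sum is divided by
#' the total number of relevant documents).
#'
#' @param ranked_ids Character vector of document ids, best first.
#' @param relevant Character vector/set of relevant document ids.
#' @return AP in \[0, 1\]; `NA` when `relevant` is empty.
#' @export
average_precision <- function(ranked_ids, relevant) {
  if (length(relevant) == 0) return(NA_real_)
  is_rel <- ranked_ids %in% relevant
  if (!any(is_rel)) return(0)
  hit_ranks <- which(is_rel)
  prec_at_hit <- seq_along(hit_ranks) / hit_ranks
  sum(prec_at_hit) / length(unique(relevant))
}

#' Reciprocal rank of the first relevant document
#'
#' @inheritParams average_precision
#' @return 1 / rank of the first relevant document; 0 when none is
#'   retrieved; `NA` when `relevant` is empty.
#' @export
reciprocal_rank <- function(ranked_ids, relevant) {
  if (length(relevant) == 0) return(NA_real_)
  first <- which(ranked_ids %in% relevant)[1]
  if (is.na(first)) 0 else 1 / first
}

#' Normalized discounted cumulative gain (binary gains)
#'
#' DCG sums `1 / log2(i + 1)` over the ranks `i` of relevant documents (up to
#' `cutoff` when given); the ideal DCG places all relevant documents first.
#'
#' @inheritParams average_precision
#' @param cutoff Optional rank cutoff.
#' @return nDCG in \[0, 1\]; `NA` when `relevant` is empty.
#' @export
ndcg <- function(ranked_ids, relevant, cutoff = NULL) {
  n_rel <- length(unique(relevant))
  if (n_rel == 0) return(NA_real_)
  if (!is.null(cutoff)) ranked_ids <- ranked_ids[seq_len(min(cutoff, length(ranked_ids)))]
  gains <- as.numeric(ranked_ids %in% relevant)
  dcg <- sum(gains / log2(seq_along(gains) + 1))
  n_ideal <- if (is.null(cutoff)) n_rel else min(n_rel, cutoff)
  idcg <- sum(1 / log2(seq_len(n_ideal) + 1))
  dcg / idcg
}

#' Ratio of mean relevant rank to mean irrelevant rank
#'
#' The filtering-robust comparison metric: the mean 1-based rank of the
#' relevant documents divided by the mean rank of the irrelevant ones. Lower
#' is better — it means relevant documents sit systematically above
#' irrelevant ones, regardless of how far down the absolute ranks are.
#'
#' @param relevant_positions,irrelevant_positions Positive integer ranks of
#'   the judged documents in the full ranking.
#' @return Positive real; `NA` when there are no irrelevant positions.
#' @export
rel_vs_irrel <- function(relevant_positions, irrelevant_positions) {
  if (length(relevant_positions) == 0) return(NA_real_)
  stopifnot(all(relevant_positions >= 1), all(relevant_positions %% 1 == 0))
  if (length(irrelevant_positions) == 0) return(NA_real_)
  stopifnot(all(irrelevant_positions >= 1), all(irrelevant_positions %% 1 == 0))
  mean(relevant_positions) / mean(irrelevant_positions)
}

#' Rel-vs-IrRel of a ranking under a judgment set
#'
#' @param ranked_ids Document ids, best first.
#' @param relevant,irrelevant Judged document id sets (disjoint).
#' @return The mean-rank ratio computed from the positions of the judged
#'   documents present in the ranking.
#' @export
rel_vs_irrel_ranking <- function(ranked_ids, relevant, irrelevant) {
  rel_pos <- which(ranked_ids %in% relevant)
  irr_pos <- which(ranked_ids %in% irrelevant)
  if (length(rel_pos) == 0 || length(irr_pos) == 0) return(NA_real_)
  rel_vs_irrel(rel_pos, irr_pos)
}

#' Restricted precision and recall at k
#'
#' For small judged sets: the ranking is first restricted to judged documents
#' (relevant or irrelevant), preserving order, and `k` indexes positions in
#' that restricted list. `P@k` is the fraction of the first `k` restricted
#' documents that are relevant; `R@k` divides the same count by the number of
#' judged relevant documents.
#'
#' @param ranked_ids Document ids, best first.
#' @param relevant,irrelevant Disjoint judged id sets.
#' @param k Integer vector of cutoffs; defaults to every position of the
#'   restricted list. Values beyond the restricted length yield `NA`.
#' @return Tibble with columns `k`, `precision`, `recall`.
#' @export
restricted_pr_at_k <- function(ranked_ids, relevant, irrelevant, k = NULL) {
  if (length(intersect(relevant, irrelevant)) > 0) {
    abort("judged relevant and irrelevant sets must be disjoint")
  }
  restricted <- ranked_ids[ranked_ids %in% c(relevant, irrelevant)]
  len <- length(restricted)
  if (is.null(k)) k <- seq_len(len)
  k <- as.integer(k)
  rel_cum <- cumsum(restricted %in% relevant)
  n_rel <- length(unique(relevant))
  tibble(
    k = k,
    precision = ifelse(k >= 1 & k <= len, rel_cum[pmin(k, max(len, 1L))] / k, NA_real_),
    recall = ifelse(k >= 1 & k <= len,
                    if (n_rel == 0) NA_real_ else rel_cum[pmin(k, max(len, 1L))] / n_rel,
                    NA_real_)
  )
}

#' Per-query metrics of ranked results under judgments
#'
#' @param results Tibble with columns `query_id`, `doc_id` and `rank`
#'   (ascending best-first within each query).
#' @param judgments Tibble with `query_id`, `doc_id`, `relevant` (logical).
#' @param cutoff Optional nDCG cutoff.
#' @return Tibble with one row per query: `ap`, `rr`, `ndcg`,
#'   `rel_vs_irrel` (metrics are `NA` where undefined, e.g. no relevant
#'   documents judged for the query).
#' @export
evaluate_rankings <- function(results, judgments, cutoff = NULL) {
  stopifnot(all(c("query_id", "doc_id", "rank") %in% names(results)),
            all(c("query_id", "doc_id", "relevant") %in% names(judgments)))
  queries <- unique(judgments$query_id)
  rows <- map(queries, function(q) {
    ranked <- results |> filter(.data$query_id == q) |> arrange(.data$rank) |> pull("doc_id")
    j <- judgments |> filter(.data$query_id == q)
    rel <- j$doc_id[j$relevant]
    irr <- j$doc_id[!j$relevant]
    tibble(query_id = q,
           n_relevant = length(rel), n_irrelevant = length(irr),
           ap = average_precision(ranked, rel),
           rr = reciprocal_rank(ranked, rel),
           ndcg = ndcg(ranked, rel, cutoff),
           rel_vs_irrel = rel_vs_irrel_ranking(ranked, rel, irr))
  })
  bind_rows(rows)
}

#' Compare named rankers over shared judgment sets
#'
#' Computes MAP, MRR and mean nDCG per ranker (means over queries where the
#' metric is defined) and counts, per ranker, the queries on which its
#' Rel-vs-IrRel ratio is best; ties credit every tied ranker.
#'
#' @param results Tibble with columns `ranker`, `query_id`, `doc_id`, `rank`.
#' @param judgments Judgment tibble as in [evaluate_rankings()].
#' @param cutoff Optional nDCG cutoff.
#' @return A `clinrank_ranker_comparison` tibble: one row per ranker with
#'   `map`, `mrr`, `ndcg`, `n_best_rel_vs_irrel`, `n_queries`.
#' @export
compare_rankers <- function(results, judgments, cutoff = NULL) {
  rankers <- unique(results$ranker)
  if (length(rankers) < 2) abort("need at least 2 rankers to compare")
  per_query <- bind_rows(lapply(rankers, function(rk) {
    evaluate_rankings(results[results$ranker == rk, , drop = FALSE],
                      judgments, cutoff) |>
      mutate(ranker = rk)
  }))
  best_counts <- per_query |>
    filter(!is.na(.data$rel_vs_irrel)) |>
    group_by(.data$query_id) |>
    filter(.data$rel_vs_irrel <= min(.data$rel_vs_irrel) + 1e-12) |>
    ungroup() |>
    count(.data$ranker, name = "n_best_rel_vs_irrel")
  summary <- per_query |>
    group_by(.data$ranker) |>
    summarise(map = mean(.data$ap, na.rm = TRUE),
              mrr = mean(.data$rr, na.rm = TRUE),
              ndcg = mean(.data$ndcg, na.rm = TRUE),
              n_queries = dplyr::n_distinct(.data$query_id),
              .groups = "drop") |>
    left_join(best_counts, by = "ranker") |>
    mutate(n_best_rel_vs_irrel = tidyr::replace_na(.data$n_best_rel_vs_irrel, 0L))
  structure(summary, per_query = per_query,
            class = c("clinrank_ranker_comparison", class(summary)))
}

#' Per-gene gold-standard ranking evaluation
#'
#' The silver-standard protocol for choosing a ranking function: for every
#' gene in the gold map, issue a single-gene query (synonym-expanded),
#' retrieve all documents mentioning the gene, rank them under each sort key
#' and score the gold documents as the relevant set (recall of gold documents
#' among those retrieved, AP, RR, nDCG). Genes retrieving no documents are
#' counted and reported with `NA` metrics.
#'
#' @param scored_docs Annotated + scored corpus tibble.
#' @param gold Tibble with columns `gene` (symbol) and `doc_id`.
#' @param lexicon Gene lexicon.
#' @param sort_keys Sort keys to evaluate.
#' @param stats [fit_vsm()] statistics, required when `keyword_score` is
#'   among the keys.
#' @param pooled_recall Also report recall pooled over genes (total gold
#'   documents retrieved / total gold documents) instead of only the
#'   per-gene mean.
#' @return Tibble with one row per sort key: mean `recall`, `map`, `mrr`,
#'   `ndcg`, `n_queries`, `n_empty` (+ `pooled_recall` when requested);
#'   per-gene detail in the `detail` attribute.
#' @export
per_gene_gold_eval <- function(scored_docs, gold, lexicon,
                               sort_keys = c("rank_score", "keyword_score"),
                               stats = NULL, pooled_recall = FALSE) {
  stopifnot(all(c("gene", "doc_id") %in% names(gold)))
  if ("keyword_score" %in% sort_keys && is.null(stats)) {
    abort("sort key 'keyword_score' needs corpus statistics (fit_vsm)")
  }
  genes <- unique(gold$gene)
  detail <- bind_rows(lapply(genes, function(g) {
    gold_ids <- unique(gold$doc_id[gold$gene == g])
    q <- query_spec(genes = g)
    cand <- filter_candidates(scored_docs, q, lexicon)
    if (nrow(cand) == 0) {
      return(tibble(gene = g, sort_key = sort_keys, n_retrieved = 0L,
                    recall = NA_real_, ap = NA_real_, rr = NA_real_,
                    ndcg = NA_real_, n_gold = length(gold_ids),
                    n_gold_retrieved = 0L))
    }
    if ("keyword_score" %in% sort_keys) {
      cand$keyword_score <- keyword_score(cand, q, stats, lexicon)$keyword_score
    }
    bind_rows(lapply(sort_keys, function(key) {
      ranked <- rank_documents(cand, key)$doc_id
      got <- sum(gold_ids %in% ranked)
      tibble(gene = g, sort_key = key, n_retrieved = length(ranked),
             recall = got / length(gold_ids),
             ap = average_precision(ranked, gold_ids),
             rr = reciprocal_rank(ranked, gold_ids),
             ndcg = ndcg(ranked, gold_ids),
             n_gold = length(gold_ids), n_gold_retrieved = got)
    }))
  }))
  out <- detail |>
    group_by(.data$sort_key) |>
    summarise(recall = mean(.data$recall, na.rm = TRUE),
              map = mean(.data$ap, na.rm = TRUE),
              mrr = mean(.data$rr, na.rm = TRUE),
              ndcg = mean(.data$ndcg, na.rm = TRUE),
              n_queries = n(),
              n_empty = sum(.data$n_retrieved == 0),
              pooled_recall = sum(.data$n_gold_retrieved) / sum(.data$n_gold),
              .groups = "drop")
  if (!pooled_recall) out$pooled_recall <- NULL
  structure(out, detail = detail, class = c("clinrank_gold_eval", class(out)))
}
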