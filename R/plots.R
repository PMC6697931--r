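# ggplot2 views of the evaluation outputs.

#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_point facet_wrap
#'   labs position_dodge scale_y_continuous theme_minimal
NULL

#' Plot per-class precision / recall / F1 of a classifier evaluation
#'
#' @param object A `clinrank_classifier_eval` from [evaluate_classifier()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.clinrank_classifier_eval <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value") |>
    filter(!is.na(.data$value))
  ggplot(df, aes(x = .data$class, y = .data$value, fill = .data$metric)) +
    geom_col(position = position_dodge()) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(title = paste0("Classifier performance (",
                        attr(object, "task"), ", ", attr(object, "learner"), ")"),
         x = NULL, y = NULL, fill = NULL) +
    theme_minimal()
}

#' Plot ranker comparison metrics
#'
#' Bar panels of MAP, MRR and mean nDCG per ranker, the shape of a
#' comparative-evaluation table.
#'
#' @param object A `clinrank_ranker_comparison` from [compare_rankers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.clinrank_ranker_comparison <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("map", "mrr", "ndcg"),
                        names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$ranker, y = .data$value)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = NULL, title = "Ranker comparison") +
    theme_minimal()
}

#' Restricted precision/recall-at-k curves for several rankers
#'
#' For each ranker and query, restricts the ranking to judged documents,
#' computes P@k and R@k along the restricted list and averages over queries
#' at each k (dropping k values beyond a query's restricted length).
#'
#' @param results Tibble with `ranker`, `query_id`, `doc_id`, `rank`.
#' @param judgments Judgment tibble (`query_id`, `doc_id`, `relevant`).
#' @param max_k Largest k to display; defaults to the longest restricted list.
#' @return A ggplot object with one panel per measure.
#' @export
plot_pr_at_k <- function(results, judgments, max_k = NULL) {
  curves <- bind_rows(lapply(unique(results$ranker), function(rk) {
    bind_rows(lapply(unique(judgments$query_id), function(q) {
      ranked <- results |>
        filter(.data$ranker == rk, .data$query_id == q) |>
        arrange(.data$rank) |> pull("doc_id")
      j <- judgments |> filter(.data$query_id == q)
      restricted_pr_at_k(ranked, j$doc_id[j$relevant], j$doc_id[!j$relevant]) |>
        mutate(ranker = rk, query_id = q)
    }))
  }))
  if (!is.null(max_k)) curves <- filter(curves, .data$k <= max_k)
  df <- curves |>
    group_by(.data$ranker, .data$k) |>
    summarise(precision = mean(.data$precision, na.rm = TRUE),
              recall = mean(.data$recall, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_longer(c("precision", "recall"),
                        names_to = "measure", values_to = "value")
  ggplot(df, aes(x = .data$k, y = .data$value, colour = .data$ranker)) +
    geom_line() + geom_point(size = 1) +
    facet_wrap(~measure) +
    labs(x = "k (judged documents)", y = NULL, colour = NULL,
         title = "Restricted precision/recall at k") +
    theme_minimal()
}
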