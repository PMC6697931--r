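# Brute-force reference implementations computed directly from definitions.
# They are deliberately independent of the package's code paths.

oracle_ap <- function(rel_flags, n_relevant) {
  if (n_relevant == 0) return(NA_real_)
  total <- 0
  hits <- 0
  for (i in seq_along(rel_flags)) {
    if (rel_flags[i]) {
      hits <- hits + 1
      total <- total + hits / i
    }
  }
  total / n_relevant
}

oracle_rr <- function(rel_flags) {
  for (i in seq_along(rel_flags)) if (rel_flags[i]) return(1 / i)
  0
}

oracle_ndcg <- function(rel_flags, n_relevant, cutoff = NULL) {
  if (n_relevant == 0) return(NA_real_)
  if (!is.null(cutoff)) rel_flags <- rel_flags[seq_len(min(cutoff, length(rel_flags)))]
  dcg <- 0
  for (i in seq_along(rel_flags)) if (rel_flags[i]) dcg <- dcg + 1 / log2(i + 1)
  n_ideal <- if (is.null(cutoff)) n_relevant else min(n_relevant, cutoff)
  idcg <- 0
  for (i in seq_len(n_ideal)) idcg <- idcg + 1 / log2(i + 1)
  dcg / idcg
}

oracle_p_at_k <- function(rel_flags, k) sum(rel_flags[seq_len(k)]) / k
oracle_r_at_k <- function(rel_flags, k, n_relevant) sum(rel_flags[seq_len(k)]) / n_relevant

# chi-squared statistic of one term from its explicit 2 x C contingency table
oracle_chi2_term <- function(present, labels) {
  tab <- table(factor(present, levels = c(FALSE, TRUE)), labels)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  sum(ifelse(expected > 0, (tab - expected)^2 / expected, 0))
}

# smoothed tf-idf with L2 normalization, computed term by term
oracle_tfidf_matrix <- function(token_lists, vocab) {
  n <- length(token_lists)
  df <- sapply(vocab, function(t) sum(sapply(token_lists, function(d) t %in% d)))
  idf <- log((1 + n) / (1 + df)) + 1
  x <- t(sapply(token_lists, function(d) sapply(vocab, function(t) sum(d == t)) * idf))
  norms <- sqrt(rowSums(x^2))
  norms[norms == 0] <- 1
  x / norms
}
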