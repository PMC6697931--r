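# Word n-gram tf-idf features with chi-squared selection.
#
# tf-idf follows the smoothed convention tf(t,d) * (ln((1+N)/(1+df(t))) + 1)
# with document vectors L2-normalized, so a term present in every training
# document still carries weight 1 and cosine similarities stay in [0, 1].

#' Feature configuration
#'
#' @param ngram_range Integer pair (min, max) of word n-gram lengths,
#'   1 <= min <= max <= 3.
#' @param max_features_chi2 Number of features kept by chi-squared selection
#'   (capped at the vocabulary size).
#' @param min_doc_freq Minimum number of training documents a term must occur
#'   in to enter the vocabulary.
#' @param lowercase Lowercase text before tokenization.
#' @param token_pattern Regex for a single word token.
#' @return A `clinrank_feature_config` list.
#' @export
feature_config <- function(ngram_range = c(1, 2), max_features_chi2 = 20000,
                           min_doc_freq = 2, lowercase = TRUE,
                           token_pattern = "[A-Za-z0-9]+(?:-[A-Za-z0-9]+)*") {
  stopifnot(length(ngram_range) == 2, ngram_range[1] >= 1,
            ngram_range[1] <= ngram_range[2], ngram_range[2] <= 3,
            max_features_chi2 >= 1, min_doc_freq >= 1)
  structure(list(ngram_range = as.integer(ngram_range),
                 max_features_chi2 = as.integer(max_features_chi2),
                 min_doc_freq = as.integer(min_doc_freq),
                 lowercase = isTRUE(lowercase),
                 token_pattern = token_pattern),
            class = "clinrank_feature_config")
}

tokenize_terms <- function(text, cfg) {
  if (cfg$lowercase) text <- tolower(text)
  toks <- stringr::str_extract_all(text, cfg$token_pattern)
  lapply(toks, function(tk) {
    if (length(tk) == 0) return(character())
    out <- list()
    for (n in cfg$ngram_range[1]:cfg$ngram_range[2]) {
      if (length(tk) < n) next
      out[[length(out) + 1L]] <- if (n == 1) tk else
        vapply(seq_len(length(tk) - n + 1L),
               function(i) paste(tk[i:(i + n - 1L)], collapse = " "), "")
    }
    unlist(out)
  })
}

# sparse doc-term count matrix over a fixed vocabulary (named index map)
count_matrix <- function(term_lists, vocab) {
  idx <- seq_along(vocab)
  names(idx) <- vocab
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- integer(0)
  for (d in seq_along(term_lists)) {
    tt <- table(term_lists[[d]])
    j <- idx[names(tt)]
    ok <- !is.na(j)
    if (any(ok)) {
      trip_i <- c(trip_i, rep.int(d, sum(ok)))
      trip_j <- c(trip_j, unname(j[ok]))
      trip_x <- c(trip_x, as.integer(tt[ok]))
    }
  }
  sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
               dims = c(length(term_lists), length(vocab)),
               dimnames = list(NULL, vocab))
}

# chi2 statistic per term of the presence/absence x class contingency table
chi2_stats <- function(presence, labels) {
  labels <- factor(labels)
  n <- length(labels)
  classes <- levels(labels)
  tot_pres <- Matrix::colSums(presence)
  chi2 <- numeric(ncol(presence))
  for (cl in classes) {
    in_cl <- labels == cl
    nc <- sum(in_cl)
    pres_c <- Matrix::colSums(presence[in_cl, , drop = FALSE])
    e_pres <- nc * tot_pres / n
    e_abs <- nc * (n - tot_pres) / n
    d_pres <- ifelse(e_pres > 0, (pres_c - e_pres)^2 / e_pres, 0)
    d_abs <- ifelse(e_abs > 0, ((nc - pres_c) - e_abs)^2 / e_abs, 0)
    chi2 <- chi2 + d_pres + d_abs
  }
  chi2
}

#' Fit the tf-idf feature model on a training corpus
#'
#' Builds the word n-gram vocabulary (terms occurring in at least
#' `min_doc_freq` training documents), computes smoothed idf weights, scores
#' every term with the chi-squared statistic of its presence/absence against
#' the task label, and keeps the `max_features_chi2` highest-scoring terms
#' (ties broken alphabetically for determinism).
#'
#' @param docs Training document tibble.
#' @param labels Task label per document (factor or vector; >= 2 classes).
#' @param cfg A [feature_config()].
#' @return A `clinrank_features` object with the selected vocabulary, idf
#'   weights and chi-squared scores.
#' @export
fit_features <- function(docs, labels, cfg = feature_config()) {
  stopifnot(nrow(docs) == length(labels))
  if (length(unique(labels)) < 2) abort("need at least 2 classes to fit features")
  terms <- tokenize_terms(annotated_text(docs$title, docs$abstract), cfg)
  df_tab <- table(unlist(lapply(terms, unique)))
  vocab <- sort(names(df_tab[df_tab >= cfg$min_doc_freq]))
  if (length(vocab) == 0) abort("empty vocabulary after min_doc_freq filtering")
  counts <- count_matrix(terms, vocab)
  n <- nrow(docs)
  df_vec <- as.numeric(df_tab[vocab])
  chi2 <- chi2_stats(counts > 0, labels)
  k <- min(cfg$max_features_chi2, length(vocab))
  keep <- order(-chi2, vocab)[seq_len(k)]
  keep <- sort(keep)
  structure(list(
    cfg = cfg,
    vocab = vocab[keep],
    idf = log((1 + n) / (1 + df_vec[keep])) + 1,
    chi2 = chi2[keep],
    n_train = n
  ), class = "clinrank_features")
}

#' Transform documents into L2-normalized tf-idf vectors
#'
#' @param features A fitted `clinrank_features` object.
#' @param docs Document tibble.
#' @return A sparse matrix (documents x selected terms); rows with no
#'   vocabulary term are all-zero, all other rows have unit L2 norm.
#' @export
transform_features <- function(features, docs) {
  terms <- tokenize_terms(annotated_text(docs$title, docs$abstract), features$cfg)
  x <- count_matrix(terms, features$vocab)
  x <- x %*% Diagonal(x = features$idf)
  norms <- sqrt(Matrix::rowSums(x^2))
  norms[norms == 0] <- 1
  x <- Diagonal(x = 1 / norms) %*% x
  dimnames(x) <- list(docs$doc_id, features$vocab)
  x
}
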