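# Small in-code fixtures shared across test files.

braf_lexicon <- function() {
  lexicon_tibble(c("673", "3845"), c("BRAF", "KRAS"),
                 list(c("BRAF", "B-RAF1"), c("KRAS", "KRAS2FAKE")),
                 kind = "gene")
}

drug_lexicon_small <- function() {
  lexicon_tibble(c("D1", "D2"), c("Vemurafenib", "nab-paclitaxel"),
                 list("Vemurafenib", c("nab-paclitaxel", "paclitaxel")),
                 kind = "drug")
}

# one-article PubMed XML (sections = character vector of AbstractText nodes)
pubmed_article_xml <- function(pmid = "123", title = "T", sections = "A",
                               year = "2018") {
  abstract <- if (length(sections) == 0) "" else paste0(
    "<Abstract>", paste0("<AbstractText>", sections, "</AbstractText>",
                         collapse = ""), "</Abstract>")
  pmid_tag <- if (nzchar(pmid)) paste0("<PMID>", pmid, "</PMID>") else ""
  paste0("<PubmedArticle><MedlineCitation>", pmid_tag,
         "<Article><ArticleTitle>", title, "</ArticleTitle>", abstract,
         "<Journal><Title>J Test</Title><JournalIssue><PubDate><Year>", year,
         "</Year></PubDate></JournalIssue></Journal></Article>",
         "</MedlineCitation></PubmedArticle>")
}

write_pubmed_xml <- function(articles, path = withr::local_tempfile(fileext = ".xml",
                                                                    .local_envir = parent.frame())) {
  writeLines(paste0("<?xml version=\"1.0\"?><PubmedArticleSet>",
                    paste(articles, collapse = ""), "</PubmedArticleSet>"), path)
  path
}

# labeled corpus that is linearly separable by construction: class A docs use
# only A-vocabulary, class B docs only B-vocabulary
tiny_separable_corpus <- function(n_per_class = 20, seed = 42) {
  withr::with_seed(seed, {
    a_vocab <- paste0("alpha", 1:8)
    b_vocab <- paste0("beta", 1:8)
    mk <- function(vocab, n, prefix) {
      tibble::tibble(
        doc_id = paste0(prefix, seq_len(n)),
        title = replicate(n, paste(sample(vocab, 4, TRUE), collapse = " ")),
        abstract = replicate(n, paste(sample(vocab, 12, TRUE), collapse = " ")),
        pub_year = 2010L, journal = "",
        mentions = replicate(n, empty_mentions(), simplify = FALSE),
        ctype_label = NA_character_
      )
    }
    docs <- dplyr::bind_rows(mk(a_vocab, n_per_class, "a"), mk(b_vocab, n_per_class, "b"))
    docs$label_cancer <- rep(c(TRUE, FALSE), each = n_per_class)
    docs$label_clinical <- docs$label_cancer
    docs$label_ctype <- factor(ifelse(docs$label_cancer, "general_cancer", "none"),
                               levels = c("melanoma", "head_and_neck", "colorectal",
                                          "general_cancer", "none"))
    docs
  })
}

# hand-built linear model: predicts from fixed per-term weights, used to force
# exact confusion counts in evaluation tests
manual_linear_model <- function(task, classes, vocab, W, b) {
  features <- structure(
    list(cfg = feature_config(ngram_range = c(1, 1), min_doc_freq = 1,
                              max_features_chi2 = length(vocab)),
         vocab = vocab, idf = rep(1, length(vocab)),
         chi2 = rep(NA_real_, length(vocab)), n_train = 2L),
    class = "clinrank_features")
  structure(list(
    task = task, learner = "linear_svm", features = features,
    fit = list(kind = "linear_weights", model = list(W = W, b = b),
               classes = classes),
    classes = classes, best_params = list(cost = 1), cv_results = NULL,
    cv_f1 = NA_real_, score_range = c(-1, 1), n_train = 2L, seed = 1L
  ), class = "clinrank_task_model")
}
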