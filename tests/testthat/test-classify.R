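test_that("idf and L2 normalization follow the smoothed tf-idf definition", {
  docs <- document_tibble(paste0("d", 1:3),
                          title = c("apple banana", "apple cherry", "apple apple date"))
  cfg <- feature_config(ngram_range = c(1, 1), min_doc_freq = 1,
                        max_features_chi2 = 100)
  labels <- c("x", "x", "y")
  fm <- fit_features(docs, labels, cfg)
  # a term present in all N documents has idf = ln((1+N)/(1+N)) + 1 = 1
  expect_equal(fm$idf[fm$vocab == "apple"], 1)
  x <- transform_features(fm, docs)
  expect_equal(unname(sqrt(Matrix::rowSums(x^2))), rep(1, 3))
  # document with no vocabulary term is all-zero
  x0 <- transform_features(fm, document_tibble("z", "nothing matches here"))
  expect_equal(sum(x0^2), 0)
  # matches the brute-force tf-idf matrix
  toks <- list(c("apple", "banana"), c("apple", "cherry"), c("apple", "apple", "date"))
  oracle <- oracle_tfidf_matrix(toks, fm$vocab)
  expect_equal(unname(as.matrix(x)), unname(oracle), tolerance = 1e-12)
})

test_that("chi-squared selection matches brute-force 2x2 ranking on small corpora", {
  withr::with_seed(5, {
    vocab <- paste0("w", 1:10)
    n <- 40
    labels <- rep(c("a", "b"), each = n / 2)
    toks <- lapply(seq_len(n), function(i) {
      base <- sample(vocab[1:6], 5, TRUE)
      if (labels[i] == "a") c(base, "w7") else c(base, sample(c("w8", "w9"), 1))
    })
    docs <- document_tibble(paste0("d", 1:n),
                            title = vapply(toks, paste, "", collapse = " "))
  })
  cfg <- feature_config(ngram_range = c(1, 1), min_doc_freq = 1,
                        max_features_chi2 = 4)
  fm <- fit_features(docs, labels, cfg)
  all_cfg <- feature_config(ngram_range = c(1, 1), min_doc_freq = 1,
                            max_features_chi2 = 1000)
  fm_all <- fit_features(docs, labels, all_cfg)
  oracle <- vapply(fm_all$vocab, function(t) {
    present <- vapply(toks, function(d) t %in% d, TRUE)
    oracle_chi2_term(present, labels)
  }, numeric(1))
  expect_equal(unname(fm_all$chi2), unname(oracle), tolerance = 1e-12)
  top4 <- fm_all$vocab[order(-oracle, fm_all$vocab)][1:4]
  expect_setequal(fm$vocab, top4)
  # a class-exclusive term outranks equally frequent non-discriminative ones
  expect_true("w7" %in% fm$vocab)
  # K larger than the vocabulary keeps everything
  expect_equal(length(fm_all$vocab), length(unique(unlist(toks))))
})

test_that("training-corpus construction applies the silver-standard labeling rules", {
  positives <- tibble::tibble(
    doc_id = c("p1", "p2", "p3", "p4"),
    title = c("ra study", "lung study", "melanoma study", "crc study"),
    abstract = c("joint disease", "lung tumor driver", "skin lesion", "colon lesion"),
    disease = c("rheumatoid arthritis", "lung cancer", "melanoma", "colorectal cancer"),
    cancer_type = c("", "lung cancer", "melanoma", "colorectal cancer")
  )
  pool <- document_tibble(paste0("n", 1:30),
                          title = c(rep("a tumor paper", 10), rep("a plain paper", 20)),
                          abstract = "text body here")
  corpus <- build_training_corpus(positives, pool, cancer_terms = c("tumor", "cancer"),
                                  n_negatives = 15, seed = 3)
  pos <- corpus[corpus$doc_id %in% positives$doc_id, ]
  expect_true(all(pos$label_clinical))
  expect_false(pos$label_cancer[pos$doc_id == "p1"])  # non-cancer disease
  expect_equal(as.character(pos$label_ctype[pos$doc_id == "p1"]), "none")
  expect_equal(as.character(pos$label_ctype[pos$doc_id == "p2"]), "general_cancer")
  expect_equal(as.character(pos$label_ctype[pos$doc_id == "p3"]), "melanoma")
  expect_equal(as.character(pos$label_ctype[pos$doc_id == "p4"]), "colorectal")
  neg <- corpus[!corpus$doc_id %in% positives$doc_id, ]
  expect_equal(nrow(neg), 15)
  expect_true(all(grepl("plain", neg$title)))  # term-containing docs excluded
  expect_true(all(!neg$label_cancer & !neg$label_clinical))
  expect_error(
    build_training_corpus(positives, pool, c("paper"), n_negatives = 5, seed = 1),
    "available")
})

test_that("stratified split respects fractions, determinism and error cases", {
  docs <- tiny_separable_corpus(50)
  sp <- split_train_test(docs, 0.85, seed = 9)
  expect_equal(nrow(sp$train) + nrow(sp$test), 100)
  n_pos_train <- sum(sp$train$label_cancer)
  expect_true(n_pos_train %in% c(42L, 43L))
  expect_equal(length(intersect(sp$train$doc_id, sp$test$doc_id)), 0)
  sp2 <- split_train_test(docs, 0.85, seed = 9)
  expect_identical(sp$train$doc_id, sp2$train$doc_id)
  expect_error(split_train_test(docs, 1.0, seed = 1), "between 0 and 1")
  expect_error(split_train_test(docs[1, ], 0.85, seed = 1), "fewer than 2")
})

test_that("a linearly separable corpus is learned perfectly and deterministically", {
  docs <- tiny_separable_corpus(20)
  cfg <- feature_config(ngram_range = c(1, 1), min_doc_freq = 1,
                        max_features_chi2 = 50)
  m1 <- train_task_model("cancer", "linear_svm", docs, cfg,
                         search_budget = 3, seed = 4)
  expect_equal(m1$cv_f1, 1.0)
  m2 <- train_task_model("cancer", "linear_svm", docs, cfg,
                         search_budget = 3, seed = 4)
  expect_identical(m1$best_params, m2$best_params)
  expect_identical(predict_labels(m1, docs), predict_labels(m2, docs))
  # budget 1 trains the single sampled configuration
  m3 <- train_task_model("cancer", "linear_svm", docs, cfg,
                         search_budget = 1, seed = 4)
  expect_equal(nrow(m3$cv_results), 1)
  # too-small classes are rejected (5-fold CV needs 5 per class)
  small <- docs[c(1:4, 21:40), ]
  expect_error(train_task_model("cancer", "linear_svm", small, cfg, 1, 1),
               "fewer than 5")
})

test_that("random forests learn the separable corpus and are seed-stable", {
  docs <- tiny_separable_corpus(20)
  cfg <- feature_config(ngram_range = c(1, 1), min_doc_freq = 1,
                        max_features_chi2 = 50)
  m1 <- train_task_model("clinical", "random_forest", docs, cfg,
                         search_budget = 2, seed = 8)
  expect_gte(m1$cv_f1, 0.95)
  m2 <- train_task_model("clinical", "random_forest", docs, cfg,
                         search_budget = 2, seed = 8)
  expect_equal(model_raw_scores(m1, docs), model_raw_scores(m2, docs))
})

test_that("predict_scores returns finite raw scores, the argmax type and is pure", {
  b <- generate_corpus(generator_config(n_docs = 250, overlap = 0, seed = 12))
  sp <- split_train_test(b$documents, 0.85, seed = 1)
  cfg <- feature_config(ngram_range = c(1, 1), min_doc_freq = 2,
                        max_features_chi2 = 400)
  models <- train_models(sp$train, "linear_svm", cfg, search_budget = 2, seed = 5)
  out <- predict_scores(models, sp$test)
  expect_true(all(is.finite(out$cancer_raw)))
  expect_true(all(is.finite(out$clinical_raw)))
  out2 <- predict_scores(models, sp$test)
  expect_identical(out, out2)
  # scores computed on the title alone when the abstract is empty
  bare <- document_tibble("t1", title = sp$test$title[1], abstract = "")
  expect_true(is.finite(predict_scores(models, bare)$cancer_raw))
  if (!is.null(models$ctype)) {
    expect_true(all(out$ctype_label %in% models$ctype$classes))
    expect_true(all(out$ctype_margin >= 0))
  }
})

test_that("classifier evaluation reports exact precision/recall/F1 and macro", {
  # two-term feature space; the manual model predicts positive iff term "hot"
  # outweighs "cold", giving controlled confusion counts
  model <- manual_linear_model("cancer", c("non_cancer", "cancer"),
                               c("cold", "hot"),
                               W = matrix(c(-1, 1), ncol = 1,
                                          dimnames = list(c("cold", "hot"), "cancer")),
                               b = c(cancer = 0))
  docs <- document_tibble(paste0("d", 1:4),
                          title = c("hot", "hot", "hot", "cold"))
  docs$label_cancer <- c(TRUE, TRUE, FALSE, TRUE)   # TP=2 FP=1 FN=1
  docs$label_clinical <- docs$label_cancer
  ev <- evaluate_classifier(model, docs)
  pos <- ev[ev$class == "cancer", ]
  expect_equal(pos$precision, 2 / 3)
  expect_equal(pos$recall, 2 / 3)
  expect_equal(pos$f1, 2 / 3)

  all_right <- docs[docs$label_cancer == (docs$title == "hot"), ]
  ev2 <- evaluate_classifier(model, all_right)
  expect_equal(ev2$f1[ev2$class == "macro"], 1.0)

  flipped <- docs
  flipped$label_cancer <- docs$title == "cold"
  flipped$label_clinical <- flipped$label_cancer
  ev3 <- evaluate_classifier(model, flipped)
  expect_equal(ev3$f1[ev3$class == "cancer"], 0)

  # a class absent from the test set is reported NA and excluded from macro
  only_pos <- docs[docs$label_cancer, ]
  ev4 <- evaluate_classifier(model, only_pos)
  expect_true(is.na(ev4$precision[ev4$class == "non_cancer"]))
  expect_equal(ev4$recall[ev4$class == "macro"],
               ev4$recall[ev4$class == "cancer"])
})

test_that("linear model bundles round-trip through text and forests refuse", {
  docs <- tiny_separable_corpus(20)
  cfg <- feature_config(ngram_range = c(1, 1), min_doc_freq = 1,
                        max_features_chi2 = 50)
  m <- train_task_model("cancer", "linear_svm", docs, cfg, 2, seed = 2)
  dir <- withr::local_tempdir()
  write_model_bundle(m, dir)
  back <- read_model_bundle(dir)
  expect_equal(model_raw_scores(back, docs), model_raw_scores(m, docs),
               tolerance = 1e-9)
  expect_identical(predict_labels(back, docs), predict_labels(m, docs))
  rf <- train_task_model("cancer", "random_forest", docs, cfg, 1, seed = 2)
  expect_error(write_model_bundle(rf, withr::local_tempdir()), "text")
})

test_that("tidy and glance summarise fitted models", {
  docs <- tiny_separable_corpus(20)
  cfg <- feature_config(ngram_range = c(1, 1), min_doc_freq = 1,
                        max_features_chi2 = 50)
  m <- train_task_model("cancer", "linear_svm", docs, cfg, 2, seed = 2)
  td <- generics::tidy(m)
  expect_true(all(c("term", "weight") %in% names(td)))
  # alpha vocabulary drives the cancer class positively
  top <- td$term[1:3]
  expect_true(any(grepl("^alpha", top)))
  gl <- generics::glance(m)
  expect_equal(gl$task, "cancer")
  expect_true("cost" %in% names(gl))
  rf <- train_task_model("cancer", "random_forest", docs, cfg, 1, seed = 2)
  expect_true("importance" %in% names(generics::tidy(rf)))
})
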