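# Silver-standard corpus construction and the three query-independent
# document classifiers: cancer-relatedness, clinical relevance, cancer type.

map_ctype <- function(cancer_type) {
  ct <- tolower(trimws(ifelse(is.na(cancer_type), "", cancer_type)))
  dplyr::case_when(
    ct == "" ~ "none",
    stringr::str_detect(ct, "melanoma") ~ "melanoma",
    stringr::str_detect(ct, "head") & stringr::str_detect(ct, "neck") ~ "head_and_neck",
    stringr::str_detect(ct, "colorectal|colon|rectal") ~ "colorectal",
    TRUE ~ "general_cancer"
  )
}

contains_any_term <- function(text, terms) {
  if (length(terms) == 0) return(rep(FALSE, length(text)))
  hit <- rep(FALSE, length(text))
  for (term in terms) {
    hit <- hit | stringr::str_detect(
      text, stringr::regex(boundary_regex(term), ignore_case = TRUE))
  }
  hit
}

#' Build the three-task training corpus from weak labels
#'
#' Implements the silver-standard labeling rules: every positive (curated
#' knowledge-base) record is clinically relevant; positives whose disease
#' annotation lies outside cancer (empty `cancer_type`) are cancer-negative
#' and excluded from the type task; the three named cancer types keep their
#' own class and every other cancer type is folded into `general_cancer`.
#' Negatives are a seeded uniform sample of pool documents whose title and
#' abstract contain no cancer-related term (case-insensitive, token-boundary
#' match), labeled negative for all tasks.
#'
#' @param positives Tibble with columns `doc_id`, `title`, `abstract`,
#'   `cancer_type` (empty or `NA` when the disease is not a cancer) and
#'   optionally `pub_year`, `journal`.
#' @param negative_pool Document tibble to sample negatives from.
#' @param cancer_terms Character vector of cancer-related filter terms.
#' @param n_negatives Number of negatives to sample.
#' @param seed Integer seed for the sample.
#' @return A labeled document tibble with logical `label_cancer`,
#'   `label_clinical` and factor `label_ctype` columns.
#' @export
build_training_corpus <- function(positives, negative_pool, cancer_terms,
                                  n_negatives, seed) {
  stopifnot(all(c("doc_id", "title", "abstract", "cancer_type") %in% names(positives)))
  pos <- tibble(
    doc_id = as.character(positives$doc_id),
    title = positives$title,
    abstract = positives$abstract,
    pub_year = if ("pub_year" %in% names(positives)) {
      as.integer(positives$pub_year)
    } else {
      rep(YEAR_UNKNOWN, nrow(positives))
    },
    journal = if ("journal" %in% names(positives)) {
      as.character(positives$journal)
    } else {
      rep("", nrow(positives))
    },
    label_ctype = map_ctype(positives$cancer_type)
  ) |>
    mutate(label_cancer = .data$label_ctype != "none",
           label_clinical = TRUE)
  pool_text <- annotated_text(negative_pool$title, negative_pool$abstract)
  eligible <- negative_pool[!contains_any_term(pool_text, cancer_terms), , drop = FALSE]
  if (nrow(eligible) < n_negatives) {
    abort(paste0("negative pool too small after cancer-term filtering: ",
                 nrow(eligible), " available, ", n_negatives, " requested"))
  }
  neg <- withr::with_seed(seed, eligible[sample.int(nrow(eligible), n_negatives), ]) |>
    mutate(label_cancer = FALSE, label_clinical = FALSE, label_ctype = "none")
  out <- bind_rows(
    pos |> mutate(mentions = list(empty_mentions()), ctype_label = NA_character_),
    neg
  ) |>
    mutate(label_ctype = factor(.data$label_ctype, levels = CTYPE_LEVELS))
  validate_documents(out)
  out
}

task_labels <- function(docs, task) {
  switch(task,
    cancer = factor(ifelse(docs$label_cancer, "cancer", "non_cancer"),
                    levels = c("non_cancer", "cancer")),
    clinical = factor(ifelse(docs$label_clinical, "clinical", "non_clinical"),
                      levels = c("non_clinical", "clinical")),
    ctype = droplevels(factor(docs$label_ctype,
                              levels = setdiff(CTYPE_LEVELS, "none"))),
    abort(paste0("unknown task '", task, "'"))
  )
}

positive_level <- c(cancer = "cancer", clinical = "clinical")

#' Stratified train/test split
#'
#' Seeded uniform split stratified jointly over all task labels present
#' (`label_cancer`, `label_clinical`, `label_ctype`), so each task's class
#' balance is preserved. Per stratum the train size is the rounded exact
#' fraction, hence within one document of it.
#'
#' @param corpus Labeled document tibble.
#' @param train_fraction Fraction of documents in the training set, in (0, 1).
#' @param seed Integer seed.
#' @return A list with `train` and `test` tibbles (disjoint).
#' @export
split_train_test <- function(corpus, train_fraction = 0.85, seed = 1L) {
  if (nrow(corpus) == 0) abort("corpus is empty")
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  label_cols <- intersect(c("label_cancer", "label_clinical", "label_ctype"), names(corpus))
  strata <- if (length(label_cols) == 0) rep("all", nrow(corpus)) else
    do.call(paste, c(lapply(label_cols, function(cl) as.character(corpus[[cl]])), sep = "|"))
  sizes <- table(strata)
  if (any(sizes < 2)) {
    abort(paste0("stratum '", names(sizes)[which(sizes < 2)[1]], "' has fewer than 2 documents"))
  }
  in_train <- withr::with_seed(seed, {
    flag <- logical(nrow(corpus))
    for (s in names(sizes)) {
      idx <- which(strata == s)
      n_tr <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
      flag[sample(idx, n_tr)] <- TRUE
    }
    flag
  })
  list(train = corpus[in_train, ], test = corpus[!in_train, ])
}

# ---- learners ---------------------------------------------------------------

safe_colnames <- function(x) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

fit_binary_svm <- function(x, y, cost) {
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  pos <- levels(y)[2]
  first <- strsplit(colnames(attr(
    predict(fit, x[1, , drop = FALSE], decision.values = TRUE),
    "decision.values")), "/")[[1]][1]
  list(fit = fit, flip = !identical(first, pos))
}

predict_binary_svm <- function(model, x) {
  dv <- attr(predict(model$fit, x, decision.values = TRUE), "decision.values")[, 1]
  if (model$flip) -dv else unname(dv)
}

fit_learner <- function(learner, x, y, params, seed) {
  x <- safe_colnames(as.matrix(x))
  classes <- levels(y)
  if (learner == "linear_svm") {
    if (length(classes) == 2) {
      list(kind = "svm_binary", model = fit_binary_svm(x, y, params$cost),
           classes = classes)
    } else {
      # one-vs-rest for the multi-class cancer-type task
      ovr <- lapply(classes, function(cl) {
        yy <- factor(ifelse(y == cl, "pos", "rest"), levels = c("rest", "pos"))
        fit_binary_svm(x, yy, params$cost)
      })
      names(ovr) <- classes
      list(kind = "svm_ovr", model = ovr, classes = classes)
    }
  } else if (learner == "random_forest") {
    fit <- ranger::ranger(
      x = x, y = y, probability = TRUE, importance = "impurity",
      num.trees = params$num_trees,
      max.depth = if (params$max_depth == 0) NULL else params$max_depth,
      min.node.size = params$min_node_size,
      seed = seed, num.threads = 1
    )
    list(kind = "rf", model = fit, classes = classes)
  } else {
    abort(paste0("unknown learner '", learner, "'"))
  }
}

# score matrix (documents x classes); for binary learners the positive-class
# column is the signed decision value / vote fraction
learner_scores <- function(fit, x) {
  x <- safe_colnames(as.matrix(x))
  cls <- fit$classes
  if (fit$kind == "svm_binary") {
    dv <- predict_binary_svm(fit$model, x)
    cbind(matrix(-dv, ncol = 1, dimnames = list(NULL, cls[1])),
          matrix(dv, ncol = 1, dimnames = list(NULL, cls[2])))
  } else if (fit$kind == "svm_ovr") {
    do.call(cbind, lapply(cls, function(cl) {
      matrix(predict_binary_svm(fit$model[[cl]], x), ncol = 1,
             dimnames = list(NULL, cl))
    }))
  } else if (fit$kind == "linear_weights") {
    sc <- as.matrix(x %*% fit$model$W)
    sc <- sweep(sc, 2, fit$model$b, "+")
    if (length(cls) == 2 && ncol(sc) == 1) {
      sc <- cbind(-sc[, 1], sc[, 1])
      colnames(sc) <- cls
    }
    sc[, cls, drop = FALSE]
  } else {
    pr <- predict(fit$model, data = x, num.threads = 1)$predictions
    pr[, cls, drop = FALSE]
  }
}

learner_labels <- function(fit, x) {
  sc <- learner_scores(fit, x)
  factor(fit$classes[max.col(sc, ties.method = "first")], levels = fit$classes)
}

sample_params <- function(learner, budget) {
  if (learner == "linear_svm") {
    tibble(cost = 10^runif(budget, -3, 3))
  } else {
    tibble(num_trees = sample(seq(100L, 500L, by = 50L), budget, replace = TRUE),
           max_depth = sample(c(0L, 10L, 20L), budget, replace = TRUE),
           min_node_size = sample(c(1L, 5L, 10L), budget, replace = TRUE))
  }
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

macro_f1 <- function(truth, pred) {
  classes <- levels(truth)
  f1s <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    unname(prf(tp, fp, fn)["f1"])
  }, numeric(1))
  mean(f1s[!is.na(f1s)])
}

#' Train one task model with seeded randomized hyper-parameter search
#'
#' Fits the tf-idf + chi-squared feature model on the training documents for
#' the given task, draws `search_budget` hyper-parameter configurations at
#' random (regularization strength log-uniform over \[1e-3, 1e3\] for the
#' linear SVM; tree count, depth and node size for the random forest),
#' evaluates each by mean macro F1 over 5 stratified cross-validation folds,
#' refits the best configuration on the full training set and records the
#' training-corpus raw-score range as a normalization fallback.
#'
#' @param task `"cancer"`, `"clinical"` or `"ctype"` (the type task trains
#'   only on cancer documents with a known type and is multi-class,
#'   one-vs-rest for the linear learner).
#' @param learner `"linear_svm"` or `"random_forest"`.
#' @param train Labeled training tibble from [split_train_test()].
#' @param cfg A [feature_config()].
#' @param search_budget Number of random configurations to try.
#' @param seed Integer seed controlling folds, parameter draws and forests.
#' @return A `clinrank_task_model` object.
#' @export
train_task_model <- function(task, learner = c("linear_svm", "random_forest"),
                             train, cfg = feature_config(), search_budget = 10,
                             seed = 1L) {
  learner <- match.arg(learner)
  if (task == "ctype") train <- train[train$label_ctype != "none", , drop = FALSE]
  y <- task_labels(train, task)
  counts <- table(y)
  if (any(counts < 5)) {
    abort(paste0("class '", names(counts)[which(counts < 5)[1]],
                 "' has fewer than 5 training documents (5-fold CV needs 5)"))
  }
  features <- fit_features(train, y, cfg)
  x <- transform_features(features, train)
  search <- withr::with_seed(seed, {
    params <- sample_params(learner, search_budget)
    fold <- stratified_folds(y, 5L)
    cv <- vapply(seq_len(search_budget), function(b) {
      pp <- as.list(params[b, ])
      f1 <- vapply(1:5, function(kf) {
        tr <- fold != kf
        fit <- fit_learner(learner, x[tr, , drop = FALSE], droplevels(y[tr]), pp,
                           seed = seed + kf)
        pred <- learner_labels(fit, x[!tr, , drop = FALSE])
        macro_f1(droplevels(y[!tr]), factor(pred, levels = levels(droplevels(y[!tr]))))
      }, numeric(1))
      mean(f1)
    }, numeric(1))
    list(params = params, cv = cv)
  })
  best <- which.max(search$cv)
  fit <- fit_learner(learner, x, y, as.list(search$params[best, ]), seed = seed)
  raw <- learner_scores(fit, x)
  pos <- if (task %in% names(positive_level)) positive_level[[task]] else NULL
  rng <- if (is.null(pos)) range(raw) else range(raw[, pos])
  structure(list(
    task = task, learner = learner, features = features, fit = fit,
    classes = levels(y), best_params = as.list(search$params[best, ]),
    cv_results = mutate(search$params, cv_macro_f1 = search$cv),
    cv_f1 = search$cv[best], score_range = rng, n_train = nrow(train),
    seed = seed
  ), class = "clinrank_task_model")
}

#' @export
print.clinrank_task_model <- function(x, ...) {
  cat("<clinrank_task_model> task:", x$task, " learner:", x$learner, "\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  features:", length(x$features$vocab), " cv macro-F1:",
      sprintf("%.3f", x$cv_f1), "\n")
  invisible(x)
}

# raw positive-class score (binary) or score matrix (multi-class)
model_raw_scores <- function(model, docs) {
  x <- transform_features(model$features, docs)
  sc <- learner_scores(model$fit, x)
  if (model$task %in% names(positive_level)) {
    unname(sc[, positive_level[[model$task]]])
  } else {
    sc
  }
}

#' Predicted labels of a task model
#'
#' @param model A `clinrank_task_model`.
#' @param docs Document tibble.
#' @return Factor of predicted classes.
#' @export
predict_labels <- function(model, docs) {
  x <- transform_features(model$features, docs)
  learner_labels(model$fit, x)
}

#' Apply the three task models to documents
#'
#' @param models Named list with elements `cancer`, `clinical` and optionally
#'   `ctype`.
#' @param docs Document tibble.
#' @return Tibble with `doc_id`, raw `cancer_raw` / `clinical_raw` scores,
#'   the predicted `ctype_label` and the `ctype_margin` (top-1 minus top-2
#'   class score; `NA` without a type model).
#' @export
predict_scores <- function(models, docs) {
  stopifnot(all(c("cancer", "clinical") %in% names(models)))
  out <- tibble(
    doc_id = docs$doc_id,
    cancer_raw = model_raw_scores(models$cancer, docs),
    clinical_raw = model_raw_scores(models$clinical, docs)
  )
  if (!is.null(models$ctype)) {
    sc <- model_raw_scores(models$ctype, docs)
    ord <- t(apply(sc, 1, sort, decreasing = TRUE))
    out$ctype_label <- colnames(sc)[max.col(sc, ties.method = "first")]
    out$ctype_margin <- if (ncol(sc) > 1) ord[, 1] - ord[, 2] else rep(Inf, nrow(sc))
  } else {
    out$ctype_label <- NA_character_
    out$ctype_margin <- NA_real_
  }
  out
}

#' Evaluate a task model on a labeled test set
#'
#' Standard precision, recall and F1 per class plus their unweighted macro
#' average. A class absent from the test set has undefined precision/recall,
#' reported as `NA` and excluded from the macro mean.
#'
#' @param model A `clinrank_task_model`.
#' @param test Labeled document tibble.
#' @return A tibble with one row per class and a final `macro` row, of class
#'   `clinrank_classifier_eval`.
#' @export
evaluate_classifier <- function(model, test) {
  if (model$task == "ctype") test <- test[test$label_ctype != "none", , drop = FALSE]
  truth <- factor(task_labels(test, model$task), levels = model$classes)
  pred <- predict_labels(model, test)
  rows <- map(model$classes, function(cl) {
    if (!any(truth == cl)) {
      return(tibble(class = cl, precision = NA_real_, recall = NA_real_,
                    f1 = NA_real_, support = 0L))
    }
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    v <- prf(tp, fp, fn)
    tibble(class = cl, precision = unname(v["precision"]),
           recall = unname(v["recall"]), f1 = unname(v["f1"]),
           support = tp + fn)
  })
  per_class <- bind_rows(rows)
  present <- !is.na(per_class$f1)
  macro <- tibble(class = "macro",
                  precision = mean(per_class$precision[present]),
                  recall = mean(per_class$recall[present]),
                  f1 = mean(per_class$f1[present]),
                  support = sum(per_class$support))
  out <- bind_rows(per_class, macro)
  structure(out, task = model$task, learner = model$learner,
            class = c("clinrank_classifier_eval", class(out)))
}

#' Train the full model set for corpus scoring
#'
#' Convenience wrapper fitting the cancer and clinical models (and the type
#' model when the training data carries more than one cancer type).
#'
#' @inheritParams train_task_model
#' @param with_ctype Fit the cancer-type model as well.
#' @return Named list of `clinrank_task_model`s.
#' @export
train_models <- function(train, learner = "linear_svm", cfg = feature_config(),
                         search_budget = 10, seed = 1L, with_ctype = TRUE) {
  models <- list(
    cancer = train_task_model("cancer", learner, train, cfg, search_budget, seed),
    clinical = train_task_model("clinical", learner, train, cfg, search_budget, seed + 1L)
  )
  if (with_ctype) {
    ct <- droplevels(task_labels(train, "ctype"))
    if (nlevels(ct) >= 2 && all(table(ct) >= 5)) {
      models$ctype <- train_task_model("ctype", learner, train, cfg, search_budget,
                                       seed + 2L)
    }
  }
  models
}
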