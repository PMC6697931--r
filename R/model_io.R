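# Text-format persistence for fitted task models. Linear SVMs reduce to a
# weight vector per class in tf-idf feature space, which round-trips exactly
# through TSV; random forests have no compact text form and must be refit
# from the corpus (the training procedure is fully seeded).

BUNDLE_FORMAT <- "clinrank-model/1"

#' Write a fitted linear task model to a directory
#'
#' Persists the model as plain text: `config.json` (task, classes, chosen
#' hyper-parameters, score range, format tag), `vocabulary.tsv` (term, idf,
#' chi-squared score) and `weights.tsv` (class, bias, then one weight per
#' term). Only `linear_svm` models are supported; forests are not
#' serializable to a faithful text form.
#'
#' @param model A `clinrank_task_model` with learner `linear_svm`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model_bundle <- function(model, dir) {
  if (model$learner != "linear_svm") {
    abort("only linear_svm models have a text serialization; refit forests from the corpus")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vocab <- model$features$vocab
  wb <- if (model$fit$kind == "svm_binary") {
    one <- svm_weights(model$fit$model, vocab)
    list(W = matrix(one$w, ncol = 1, dimnames = list(vocab, model$classes[2])),
         b = setNames(one$b, model$classes[2]))
  } else {
    cols <- lapply(model$classes, function(cl) svm_weights(model$fit$model[[cl]], vocab))
    list(W = do.call(cbind, lapply(cols, function(x) unname(x$w))) |>
           `dimnames<-`(list(vocab, model$classes)),
         b = setNames(vapply(cols, function(x) x$b, 0), model$classes))
  }
  jsonlite::write_json(
    list(format = BUNDLE_FORMAT, task = model$task, learner = model$learner,
         classes = model$classes, best_params = model$best_params,
         cv_f1 = model$cv_f1, score_range = model$score_range,
         n_train = model$n_train, seed = model$seed,
         bias = as.list(wb$b),
         cfg = model$features$cfg[c("ngram_range", "max_features_chi2",
                                    "min_doc_freq", "lowercase", "token_pattern")],
         n_train_features = model$features$n_train),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(
    tibble(term = vocab, idf = model$features$idf, chi2 = model$features$chi2),
    file.path(dir, "vocabulary.tsv"))
  readr::write_tsv(
    as_tibble(wb$W) |> mutate(term = vocab) |> select("term", dplyr::everything()),
    file.path(dir, "weights.tsv"))
  invisible(dir)
}

#' Read a linear task model bundle
#'
#' @param dir Directory written by [write_model_bundle()].
#' @return A `clinrank_task_model` whose predictions equal the original
#'   model's (scores computed as `x %*% W + b`).
#' @export
read_model_bundle <- function(dir) {
  cfg_file <- file.path(dir, "config.json")
  if (!file.exists(cfg_file)) abort(paste0("no model bundle at '", dir, "'"))
  meta <- jsonlite::read_json(cfg_file, simplifyVector = TRUE)
  if (!identical(meta$format, BUNDLE_FORMAT)) {
    abort(paste0("unsupported bundle format '", meta$format, "'"))
  }
  voc <- readr::read_tsv(file.path(dir, "vocabulary.tsv"), col_types = "cdd",
                         progress = FALSE)
  wt <- readr::read_tsv(file.path(dir, "weights.tsv"),
                        col_types = readr::cols("term" = readr::col_character(),
                                                .default = readr::col_double()),
                        progress = FALSE)
  W <- as.matrix(wt[, setdiff(names(wt), "term"), drop = FALSE])
  rownames(W) <- wt$term
  features <- structure(
    list(cfg = do.call(feature_config, meta$cfg), vocab = voc$term,
         idf = voc$idf, chi2 = voc$chi2, n_train = meta$n_train_features),
    class = "clinrank_features")
  structure(list(
    task = meta$task, learner = meta$learner, features = features,
    fit = list(kind = "linear_weights",
               model = list(W = W, b = unlist(meta$bias)),
               classes = meta$classes),
    classes = meta$classes, best_params = as.list(meta$best_params),
    cv_results = NULL, cv_f1 = meta$cv_f1,
    score_range = as.numeric(meta$score_range), n_train = meta$n_train,
    seed = meta$seed
  ), class = "clinrank_task_model")
}
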