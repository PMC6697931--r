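#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

svm_weights <- function(bin, vocab) {
  w <- as.numeric(crossprod(bin$fit$coefs, bin$fit$SV))
  b <- -bin$fit$rho
  if (bin$flip) { w <- -w; b <- -b }
  list(w = setNames(w, vocab), b = b)
}

#' Tidy a fitted task model
#'
#' For the linear SVM, one row per (class, term) with the hyperplane weight
#' on the tf-idf feature (for binary tasks, weights of the positive class);
#' for the random forest, one row per term with its impurity importance.
#'
#' @param x A `clinrank_task_model`.
#' @param ... Unused.
#' @return A tibble of model terms.
#' @exportS3Method generics::tidy
tidy.clinrank_task_model <- function(x, ...) {
  vocab <- x$features$vocab
  if (x$fit$kind == "svm_binary") {
    wb <- svm_weights(x$fit$model, vocab)
    tibble(class = x$classes[2], term = vocab, weight = unname(wb$w)) |>
      arrange(desc(abs(.data$weight)))
  } else if (x$fit$kind == "svm_ovr") {
    bind_rows(lapply(x$classes, function(cl) {
      wb <- svm_weights(x$fit$model[[cl]], vocab)
      tibble(class = cl, term = vocab, weight = unname(wb$w))
    })) |>
      arrange(.data$class, desc(abs(.data$weight)))
  } else if (x$fit$kind == "linear_weights") {
    bind_rows(lapply(colnames(x$fit$model$W), function(cl) {
      tibble(class = cl, term = vocab, weight = x$fit$model$W[, cl])
    })) |>
      arrange(.data$class, desc(abs(.data$weight)))
  } else {
    imp <- x$fit$model$variable.importance
    tibble(term = vocab, importance = unname(imp)) |>
      arrange(desc(.data$importance))
  }
}

#' One-row summary of a fitted task model
#'
#' @param x A `clinrank_task_model`.
#' @param ... Unused.
#' @return Tibble with the task, learner, training size, feature count,
#'   cross-validated macro F1 and the chosen hyper-parameters.
#' @exportS3Method generics::glance
glance.clinrank_task_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble(task = x$task, learner = x$learner, n_train = x$n_train,
           n_features = length(x$features$vocab), cv_macro_f1 = x$cv_f1),
    as_tibble(x$best_params)
  )
}
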