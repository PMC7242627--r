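#' Train the linear-SVM baseline
#'
#' Soft-margin linear SVM with regularization constant 1 (the default of
#' the common machine-learning toolkits), fitted on exactly the rows given
#' -- held-out subjects never enter by construction. No feature scaling is
#' done here; volumes are expected to be z-scored by [apply_scaler()] and
#' masked/flattened by [flatten_volumes()] beforehand.
#'
#' @param features A `feature_matrix` (or plain numeric matrix with subject
#'   ids as rownames).
#' @param labels Integer 0/1 labels aligned with the rows (1 = patient).
#' @param cost Soft-margin constant; default 1.
#' @return An object of class `boldnine_svm`.
#' @export
train_svm <- function(features, labels, cost = 1) {
  x <- if (inherits(features, "feature_matrix")) features$values else features
  if (nrow(x) != length(labels)) abort("row/label length mismatch")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) abort("training set has a single class")
  if (min(table(labels)) < 2L) abort("need at least 2 subjects per class")
  y <- factor(labels, levels = c(0L, 1L))
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  # orientation of the decision value depends on which class e1071 saw
  # first; normalize so positive margins always mean patient (= 1)
  dv0 <- attr(predict(fit, x[1, , drop = FALSE], decision.values = TRUE),
              "decision.values")
  flip <- identical(colnames(dv0), "0/1")
  structure(list(kind = "svm", fit = fit, flip = flip, n_features = ncol(x)),
            class = "boldnine_svm")
}

#' Predict with a trained linear SVM
#'
#' @param model A `boldnine_svm`.
#' @param features A `feature_matrix` or numeric matrix with the same
#'   feature width the model was trained on.
#' @param subject_ids Optional ids; default taken from rownames.
#' @return A `prediction_set` tibble with signed margins as `score`
#'   (positive = patient) and `label = margin >= 0`.
#' @export
predict_svm <- function(model, features, subject_ids = NULL) {
  x <- if (inherits(features, "feature_matrix")) features$values else features
  if (ncol(x) != model$n_features) {
    abort(sprintf("feature width %d does not match the %d the model was trained on",
                  ncol(x), model$n_features))
  }
  pr <- predict(model$fit, x, decision.values = TRUE)
  margin <- as.numeric(attr(pr, "decision.values"))
  if (model$flip) margin <- -margin
  ids <- subject_ids %||% rownames(x) %||% as.character(seq_len(nrow(x)))
  prediction_set(ids, margin, as.integer(margin >= 0), kind = "svm")
}

#' @export
print.boldnine_svm <- function(x, ...) {
  cat(sprintf("<boldnine_svm> linear, cost 1 | %d features | %d support vectors\n",
              x$n_features, nrow(x$fit$SV)))
  invisible(x)
}
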