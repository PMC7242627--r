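#' Balanced accuracy
#'
#' Mean of sensitivity and specificity with the patient class (1) as
#' positive; insensitive to class imbalance.
#'
#' @param y_true,y_pred Integer 0/1 vectors of equal length.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' balanced_accuracy(c(1, 1, 1, 0), c(1, 0, 0, 0)) # (1/3 + 1)/2
balanced_accuracy <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(unique(y_true)) < 2L) {
    abort("balanced accuracy needs both classes present in y_true")
  }
  sens <- mean(y_pred[y_true == 1] == 1)
  spec <- mean(y_pred[y_true == 0] == 0)
  (sens + spec) / 2
}

#' F1 score
#'
#' Harmonic mean of precision and recall for the patient class. By
#' convention 0 when there are no predicted positives while true positives
#' exist, and 0 when there are neither.
#'
#' @inheritParams balanced_accuracy
#' @return A number in \[0, 1\].
#' @export
f1_score <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Majority vote over prediction sets
#'
#' Combines an odd number of aligned binary prediction sets into one: each
#' subject gets the label held by more than half the voters. An even voter
#' count is rejected (ties would be ambiguous); with an odd count no tie
#' can occur. The `score` of the result is the fraction of voters
#' predicting patient.
#'
#' @param preds List of `prediction_set` tibbles over identical subjects in
#'   identical order.
#' @return A `prediction_set` of kind `"ensemble"`.
#' @export
majority_vote <- function(preds) {
  if (length(preds) %% 2L == 0L) {
    abort("majority vote needs an odd number of voters (ties are ambiguous)")
  }
  ids <- preds[[1]]$subject_id
  for (p in preds) {
    if (!identical(p$subject_id, ids)) abort("prediction sets are misaligned")
  }
  votes <- vapply(preds, function(p) p$label, integer(length(ids)))
  if (length(ids) == 1L) votes <- matrix(votes, nrow = 1L)
  frac <- rowMeans(votes)
  prediction_set(ids, frac, as.integer(frac > 0.5), kind = "ensemble")
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation; the tie correction is essential here
#' because binary prediction vectors are massively tied. Returns NA when
#' either vector is constant (the coefficient is undefined).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Tau-b in \[-1, 1\], or NA.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  cor(x, y, method = "kendall")
}

#' Kendall agreement between model predictions
#'
#' Tau-b between the binary test-set predictions of every pair of models,
#' computed per fold on the common test set and averaged over folds. Folds
#' where either model predicts a single class are undefined for that pair
#' and are dropped from the average with a warning. Used to ask whether the
#' per-measure models carry independent information or all pick up the same
#' pattern.
#'
#' @param preds Tibble with columns `model`, `fold_id` and list-column
#'   `pred` (each a `prediction_set` over the same test subjects), or a
#'   named list of per-model lists of prediction sets.
#' @return A symmetric matrix of class `agreement_matrix` with unit
#'   diagonal, averaged over folds.
#' @export
kendall_agreement <- function(preds) {
  if (!is.data.frame(preds)) {
    preds <- dplyr::bind_rows(lapply(names(preds), function(m) {
      tibble(model = m, fold_id = seq_along(preds[[m]]),
             pred = preds[[m]])
    }))
  }
  models <- unique(preds$model)
  folds <- unique(preds$fold_id)
  acc <- matrix(0, length(models), length(models),
                dimnames = list(models, models))
  cnt <- matrix(0L, length(models), length(models))
  dropped <- 0L
  for (f in folds) {
    pf <- preds[preds$fold_id == f, ]
    labs <- lapply(models, function(m) {
      p <- pf$pred[pf$model == m][[1]]
      p$label[order(p$subject_id)]
    })
    for (i in seq_along(models)) for (j in seq_along(models)) {
      if (i == j) { acc[i, j] <- acc[i, j] + 1; cnt[i, j] <- cnt[i, j] + 1L; next }
      tau <- kendall_tau(labs[[i]], labs[[j]])
      if (is.na(tau)) { dropped <- dropped + (i < j) } else {
        acc[i, j] <- acc[i, j] + tau; cnt[i, j] <- cnt[i, j] + 1L
      }
    }
  }
  if (dropped > 0L) {
    warn(sprintf("%d model pair-fold(s) had constant predictions; excluded from the average",
                 dropped))
  }
  out <- acc / pmax(cnt, 1L)
  out[cnt == 0L] <- NA_real_
  structure(out, class = c("agreement_matrix", "matrix", "array"))
}

#' @export
print.agreement_matrix <- function(x, ...) {
  cat("<agreement_matrix> Kendall tau-b between model predictions, averaged over folds\n")
  print(round(unclass(x), 3))
  invisible(x)
}
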