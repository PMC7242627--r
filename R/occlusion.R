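#' Zero out one atlas region of an input volume
#'
#' Sets every voxel belonging to the region to 0 (across all channels for
#' multi-channel inputs), leaving everything else untouched. Occluding two
#' disjoint regions in sequence is order-independent.
#'
#' @param x A [summary_volume()], a 3D array, a (channels, x, y, z) array,
#'   or a (channels, x, y, z, subjects) array.
#' @param atlas A [label_atlas()] on the same spatial grid.
#' @param roi_id A region id present in `atlas$roi_ids` (background 0 is
#'   not occludable).
#' @return The input with the region zeroed, same type.
#' @export
occlude <- function(x, atlas, roi_id) {
  if (!roi_id %in% atlas$roi_ids) {
    abort(sprintf("roi_id %s is not a region of the atlas", roi_id))
  }
  sel <- atlas$labels == roi_id
  grid <- dim(atlas$labels)
  if (inherits(x, "summary_volume")) {
    if (!identical(dim(x$data), grid)) abort("atlas grid mismatch")
    x$data[sel] <- 0
    return(x)
  }
  d <- dim(x)
  if (length(d) == 3L) {
    if (!identical(d, grid)) abort("atlas grid mismatch")
    x[sel] <- 0
  } else if (length(d) %in% c(4L, 5L)) {
    if (!identical(d[2:4], grid)) abort("atlas grid mismatch")
    reps <- if (length(d) == 5L) d[5] else 1L
    m <- matrix(x, d[1], prod(grid) * reps)
    m[, rep(as.vector(sel), reps)] <- 0
    x <- array(m, d)
  } else {
    abort("cannot occlude an object of this shape")
  }
  x
}

# occlusion for SVM feature matrices: zero the columns whose source voxel
# lies in the region
occlude_features <- function(fm, atlas, roi_id) {
  if (!roi_id %in% atlas$roi_ids) {
    abort(sprintf("roi_id %s is not a region of the atlas", roi_id))
  }
  roi_vox <- which(as.vector(atlas$labels == roi_id))
  cols <- fm$voxel_idx %in% roi_vox
  fm$values[, cols] <- 0
  fm
}

rescore_fold <- function(fit, classifier, atlas, roi_id) {
  if (!is.null(fit$components)) {
    preds <- lapply(fit$components, function(cp) {
      rescore_fold(cp, classifier, atlas, roi_id)
    })
    return(majority_vote(preds))
  }
  if (classifier == "cnn") {
    x <- occlude(fit$test_input, atlas, roi_id)
    predict_cnn(fit$model, x, subject_ids = fit$test_ids)
  } else {
    fm <- occlude_features(fit$test_input, atlas, roi_id)
    predict_svm(fit$model, fm, subject_ids = fit$test_ids)
  }
}

#' Occlusion attribution of classifier performance to atlas regions
#'
#' For each atlas region, zeroes the region in every fold's (already
#' normalized) test inputs, re-scores the stored fold models without any
#' retraining, and averages balanced accuracy and F1 across folds. The drop
#' relative to the un-occluded baseline suggests how much the region's
#' voxels contributed; regions are ranked by descending drop. The analysis
#' is descriptive -- no statistical test is attached to the drops.
#'
#' @param result An `eval_result` produced with `keep_fits = TRUE`.
#' @param atlas A [label_atlas()] on the data grid.
#' @param top_n Number of top regions to report in the ranking; default 10.
#' @return An `occlusion_report`: `baseline` (fold-mean and sd of the
#'   un-occluded metrics, bit-identical to the evaluation's numbers),
#'   `per_roi` tibble, and `ranking` of region ids by descending balanced
#'   accuracy drop.
#' @export
run_occlusion <- function(result, atlas, top_n = 10L) {
  stopifnot(inherits(result, "eval_result"))
  if (is.null(result$folds[[1]]$fit)) {
    abort("result was produced without keep_fits = TRUE; refit with it")
  }
  fit0 <- result$folds[[1]]$fit
  if (!is.null(fit0$components)) fit0 <- fit0$components[[1]]
  grid <- if (result$classifier == "cnn") dim(fit0$test_input)[2:4] else
    dim(fit0$masks[[1]]$mask)
  if (!identical(as.integer(dim(atlas$labels)), as.integer(grid))) {
    abort(sprintf("atlas grid %s mismatches the data grid %s",
                  paste(dim(atlas$labels), collapse = "x"),
                  paste(grid, collapse = "x")))
  }
  base <- result$per_fold
  rows <- lapply(atlas$roi_ids, function(roi) {
    ba <- f1v <- numeric(length(result$folds))
    for (i in seq_along(result$folds)) {
      f <- result$folds[[i]]
      pred <- rescore_fold(f$fit, result$classifier, atlas, roi)
      ba[i] <- balanced_accuracy(f$y_test, pred$label)
      f1v[i] <- f1_score(f$y_test, pred$label)
    }
    tibble(roi_id = roi,
           roi_name = unname(atlas$roi_names[as.character(roi)]),
           bal_acc_mean = mean(ba), bal_acc_sd = sd(ba),
           f1_mean = mean(f1v), f1_sd = sd(f1v))
  })
  per_roi <- dplyr::bind_rows(rows)
  per_roi$drop <- mean(base$balanced_accuracy) - per_roi$bal_acc_mean
  per_roi$f1_drop <- mean(base$f1) - per_roi$f1_mean
  per_roi <- dplyr::arrange(per_roi, dplyr::desc(.data$drop))
  structure(list(
    baseline = tibble(bal_acc_mean = mean(base$balanced_accuracy),
                      bal_acc_sd = sd(base$balanced_accuracy),
                      f1_mean = mean(base$f1), f1_sd = sd(base$f1)),
    per_roi = per_roi,
    ranking = head(per_roi$roi_id, top_n),
    strategy = result$strategy, classifier = result$classifier),
    class = "occlusion_report")
}

#' @export
print.occlusion_report <- function(x, ...) {
  cat(sprintf("<occlusion_report> %s | %s\n", x$strategy, x$classifier))
  cat(sprintf("  all brain: balanced accuracy %.3f (sd %.3f), F1 %.3f (sd %.3f)\n",
              x$baseline$bal_acc_mean, x$baseline$bal_acc_sd,
              x$baseline$f1_mean, x$baseline$f1_sd))
  print(head(x$per_roi, length(x$ranking)))
  invisible(x)
}
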