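#' Compute summary measures for a set of runs
#'
#' Maps [compute_all()] over a cohort and returns the tidy per-(subject,
#' measure) table that the evaluation functions consume.
#'
#' @param runs List of [bold_run()] objects.
#' @param params A [measure_params()].
#' @param measures Measures to compute; default all nine.
#' @return A tibble of class `measure_set` with columns `subject_id`,
#'   `measure` and list-column `volume`.
#' @export
summarize_runs <- function(runs, params = measure_params(),
                           measures = measure_names()) {
  rows <- lapply(runs, function(r) {
    maps <- compute_all(r, params, measures)
    tibble(subject_id = r$subject_id, measure = names(maps),
           volume = unname(maps))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("measure_set", class(out))
  out
}

# extract one measure's volumes for given subjects, in the given order
vols_for <- function(measure_set, measure, ids) {
  sub <- measure_set[measure_set$measure == measure, ]
  pos <- match(ids, sub$subject_id)
  if (anyNA(pos)) {
    abort(sprintf("measure '%s' missing for subject(s): %s", measure,
                  paste(ids[is.na(pos)], collapse = ", ")))
  }
  sub$volume[pos]
}

labels_for <- function(manifest, ids) {
  manifest$label[match(ids, manifest$subject_id)]
}

# assemble a (channels, x, y, z, subjects) input array from scaled volumes;
# vols_by_measure: named list measure -> list of volumes aligned on subjects
build_cnn_input <- function(vols_by_measure, measures) {
  n <- length(vols_by_measure[[measures[1]]])
  d <- dim(vols_by_measure[[measures[1]]][[1]]$data)
  x <- array(0, c(length(measures), d, n))
  for (ci in seq_along(measures)) {
    vl <- vols_by_measure[[measures[ci]]]
    for (i in seq_len(n)) x[ci, , , , i] <- vl[[i]]$data
  }
  x
}

# fit one single-measure (or multi-measure) classifier on one fold
fit_fold <- function(measure_set, manifest, fold, measures, classifier,
                     config, mask_fraction, fold_seed) {
  train_ids <- fold$train_ids[[1]]
  val_ids <- fold$val_ids[[1]]
  test_ids <- fold$test_ids[[1]]
  y_train <- labels_for(manifest, train_ids)
  y_val <- labels_for(manifest, val_ids)
  y_test <- labels_for(manifest, test_ids)
  if (classifier == "cnn") {
    scaled <- lapply(setNames(measures, measures), function(mm) {
      sc <- fit_scaler(vols_for(measure_set, mm, train_ids))
      list(train = lapply(vols_for(measure_set, mm, train_ids),
                          apply_scaler, scaler = sc),
           val = lapply(vols_for(measure_set, mm, val_ids),
                        apply_scaler, scaler = sc),
           test = lapply(vols_for(measure_set, mm, test_ids),
                         apply_scaler, scaler = sc),
           scaler = sc)
    })
    grid <- dim(scaled[[1]]$train[[1]]$data)
    x_train <- build_cnn_input(lapply(scaled, `[[`, "train"), measures)
    x_val <- build_cnn_input(lapply(scaled, `[[`, "val"), measures)
    x_test <- build_cnn_input(lapply(scaled, `[[`, "test"), measures)
    cfg <- config; cfg$seed <- fold_seed
    model <- build_cnn(cnn_spec(grid, in_channels = length(measures)),
                       seed = fold_seed)
    model <- train_cnn(model, x_train, y_train, x_val, y_val, cfg)
    pred <- predict_cnn(model, x_test, subject_ids = test_ids)
    list(pred = pred, model = model, test_input = x_test,
         test_ids = test_ids, y_test = y_test,
         scalers = lapply(scaled, `[[`, "scaler"))
  } else {
    per_meas <- lapply(setNames(measures, measures), function(mm) {
      train_vols <- vols_for(measure_set, mm, train_ids)
      gm <- build_group_mask(train_vols, mask_fraction)
      sc <- fit_scaler(train_vols)
      tr <- flatten_volumes(lapply(train_vols, apply_scaler, scaler = sc), gm)
      te <- flatten_volumes(lapply(vols_for(measure_set, mm, test_ids),
                                   apply_scaler, scaler = sc), gm)
      list(train = tr, test = te, mask = gm, scaler = sc)
    })
    if (length(measures) == 1L) {
      ftr <- per_meas[[1]]$train; fte <- per_meas[[1]]$test
    } else {
      ftr <- concat_measures(lapply(per_meas, `[[`, "train"))
      fte <- concat_measures(lapply(per_meas, `[[`, "test"))
    }
    model <- train_svm(ftr, y_train)
    pred <- predict_svm(model, fte, subject_ids = test_ids)
    list(pred = pred, model = model, test_input = fte,
         test_ids = test_ids, y_test = y_test,
         masks = lapply(per_meas, `[[`, "mask"),
         scalers = lapply(per_meas, `[[`, "scaler"))
  }
}

#' Run a classification strategy over cross-validation folds
#'
#' Executes one of the three strategies for one classifier over a set of
#' folds, refitting the feature scaler (and, for the SVM, the 90% group
#' mask) on each fold's training subjects only:
#' \describe{
#'   \item{`sm:<measure>`}{one classifier on a single summary measure;}
#'   \item{`mm_model`}{one classifier on all nine measures -- stacked as
#'     nine channels for the CNN, concatenated features for the SVM;}
#'   \item{`mm_ensemble`}{nine single-measure classifiers whose binary
#'     predictions are combined by majority vote.}
#' }
#' CNN models are selected at the best-validation-accuracy epoch; the SVM
#' is fitted once on the training subjects.
#'
#' @param measure_set A `measure_set` tibble from [summarize_runs()].
#' @param manifest Manifest tibble.
#' @param splits A `fold_splits` tibble.
#' @param strategy `"sm:<measure>"`, `"mm_ensemble"` or `"mm_model"`.
#' @param classifier `"cnn"` or `"svm"`.
#' @param config A [train_config()] (CNN only). Per-fold seeds derive from
#'   `config$seed + fold_id`.
#' @param mask_fraction Group-mask fraction for the SVM path; default 0.9.
#' @param keep_fits Keep fitted models and normalized test inputs on the
#'   result (needed by [run_occlusion()]).
#' @return An `eval_result`: per-fold balanced accuracy and F1 on the test
#'   set, stored predictions, and (for `mm_ensemble`) the component
#'   single-measure predictions.
#' @export
run_strategy <- function(measure_set, manifest, splits, strategy,
                         classifier = c("cnn", "svm"),
                         config = train_config(), mask_fraction = 0.9,
                         keep_fits = FALSE) {
  classifier <- match.arg(classifier)
  manifest <- validate_manifest(manifest)
  available <- unique(measure_set$measure)
  if (grepl("^sm:", strategy)) {
    meas <- sub("^sm:", "", strategy)
    check_measure(meas)
    if (!meas %in% available) {
      abort(sprintf("strategy '%s' needs measure '%s', which is absent",
                    strategy, meas))
    }
    mode <- "sm"; measures <- meas
  } else if (strategy %in% c("mm_ensemble", "mm_model")) {
    miss <- setdiff(measure_names(), available)
    if (length(miss)) {
      abort(paste0(strategy, " needs all nine measures; missing: ",
                   paste(miss, collapse = ", ")))
    }
    mode <- strategy; measures <- measure_names()
  } else {
    abort(sprintf("unknown strategy '%s'", strategy))
  }

  folds <- vector("list", nrow(splits))
  for (i in seq_len(nrow(splits))) {
    fold <- splits[i, ]
    fold_seed <- config$seed + splits$fold_id[i]
    if (mode == "mm_ensemble") {
      comps <- lapply(setNames(measures, measures), function(mm) {
        fit_fold(measure_set, manifest, fold, mm, classifier,
                 config, mask_fraction, fold_seed)
      })
      pred <- majority_vote(lapply(comps, `[[`, "pred"))
      fit <- list(pred = pred, components = comps,
                  test_ids = comps[[1]]$test_ids, y_test = comps[[1]]$y_test)
    } else {
      fit <- fit_fold(measure_set, manifest, fold, measures, classifier,
                      config, mask_fraction, fold_seed)
    }
    folds[[i]] <- list(
      fold_id = splits$fold_id[i],
      held_out_site = splits$held_out_site[i],
      pred = fit$pred,
      y_test = fit$y_test,
      balanced_accuracy = balanced_accuracy(fit$y_test, fit$pred$label),
      f1 = f1_score(fit$y_test, fit$pred$label),
      fit = if (keep_fits || mode == "mm_ensemble") fit else NULL)
  }
  per_fold <- dplyr::bind_rows(lapply(folds, function(f) {
    tibble(fold_id = f$fold_id, held_out_site = f$held_out_site,
           balanced_accuracy = f$balanced_accuracy, f1 = f$f1)
  }))
  structure(list(strategy = strategy, classifier = classifier,
                 scheme = splits$scheme[1], per_fold = per_fold,
                 mean_balanced_accuracy = mean(per_fold$balanced_accuracy),
                 mean_f1 = mean(per_fold$f1),
                 folds = folds),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s | %s | %s CV (%d folds)\n",
              x$strategy, x$classifier, x$scheme, nrow(x$per_fold)))
  cat(sprintf("  mean balanced accuracy %.3f | mean F1 %.3f\n",
              x$mean_balanced_accuracy, x$mean_f1))
  invisible(x)
}

#' Test-set predictions stored on an evaluation result
#'
#' @param result An `eval_result`.
#' @param component Optional measure name to extract one ensemble
#'   component's predictions instead of the combined ones.
#' @return A tibble with one row per fold: `fold_id` and list-column `pred`.
#' @export
fold_predictions <- function(result, component = NULL) {
  dplyr::bind_rows(lapply(result$folds, function(f) {
    p <- if (is.null(component)) f$pred else f$fit$components[[component]]$pred
    tibble(fold_id = f$fold_id, pred = list(p))
  }))
}

#' Permutation null band for a mean cross-validated metric
#'
#' Permutes the true test labels within each fold and recomputes the mean
#' metric, repeatedly, giving the chance distribution of the observed mean
#' under no association. Models are not refitted: the null is over the
#' alignment of fixed predictions with labels.
#'
#' @param result An `eval_result`.
#' @param n_perm Number of permutations; default 100.
#' @param metric `"balanced_accuracy"` or `"f1"`.
#' @param seed RNG seed.
#' @return Numeric vector of `n_perm` null mean metrics.
#' @export
permutation_null <- function(result, n_perm = 100L,
                             metric = c("balanced_accuracy", "f1"),
                             seed = 1L) {
  metric <- match.arg(metric)
  fn <- if (metric == "balanced_accuracy") balanced_accuracy else f1_score
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  vapply(seq_len(n_perm), function(i) {
    mean(vapply(result$folds, function(f) {
      fn(sample(f$y_test), f$pred$label)
    }, 0))
  }, 0)
}
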