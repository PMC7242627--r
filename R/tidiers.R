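#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_tile geom_hline labs scale_fill_gradient2 theme_minimal
#'   facet_wrap coord_flip geom_errorbar
#' @export
ggplot2::autoplot

#' @describeIn run_strategy tidy(): one row per fold with both metrics.
#' @param x,object An `eval_result`.
#' @param ... Unused.
#' @method tidy eval_result
#' @export
tidy.eval_result <- function(x, ...) {
  dplyr::mutate(x$per_fold, strategy = x$strategy, classifier = x$classifier,
                scheme = x$scheme, .before = 1)
}

#' @describeIn run_strategy glance(): one-row fold-mean summary.
#' @method glance eval_result
#' @export
glance.eval_result <- function(x, ...) {
  tibble(strategy = x$strategy, classifier = x$classifier,
         scheme = x$scheme, n_folds = nrow(x$per_fold),
         balanced_accuracy = x$mean_balanced_accuracy,
         f1 = x$mean_f1,
         balanced_accuracy_sd = sd(x$per_fold$balanced_accuracy),
         f1_sd = sd(x$per_fold$f1))
}

#' @describeIn run_strategy autoplot(): per-fold metrics with fold means.
#' @method autoplot eval_result
#' @export
autoplot.eval_result <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object),
                            c("balanced_accuracy", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot(df, aes(x = factor(.data$fold_id), y = .data$value)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    facet_wrap(~metric) +
    labs(x = "fold", y = NULL,
         title = sprintf("%s / %s (%s CV)", object$strategy,
                         object$classifier, object$scheme)) +
    theme_minimal()
}

#' @describeIn train_cnn tidy(): the per-epoch training log.
#' @param x,object A trained `boldnine_cnn`.
#' @param ... Unused.
#' @method tidy boldnine_cnn
#' @export
tidy.boldnine_cnn <- function(x, ...) {
  if (is.null(x$training_log)) abort("model has not been trained")
  x$training_log
}

#' @describeIn train_cnn glance(): parameter count, best epoch and its
#'   validation accuracy.
#' @method glance boldnine_cnn
#' @export
glance.boldnine_cnn <- function(x, ...) {
  tibble(parameters = parameter_count(x),
         epochs_run = if (is.null(x$training_log)) 0L else nrow(x$training_log),
         best_epoch = x$best_epoch,
         best_val_accuracy = if (is.null(x$training_log)) NA_real_ else
           x$training_log$val_accuracy[x$best_epoch],
         final_train_accuracy = if (is.null(x$training_log)) NA_real_ else
           x$training_log$train_accuracy[nrow(x$training_log)])
}

#' @describeIn train_cnn autoplot(): loss and accuracy curves over epochs.
#' @method autoplot boldnine_cnn
#' @export
autoplot.boldnine_cnn <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), -"epoch",
                            names_to = "series", values_to = "value")
  ggplot(df, aes(x = .data$epoch, y = .data$value, color = .data$series)) +
    geom_line() +
    labs(x = "epoch", y = NULL, color = NULL,
         title = sprintf("training curves (best epoch %d)",
                         object$best_epoch)) +
    theme_minimal()
}

#' @describeIn kendall_agreement tidy(): long pairwise table.
#' @param x,object An `agreement_matrix`.
#' @param ... Unused.
#' @method tidy agreement_matrix
#' @export
tidy.agreement_matrix <- function(x, ...) {
  m <- unclass(x)
  tidyr::pivot_longer(as_tibble(m, rownames = "model_a"), -"model_a",
                      names_to = "model_b", values_to = "tau")
}

#' @describeIn kendall_agreement autoplot(): heatmap of the average tau-b.
#' @method autoplot agreement_matrix
#' @export
autoplot.agreement_matrix <- function(object, ...) {
  df <- tidy.agreement_matrix(object)
  ggplot(df, aes(x = .data$model_a, y = .data$model_b, fill = .data$tau)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1), low = "darkblue",
                         mid = "white", high = "darkred") +
    labs(x = NULL, y = NULL, fill = "tau-b",
         title = "prediction agreement between models") +
    theme_minimal()
}

#' @describeIn run_occlusion tidy(): the per-region table, baseline row
#'   first.
#' @param x,object An `occlusion_report`.
#' @param ... Unused.
#' @method tidy occlusion_report
#' @export
tidy.occlusion_report <- function(x, ...) {
  base <- dplyr::mutate(x$baseline, roi_id = NA_integer_,
                        roi_name = "all brain", drop = 0, f1_drop = 0,
                        .before = 1)
  dplyr::bind_rows(base, x$per_roi)
}

#' @describeIn run_occlusion glance(): baseline metrics and the top region.
#' @method glance occlusion_report
#' @export
glance.occlusion_report <- function(x, ...) {
  tibble(strategy = x$strategy, classifier = x$classifier,
         baseline_balanced_accuracy = x$baseline$bal_acc_mean,
         baseline_f1 = x$baseline$f1_mean,
         top_roi = x$ranking[1],
         top_drop = x$per_roi$drop[1],
         n_rois = nrow(x$per_roi))
}

#' @describeIn run_occlusion autoplot(): balanced-accuracy drop per region.
#' @param top_n Number of regions to show.
#' @method autoplot occlusion_report
#' @export
autoplot.occlusion_report <- function(object, top_n = 10L, ...) {
  df <- head(object$per_roi, top_n)
  df$roi_name <- factor(df$roi_name, levels = rev(df$roi_name))
  ggplot(df, aes(x = .data$roi_name, y = .data$drop)) +
    geom_col(fill = "firebrick") +
    coord_flip() +
    labs(x = NULL, y = "balanced accuracy drop",
         title = sprintf("occlusion attribution (%s / %s)",
                         object$strategy, object$classifier)) +
    theme_minimal()
}
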