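#' Simulate a cohort to disk with provenance
#'
#' Wraps [generate_cohort()] for command-line use: writes the NIfTI runs,
#' the manifest, and a JSON provenance record of the full specification so
#' the cohort can be regenerated bit-for-bit.
#'
#' @param spec A [cohort_spec()].
#' @param effects List of [effect_spec()] objects.
#' @param dir Output directory.
#' @return The manifest tibble, invisibly.
#' @export
simulate_cohort <- function(spec, effects = list(), dir) {
  out <- generate_cohort(spec, effects, dir = dir)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    prov <- list(spec = spec[setdiff(names(spec), "sites")],
                 sites = spec$sites,
                 effects = lapply(effects, function(e) {
                   list(kind = e$kind, magnitude = e$magnitude,
                        applies_to = e$applies_to,
                        n_roi_voxels = sum(e$roi))
                 }))
    jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out$manifest)
}

#' Compute and write summary measures for every manifest subject
#'
#' Reads each subject's 4D run, computes the requested measures, and writes
#' one 3D NIfTI per (subject, measure) named `<subject>_<measure>.nii.gz`,
#' plus a tab-delimited index. Resumable: existing outputs are skipped
#' unless `force = TRUE`. Subjects failing the minimum-timepoints inclusion
#' cutoff are skipped with the reason recorded in the index.
#'
#' @param manifest Manifest tibble with valid `path` entries.
#' @param out_dir Output directory.
#' @param params A [measure_params()].
#' @param measures Which measures; default all nine.
#' @param force Recompute existing outputs.
#' @param tr_override Optional TR overriding the NIfTI headers.
#' @return Index tibble (`subject_id`, `measure`, `path`, `status`),
#'   invisibly; also written to `out_dir/index.tsv`.
#' @export
summarize_cohort <- function(manifest, out_dir, params = measure_params(),
                             measures = measure_names(), force = FALSE,
                             tr_override = NULL) {
  manifest <- validate_manifest(manifest)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    paths <- file.path(out_dir, paste0(sid, "_", measures, ".nii.gz"))
    if (!force && all(file.exists(paths))) {
      rows[[i]] <- tibble(subject_id = sid, measure = measures,
                          path = paths, status = "cached")
      next
    }
    run <- tryCatch(
      read_bold(manifest$path[i], tr_override = tr_override,
                subject_id = sid),
      boldnine_inclusion_error = function(e) e, error = function(e) e)
    if (inherits(run, "condition")) {
      rows[[i]] <- tibble(subject_id = sid, measure = measures,
                          path = NA_character_,
                          status = paste0("skipped: ", conditionMessage(run)))
      next
    }
    maps <- compute_all(run, params, measures)
    for (j in seq_along(measures)) write_summary(maps[[j]], paths[j])
    rows[[i]] <- tibble(subject_id = sid, measure = measures,
                        path = paths, status = "computed")
  }
  index <- dplyr::bind_rows(rows)
  readr::write_tsv(index, file.path(out_dir, "index.tsv"))
  invisible(index)
}

#' Load written summary maps back into a measure set
#'
#' @param index Index tibble from [summarize_cohort()] (or its `index.tsv`).
#' @return A `measure_set` tibble restricted to successfully computed maps.
#' @export
load_measures <- function(index) {
  if (is.character(index)) {
    index <- readr::read_tsv(index, show_col_types = FALSE, progress = FALSE)
  }
  ok <- index[!is.na(index$path) & file.exists(index$path), ]
  out <- dplyr::mutate(ok, volume = purrr::pmap(
    list(.data$subject_id, .data$measure, .data$path),
    function(sid, mm, p) {
      img <- RNifti::readNifti(p)
      summary_volume(sid, mm, array(as.vector(img), dim(img)))
    }))
  out <- out[, c("subject_id", "measure", "volume")]
  class(out) <- c("measure_set", class(out))
  out
}

#' Evaluate strategies and classifiers over a cross-validation scheme
#'
#' Runs the requested strategy-by-classifier grid with [run_strategy()] and
#' collects the fold-mean metrics into a single tidy table (the layout of a
#' results table: one row per strategy, classifier and scheme). Optionally
#' writes the table and computes the Kendall agreement matrix between all
#' single-measure models and the ensemble.
#'
#' @param measure_set A `measure_set` tibble.
#' @param manifest Manifest tibble.
#' @param splits A `fold_splits` tibble (from [split_fivefold()] or
#'   [split_leave_site_out()]).
#' @param strategies Character vector of strategies.
#' @param classifiers Character vector among `"cnn"`, `"svm"`.
#' @param config A [train_config()].
#' @param mask_fraction SVM group-mask fraction.
#' @param out_dir Optional directory for `results.tsv` (and
#'   `agreement.tsv`).
#' @param agreement Also compute the agreement matrix (needs
#'   `"mm_ensemble"` among the strategies).
#' @param keep_fits Passed to [run_strategy()].
#' @return A tibble with one row per (strategy, classifier): the mean
#'   metrics plus a list-column `result` of `eval_result` objects, and the
#'   agreement matrix as attribute `"agreement"` when requested.
#' @export
evaluate_cohort <- function(measure_set, manifest, splits, strategies,
                            classifiers = c("cnn", "svm"),
                            config = train_config(), mask_fraction = 0.9,
                            out_dir = NULL, agreement = FALSE,
                            keep_fits = FALSE) {
  grid <- expand.grid(strategy = strategies, classifier = classifiers,
                      stringsAsFactors = FALSE)
  results <- purrr::pmap(grid, function(strategy, classifier) {
    run_strategy(measure_set, manifest, splits, strategy, classifier,
                 config = config, mask_fraction = mask_fraction,
                 keep_fits = keep_fits)
  })
  out <- tibble(scheme = splits$scheme[1],
                strategy = grid$strategy, classifier = grid$classifier,
                balanced_accuracy = vapply(results, function(r)
                  r$mean_balanced_accuracy, 0),
                f1 = vapply(results, function(r) r$mean_f1, 0),
                result = results)
  agr <- NULL
  if (agreement) {
    ens_i <- which(grid$strategy == "mm_ensemble")
    if (length(ens_i) == 0L) {
      abort("agreement analysis needs 'mm_ensemble' among the strategies")
    }
    agr_in <- list()
    for (i in ens_i[1]) {
      r <- results[[i]]
      for (mm in measure_names()) {
        agr_in[[paste0("sm:", mm)]] <-
          lapply(r$folds, function(f) f$fit$components[[mm]]$pred)
      }
      agr_in[["mm_ensemble"]] <- lapply(r$folds, function(f) f$pred)
    }
    agr <- kendall_agreement(agr_in)
    attr(out, "agreement") <- agr
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(out[, setdiff(names(out), "result")],
                     file.path(out_dir, "results.tsv"))
    if (!is.null(agr)) {
      readr::write_tsv(as_tibble(unclass(agr), rownames = "model"),
                       file.path(out_dir, "agreement.tsv"))
    }
  }
  out
}

#' Run and write an occlusion report
#'
#' @param result An `eval_result` produced with `keep_fits = TRUE`.
#' @param atlas A [label_atlas()].
#' @param top_n Regions to report; default 10.
#' @param out_dir Optional directory for `occlusion.tsv`.
#' @return An `occlusion_report`.
#' @export
occlude_cohort <- function(result, atlas, top_n = 10L, out_dir = NULL) {
  rep <- run_occlusion(result, atlas, top_n)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    base_row <- tibble(roi_id = NA_integer_, roi_name = "all brain",
                       bal_acc_mean = rep$baseline$bal_acc_mean,
                       bal_acc_sd = rep$baseline$bal_acc_sd,
                       f1_mean = rep$baseline$f1_mean,
                       f1_sd = rep$baseline$f1_sd,
                       drop = 0, f1_drop = 0)
    readr::write_tsv(dplyr::bind_rows(base_row, rep$per_roi),
                     file.path(out_dir, "occlusion.tsv"))
  }
  rep
}
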