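#' Five-fold cross-validation splits with a fixed shared test set
#'
#' First carves out a single test set of `test_fraction` of the cohort,
#' stratified by site and diagnostic label, that is *identical across all
#' folds* -- a common benchmark every fold's model is scored on. The
#' remaining subjects are divided into `k` folds (same stratification);
#' fold i serves as the validation set and the other folds as training.
#' When a site-by-label stratum is smaller than `k`, stratification falls
#' back to label only, with a warning.
#'
#' @param manifest Manifest tibble (`subject_id`, `site`, `label`).
#' @param test_fraction Fraction held out as the common test set; default
#'   0.1.
#' @param k Number of folds; default 5.
#' @param seed RNG seed; identical seeds give identical splits.
#' @return A tibble of class `fold_splits` with one row per fold: `fold_id`,
#'   `scheme`, `held_out_site` (NA), and list-columns `train_ids`,
#'   `val_ids`, `test_ids`.
#' @export
split_fivefold <- function(manifest, test_fraction = 0.1, k = 5L, seed = 1L) {
  manifest <- validate_manifest(manifest)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  strata <- split(manifest$subject_id,
                  paste(manifest$site, manifest$label, sep = "|"))
  if (any(vapply(strata, length, 0L) < k)) {
    warn("a site-by-label stratum is smaller than k; stratifying by label only")
    strata <- split(manifest$subject_id, manifest$label)
  }
  test_ids <- character(); fold_of <- list()
  for (s in strata) {
    s <- sample(s)
    n_test <- round(test_fraction * length(s))
    test_ids <- c(test_ids, s[seq_len(n_test)])
    rest <- s[setdiff(seq_along(s), seq_len(n_test))]
    if (length(rest)) {
      fold_of[[length(fold_of) + 1L]] <-
        tibble(subject_id = rest,
               fold = rep_len(sample(seq_len(k)), length(rest)))
    }
  }
  assign_tb <- dplyr::bind_rows(fold_of)
  test_ids <- sort(test_ids)
  folds <- lapply(seq_len(k), function(i) {
    val <- sort(assign_tb$subject_id[assign_tb$fold == i])
    train <- sort(assign_tb$subject_id[assign_tb$fold != i])
    tibble(fold_id = i, scheme = "fivefold", held_out_site = NA_character_,
           train_ids = list(train), val_ids = list(val),
           test_ids = list(test_ids))
  })
  out <- dplyr::bind_rows(folds)
  class(out) <- c("fold_splits", class(out))
  out
}

#' Leave-site-out cross-validation splits
#'
#' Each named site is held out in turn as the test set; the remaining
#' subjects are randomly split into 90% training and 10% validation
#' (validation used for epoch selection). Held-out-site subjects never
#' appear in training or validation.
#'
#' @param manifest Manifest tibble.
#' @param sites Sites to hold out; default all sites in the manifest.
#' @param val_fraction Fraction of the non-held-out subjects used for
#'   validation; default 0.1.
#' @param seed RNG seed.
#' @return A `fold_splits` tibble, one row per held-out site.
#' @export
split_leave_site_out <- function(manifest, sites = NULL, val_fraction = 0.1,
                                 seed = 1L) {
  manifest <- validate_manifest(manifest)
  if (length(unique(manifest$site)) < 2L) {
    abort("leave-site-out needs at least 2 sites")
  }
  sites <- sites %||% sort(unique(manifest$site))
  unknown <- setdiff(sites, manifest$site)
  if (length(unknown)) {
    abort(paste0("unknown site(s): ", paste(unknown, collapse = ", ")))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  folds <- lapply(seq_along(sites), function(i) {
    s <- sites[i]
    test <- manifest$subject_id[manifest$site == s]
    if (length(test) < 2L) abort(sprintf("site '%s' has fewer than 2 subjects", s))
    rest <- sample(manifest$subject_id[manifest$site != s])
    n_val <- max(1L, round(val_fraction * length(rest)))
    tibble(fold_id = i, scheme = "leave_site_out", held_out_site = s,
           train_ids = list(sort(rest[-seq_len(n_val)])),
           val_ids = list(sort(rest[seq_len(n_val)])),
           test_ids = list(sort(test)))
  })
  out <- dplyr::bind_rows(folds)
  class(out) <- c("fold_splits", class(out))
  out
}

#' @export
print.fold_splits <- function(x, ...) {
  cat(sprintf("<fold_splits> %s | %d folds | train/val/test sizes: %s\n",
              x$scheme[1], nrow(x),
              paste(vapply(seq_len(nrow(x)), function(i) {
                sprintf("%d/%d/%d", length(x$train_ids[[i]]),
                        length(x$val_ids[[i]]), length(x$test_ids[[i]]))
              }, ""), collapse = " ")))
  invisible(x)
}
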