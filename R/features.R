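#' Fit a voxel-wise feature scaler on training subjects
#'
#' Computes the per-voxel mean and (population) standard deviation of one
#' summary measure across the *training* subjects only; applying the scaler
#' z-scores every subject against these training statistics. Fitting on the
#' training sample and applying to the whole dataset is what keeps the test
#' set untouched.
#'
#' @param vols List of [summary_volume()] objects sharing measure and grid.
#' @param ids Character vector of training subject ids; must be a subset of
#'   the subjects in `vols`. Defaults to all subjects in `vols`.
#' @return A list of class `scaler_params` with 3D `mean` and `std` arrays,
#'   the measure name, and `fitted_on`.
#' @export
fit_scaler <- function(vols, ids = NULL) {
  stopifnot(length(vols) >= 1)
  meas <- unique(vapply(vols, function(v) v$measure, ""))
  if (length(meas) != 1L) abort("all volumes must share one measure")
  all_ids <- vapply(vols, function(v) v$subject_id, "")
  if (is.null(ids)) ids <- all_ids
  if (!all(ids %in% all_ids)) abort("`ids` must be a subset of the volumes' subjects")
  use <- vols[match(ids, all_ids)]
  if (length(use) < 2L) abort("need at least 2 training subjects to fit a scaler")
  d <- dim(use[[1]]$data)
  m <- vapply(use, function(v) {
    if (!identical(dim(v$data), d)) abort("grid mismatch across volumes")
    as.vector(v$data)
  }, numeric(prod(d)))
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - mu)^2))     # population sd, the feature-scaling convention
  structure(list(mean = array(mu, d), std = array(sdv, d),
                 measure = meas, fitted_on = ids),
            class = "scaler_params")
}

#' Apply a fitted scaler to a summary volume
#'
#' Returns `(x - mean) / std` voxel-wise; voxels with zero training standard
#' deviation map to 0 rather than NaN. Applying a scaler twice is not the
#' same as applying it once (z-scoring is not idempotent).
#'
#' @param scaler A `scaler_params` from [fit_scaler()].
#' @param vol A [summary_volume()] of the same measure on the same grid.
#' @return A normalized [summary_volume()].
#' @export
apply_scaler <- function(scaler, vol) {
  if (!inherits(scaler, "scaler_params")) abort("`scaler` must come from fit_scaler()")
  if (!identical(scaler$measure, vol$measure)) {
    abort(sprintf("scaler was fitted on '%s' but volume is '%s'",
                  scaler$measure, vol$measure))
  }
  if (!identical(dim(scaler$mean), dim(vol$data))) abort("grid mismatch")
  z <- (vol$data - scaler$mean)
  ok <- scaler$std > 0
  z[ok] <- z[ok] / scaler$std[ok]
  z[!ok] <- 0
  summary_volume(vol$subject_id, vol$measure, z,
                 c(vol$params, list(scaled = TRUE)))
}

#' Build the group brain mask for SVM features
#'
#' Keeps a voxel when its raw summary value is nonzero in at least
#' `fraction` of the supplied subjects (and in at least one subject). Built
#' independently per measure, on raw (pre-scaling) values, from training
#' subjects only. Higher fractions give subset masks.
#'
#' @param vols List of [summary_volume()] of one measure.
#' @param fraction Required fraction of subjects with nonzero values;
#'   default 0.9.
#' @return A list of class `group_mask` with fields `mask` (3D logical),
#'   `fraction` and `n_features`.
#' @export
build_group_mask <- function(vols, fraction = 0.9) {
  if (length(vols) == 0L) abort("no volumes supplied")
  d <- dim(vols[[1]]$data)
  cnt <- Reduce(`+`, lapply(vols, function(v) {
    if (!identical(dim(v$data), d)) abort("grid mismatch across volumes")
    v$data != 0
  }))
  keep <- cnt >= fraction * length(vols) & cnt > 0
  structure(list(mask = array(keep, d), fraction = fraction,
                 n_features = sum(keep)),
            class = "group_mask")
}

#' Flatten summary volumes into a subjects-by-features matrix
#'
#' One row per subject, one column per in-mask voxel, in fixed column-major
#' voxel order (first spatial axis fastest) so layouts reproduce across
#' runs.
#'
#' @param vols List of [summary_volume()] of one measure.
#' @param mask A `group_mask` (or 3D logical array).
#' @return A list of class `feature_matrix`: `values` (matrix with subject
#'   ids as rownames), `subject_ids`, `measure`, `voxel_idx` (linear voxel
#'   index of each column).
#' @export
flatten_volumes <- function(vols, mask) {
  m <- if (inherits(mask, "group_mask")) mask$mask else mask
  d <- dim(vols[[1]]$data)
  if (!identical(dim(m), d)) abort("mask grid does not match volumes")
  idx <- which(as.vector(m))
  vals <- t(vapply(vols, function(v) {
    if (!identical(dim(v$data), d)) abort("grid mismatch across volumes")
    as.vector(v$data)[idx]
  }, numeric(length(idx))))
  ids <- vapply(vols, function(v) v$subject_id, "")
  rownames(vals) <- ids
  structure(list(values = vals, subject_ids = ids,
                 measure = vols[[1]]$measure, voxel_idx = idx),
            class = "feature_matrix")
}

#' Concatenate per-measure feature matrices
#'
#' Horizontal concatenation in the canonical measure order
#' ([measure_names()]), producing the flattened nine-measure feature vector
#' used by the multi-measure SVM.
#'
#' @param per_measure Named list measure -> `feature_matrix`.
#' @return A `feature_matrix` whose `measure` is `"mm"` and whose
#'   `feature_origin` records the per-column measure.
#' @export
concat_measures <- function(per_measure) {
  ord <- intersect(measure_names(), names(per_measure))
  if (length(ord) == 0L) abort("no recognizable measures in input")
  ids <- per_measure[[ord[1]]]$subject_ids
  for (mm in ord) {
    if (!identical(per_measure[[mm]]$subject_ids, ids)) {
      abort(sprintf("subject set for '%s' differs from '%s'", mm, ord[1]))
    }
  }
  vals <- do.call(cbind, lapply(ord, function(mm) per_measure[[mm]]$values))
  rownames(vals) <- ids
  origin <- unlist(lapply(ord, function(mm) {
    rep(mm, length(per_measure[[mm]]$voxel_idx))
  }))
  voxel_idx <- unlist(lapply(ord, function(mm) per_measure[[mm]]$voxel_idx))
  structure(list(values = vals, subject_ids = ids, measure = "mm",
                 voxel_idx = voxel_idx, feature_origin = origin),
            class = "feature_matrix")
}

#' Stack the nine summary measures as channels
#'
#' Builds the nine-channel input volume for the multi-measure CNN: an array
#' of shape (9, X, Y, Z) with channels in canonical measure order.
#'
#' @param per_measure Named list measure -> [summary_volume()] for one
#'   subject; all nine measures must be present on a common grid.
#' @return A numeric array of dim `c(9, grid)`.
#' @export
stack_channels <- function(per_measure) {
  miss <- setdiff(measure_names(), names(per_measure))
  if (length(miss)) {
    abort(paste0("missing measure(s): ", paste(miss, collapse = ", ")))
  }
  d <- dim(per_measure[[measure_names()[1]]]$data)
  out <- array(0, c(9L, d))
  for (i in seq_along(measure_names())) {
    v <- per_measure[[measure_names()[i]]]
    if (!identical(dim(v$data), d)) abort("grid mismatch across measures")
    out[i, , , ] <- v$data
  }
  out
}

#' Persist and reload a fitted scaler
#'
#' The voxel-wise mean and standard deviation are written as two 3D NIfTI
#' maps plus a JSON sidecar naming the measure and the training subjects
#' the scaler was fitted on.
#'
#' @param scaler A `scaler_params`.
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix; defaults to the measure name.
#' @return The directory, invisibly.
#' @export
write_scaler <- function(scaler, dir, prefix = scaler$measure) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_summary(scaler$mean, file.path(dir, paste0(prefix, "_mean.nii.gz")))
  write_summary(scaler$std, file.path(dir, paste0(prefix, "_std.nii.gz")))
  jsonlite::write_json(
    list(measure = scaler$measure, fitted_on = scaler$fitted_on),
    file.path(dir, paste0(prefix, "_scaler.json")), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(dir, prefix) {
  side <- jsonlite::read_json(file.path(dir, paste0(prefix, "_scaler.json")),
                              simplifyVector = TRUE)
  rd <- function(suffix) {
    img <- RNifti::readNifti(file.path(dir, paste0(prefix, suffix)))
    array(as.vector(img), dim(img))
  }
  structure(list(mean = rd("_mean.nii.gz"), std = rd("_std.nii.gz"),
                 measure = side$measure, fitted_on = side$fitted_on),
            class = "scaler_params")
}

#' Persist and reload a group mask
#'
#' @param mask A `group_mask`.
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @return The directory, invisibly.
#' @export
write_group_mask <- function(mask, dir, prefix = "group") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_summary(array(as.numeric(mask$mask), dim(mask$mask)),
                file.path(dir, paste0(prefix, "_mask.nii.gz")))
  jsonlite::write_json(
    list(fraction = mask$fraction, n_features = mask$n_features),
    file.path(dir, paste0(prefix, "_mask.json")), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_group_mask
#' @export
read_group_mask <- function(dir, prefix = "group") {
  side <- jsonlite::read_json(file.path(dir, paste0(prefix, "_mask.json")),
                              simplifyVector = TRUE)
  img <- RNifti::readNifti(file.path(dir, paste0(prefix, "_mask.nii.gz")))
  m <- array(as.vector(img) != 0, dim(img))
  structure(list(mask = m, fraction = side$fraction,
                 n_features = side$n_features),
            class = "group_mask")
}
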