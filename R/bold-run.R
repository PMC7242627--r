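#' Construct a BOLD run object
#'
#' A `bold_run` bundles one subject's 4D BOLD array with its repetition time,
#' brain mask and orientation. The minimum-duration inclusion rule (at least
#' 100 timepoints) is enforced at construction unless relaxed for toy inputs.
#'
#' @param subject_id Character scalar.
#' @param data 4D numeric array indexed (x, y, z, t). The first spatial axis
#'   is the left-right axis; homotopic mirroring flips this axis.
#' @param tr Repetition time in seconds (> 0).
#' @param brain_mask Optional 3D logical array on the same grid. Defaults to
#'   voxels with nonzero temporal variance.
#' @param affine 4x4 orientation matrix. Defaults to a diagonal voxel-size
#'   matrix built from `voxel_size`.
#' @param voxel_size Isotropic voxel edge in mm used for the default affine.
#' @param min_timepoints Inclusion cutoff on the number of timepoints;
#'   default 100. Lower it only for small test fixtures.
#'
#' @return An object of class `bold_run`.
#' @export
#' @examples
#' arr <- array(rnorm(4 * 4 * 4 * 120), c(4, 4, 4, 120))
#' run <- bold_run("sub-01", arr, tr = 2)
#' run$grid_shape
bold_run <- function(subject_id, data, tr, brain_mask = NULL, affine = NULL,
                     voxel_size = 4, min_timepoints = 100) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    abort("`data` must be a 4D array indexed (x, y, z, t)")
  }
  d <- dim(data)
  if (d[4] < min_timepoints) {
    abort(sprintf(
      "run has %d timepoints; inclusion cutoff requires at least %d",
      d[4], min_timepoints), class = "boldnine_inclusion_error")
  }
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    abort("`tr` must be a positive number of seconds")
  }
  grid <- d[1:3]
  if (is.null(brain_mask)) {
    v <- matrixwise_var(matrix(data, prod(grid), d[4]))
    brain_mask <- array(v > 0, grid)
  }
  if (!identical(dim(brain_mask), as.integer(grid)) &&
      !identical(dim(brain_mask), grid)) {
    abort("`brain_mask` must share the run's spatial grid")
  }
  storage.mode(brain_mask) <- "logical"
  if (anyNA(data[rep(brain_mask, d[4])]) ||
      any(!is.finite(data[rep(brain_mask, d[4])]))) {
    abort("non-finite values inside the brain mask")
  }
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size, 3), 1))
  }
  structure(
    list(subject_id = as.character(subject_id), data = data,
         tr = as.numeric(tr), grid_shape = as.integer(grid),
         brain_mask = brain_mask, affine = affine),
    class = "bold_run")
}

# rowwise variance of a voxels-by-time matrix without apply()
matrixwise_var <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %s | grid %s | %d timepoints | TR %.2fs | %d in-mask voxels\n",
              x$subject_id, paste(x$grid_shape, collapse = "x"),
              dim(x$data)[4], x$tr, sum(x$brain_mask)))
  invisible(x)
}

#' Construct a summary volume
#'
#' One 3D map for one (subject, measure) pair, plus the parameter settings
#' actually used to compute it.
#'
#' @param subject_id Character scalar.
#' @param measure One of [measure_names()].
#' @param data 3D numeric array on the BOLD grid.
#' @param params Named list of the measure's settings.
#' @return Object of class `summary_volume`.
#' @export
summary_volume <- function(subject_id, measure, data, params = list()) {
  check_measure(measure)
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array")
  }
  structure(
    list(subject_id = as.character(subject_id), measure = measure,
         data = data, params = params),
    class = "summary_volume")
}

#' @export
print.summary_volume <- function(x, ...) {
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("<summary_volume> %s | %s | grid %s | range [%.4g, %.4g]\n",
              x$subject_id, x$measure, paste(dim(x$data), collapse = "x"),
              rng[1], rng[2]))
  invisible(x)
}

#' Construct a label atlas
#'
#' A 3D integer parcellation on the BOLD grid: 0 is background, positive
#' integers are region ids used by the occlusion analysis.
#'
#' @param labels 3D integer array.
#' @param roi_names Optional named character vector mapping id to region name.
#' @return Object of class `label_atlas` with fields `labels`, `roi_ids`,
#'   `roi_names`.
#' @export
label_atlas <- function(labels, roi_names = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    abort("`labels` must be a 3D array")
  }
  if (any(labels != round(labels))) abort("atlas values must be integers")
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) abort("atlas contains no positive region labels")
  nm <- setNames(paste0("roi_", ids), as.character(ids))
  if (!is.null(roi_names)) nm[names(roi_names)] <- roi_names
  structure(list(labels = labels, roi_ids = ids, roi_names = nm),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> grid %s | %d regions\n",
              paste(dim(x$labels), collapse = "x"), length(x$roi_ids)))
  invisible(x)
}
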