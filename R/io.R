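#' Read a 4D BOLD run from a NIfTI file
#'
#' Loads a 4D NIfTI, takes the repetition time from the header (`pixdim[4]`)
#' unless overridden, and applies the minimum-duration inclusion rule.
#' Headers in the wild carry unreliable TRs, so an explicit `tr_override`
#' always wins.
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param tr_override Optional TR in seconds replacing the header value.
#' @param subject_id Subject identifier; defaults to the file stem.
#' @param min_timepoints Inclusion cutoff (default 100).
#' @return A [bold_run()].
#' @export
read_bold <- function(path, tr_override = NULL, subject_id = NULL,
                      min_timepoints = 100) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) {
    abort(sprintf("expected a 4D NIfTI, got %d dimensions", length(d)))
  }
  tr <- tr_override %||% RNifti::pixdim(img)[4]
  if (is.null(tr) || !is.finite(tr) || tr <= 0) {
    abort("TR missing from header pixdim[4]; pass `tr_override`")
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  bold_run(subject_id, array(as.vector(img), dim(img)), tr = tr,
           affine = unclass(aff)[1:4, 1:4], min_timepoints = min_timepoints)
}

#' Read a subject manifest
#'
#' The manifest is a comma- or tab-delimited table with a header row and
#' columns `subject_id`, `site`, `label`, `path` (plus optional
#' `n_timepoints`). Diagnostic labels may be coded as the strings
#' `ASD`/`CON` or as integers 1/0 (patient/control).
#'
#' @param path Path to the delimited file.
#' @return A tibble with columns `subject_id`, `site`, `label` (integer 0/1),
#'   `path`, and `n_timepoints` if present.
#' @export
read_manifest <- function(path) {
  df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  validate_manifest(df)
}

#' Validate (and normalize) a manifest tibble
#'
#' @param df Data frame with columns `subject_id`, `site`, `label`, `path`.
#' @return The manifest as a tibble with integer 0/1 labels.
#' @export
validate_manifest <- function(df) {
  need <- c("subject_id", "site", "label", "path")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("manifest missing columns: ",
                                 paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) abort("manifest is empty")
  df <- as_tibble(df)
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    abort("duplicate subject_id values in manifest")
  }
  if (any(!nzchar(df$site))) abort("empty site names in manifest")
  lab <- df$label
  if (is.character(lab) || is.factor(lab)) {
    lab <- as.character(lab)
    map <- c(ASD = 1L, CON = 0L, patient = 1L, control = 0L,
             "1" = 1L, "0" = 0L)
    if (any(!lab %in% names(map))) {
      abort(sprintf("unknown label value(s): %s",
                    paste(unique(lab[!lab %in% names(map)]), collapse = ", ")))
    }
    df$label <- unname(map[lab])
  } else {
    if (any(!lab %in% c(0, 1))) abort("numeric labels must be 0 or 1")
    df$label <- as.integer(lab)
  }
  df
}

#' Write a manifest to disk
#'
#' @param manifest Manifest tibble.
#' @param path Output path; format chosen by extension (`.tsv` for tab).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(manifest, path, delim = delim)
  invisible(path)
}

#' Read a 3D label atlas from a NIfTI file
#'
#' @param path Path to a 3D integer NIfTI.
#' @param names_path Optional two-column delimited file (`roi_id`, `name`).
#' @param grid_shape Optional expected grid; mismatch is an error.
#' @return A [label_atlas()].
#' @export
read_atlas <- function(path, names_path = NULL, grid_shape = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) abort("atlas must be a 3D NIfTI")
  if (!is.null(grid_shape) && !identical(as.integer(d), as.integer(grid_shape))) {
    abort(sprintf("atlas grid %s does not match dataset grid %s",
                  paste(d, collapse = "x"), paste(grid_shape, collapse = "x")))
  }
  nm <- NULL
  if (!is.null(names_path)) {
    tb <- readr::read_delim(names_path, show_col_types = FALSE, progress = FALSE)
    nm <- setNames(as.character(tb[[2]]), as.character(tb[[1]]))
  }
  label_atlas(as.array(img), roi_names = nm)
}

#' Write a summary volume as a 3D NIfTI
#'
#' Values round-trip exactly at double precision (`write_summary` then
#' [RNifti::readNifti()] reproduces the array bit-for-bit).
#'
#' @param vol A [summary_volume()] or 3D array.
#' @param path Output `.nii`/`.nii.gz` path; the directory must exist.
#' @param affine Optional 4x4 orientation matrix; taken from `vol$params$affine`
#'   when present.
#' @param voxel_size Voxel edge in mm for the default header.
#' @return `path`, invisibly.
#' @export
write_summary <- function(vol, path, affine = NULL, voxel_size = 4) {
  if (!dir.exists(dirname(path))) {
    abort(sprintf("directory does not exist: %s", dirname(path)))
  }
  arr <- if (inherits(vol, "summary_volume")) vol$data else vol
  if (length(dim(arr)) != 3L) abort("summary volumes are 3D")
  img <- RNifti::asNifti(array(as.double(arr), dim(arr)))
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a label atlas as an integer NIfTI
#'
#' @param atlas A [label_atlas()].
#' @param path Output path.
#' @param voxel_size Voxel edge in mm.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path, voxel_size = 4) {
  img <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}
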