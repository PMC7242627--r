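#' Specification of a synthetic multi-site BOLD cohort
#'
#' Describes a cohort of two diagnostic groups (patients and controls)
#' spread over acquisition sites with per-site mean/scale shifts --
#' emulating the multi-site heterogeneity of aggregated clinical rs-fMRI
#' datasets. Voxel time series are AR(1) noise plus shared low-frequency
#' oscillations; group effects are injected via [effect_spec()].
#'
#' @param n_subjects Cohort size.
#' @param grid_shape Spatial grid; default `c(24, 24, 24)` -- small enough
#'   that CNN training stays a CPU matter while every pipeline stage is
#'   exercised. The full 45x54x45 grid is equally supported.
#' @param n_timepoints Timepoints per run; default 120 (above the
#'   100-timepoint inclusion cutoff).
#' @param tr Repetition time in seconds; default 2.
#' @param sites Tibble with columns `name`, `proportion` (summing to 1),
#'   `mean_shift`, `scale_shift`. Default: three sites with modest shifts.
#' @param prevalence Fraction of patients; default 0.5.
#' @param ar_coef AR(1) coefficient of the voxel noise; default 0.3.
#' @param n_background_osc Number of shared in-band background oscillations
#'   per subject; default 3.
#' @param seed Base seed; every subject's randomness derives from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, grid_shape = c(24, 24, 24),
                        n_timepoints = 120, tr = 2,
                        sites = default_sites(), prevalence = 0.5,
                        ar_coef = 0.3, n_background_osc = 3L, seed = 1L) {
  stopifnot(n_subjects >= 2, n_timepoints >= 8, tr > 0)
  sites <- as_tibble(sites)
  if (abs(sum(sites$proportion) - 1) > 1e-8) {
    abort("site proportions must sum to 1")
  }
  if (prevalence <= 0 || prevalence >= 1) abort("prevalence must lie in (0, 1)")
  if (n_subjects < 2L * nrow(sites)) {
    abort("need at least 2 subjects per site")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 grid_shape = as.integer(grid_shape),
                 n_timepoints = as.integer(n_timepoints), tr = tr,
                 sites = sites, prevalence = prevalence,
                 ar_coef = ar_coef,
                 n_background_osc = as.integer(n_background_osc),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_sites <- function() {
  tibble(name = c("siteA", "siteB", "siteC"),
         proportion = c(0.5, 0.3, 0.2),
         mean_shift = c(0, 0.5, -0.5),
         scale_shift = c(1, 1.15, 0.9))
}

#' Specification of a group effect
#'
#' A localized difference between the diagnostic groups, expressed as a
#' signal feature that one (and essentially only one) summary measure is
#' sensitive to:
#' \describe{
#'   \item{`local_synchrony`}{region voxels of affected subjects share a
#'     latent component carrying a `magnitude` fraction of their variance
#'     (a variance-preserving correlated mixture) -- raises ReHo and degree
#'     centrality inside the region while leaving amplitude spectra
#'     essentially unchanged;}
#'   \item{`low_freq_amplitude`}{extra in-band oscillation of amplitude
#'     `magnitude` with a random phase per region voxel -- raises ALFF
#'     without synchronizing neighbors;}
#'   \item{`homotopic_coupling`}{the shared-latent mixture applied to the
#'     region *and* its left-right mirror -- raises VMHC.}
#' }
#' With magnitude 0 the groups are exchangeable.
#'
#' @param kind One of the three effect kinds.
#' @param roi 3D logical array marking the region (on the cohort grid).
#' @param magnitude For the two coupling kinds, the shared-variance
#'   fraction (capped at 0.95); for `low_freq_amplitude`, the oscillation
#'   amplitude relative to unit noise sd. >= 0.
#' @param applies_to `"patient"` (default) or `"control"`.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(kind = c("local_synchrony", "low_freq_amplitude",
                                 "homotopic_coupling"),
                        roi, magnitude, applies_to = c("patient", "control")) {
  kind <- match.arg(kind)
  applies_to <- match.arg(applies_to)
  stopifnot(magnitude >= 0, is.array(roi), length(dim(roi)) == 3L)
  structure(list(kind = kind, roi = array(as.logical(roi), dim(roi)),
                 magnitude = magnitude, applies_to = applies_to),
            class = "effect_spec")
}

# ellipsoidal brain mask inscribed in the grid
ellipsoid_mask <- function(grid, fill = 0.9) {
  cx <- (grid + 1) / 2
  r <- grid / 2 * fill
  g <- arrayInd(seq_len(prod(grid)), grid)
  inside <- ((g[, 1] - cx[1]) / r[1])^2 + ((g[, 2] - cx[2]) / r[2])^2 +
    ((g[, 3] - cx[3]) / r[3])^2 <= 1
  array(inside, grid)
}

# AR(1) innovations-to-series recursion for many voxels at once; returns
# an n x v matrix (time by voxel)
ar1_matrix <- function(n, v, phi) {
  m <- matrix(rnorm(n * v), v, n)      # voxel-major: column ops contiguous
  for (t in 2:n) m[, t] <- phi * m[, t - 1] + m[, t]
  t(m)
}

# a latent AR(1) signal with the same spectral family as the voxel noise,
# standardized to zero mean and unit sd: mixing it in changes correlation
# structure without changing marginal amplitude
latent_signal <- function(n, ar_coef) {
  as.vector(scale(ar1_matrix(n, 1L, ar_coef)))
}

#' Generate one synthetic BOLD run
#'
#' Voxel series are AR(1) noise (unit innovation sd) plus shared in-band
#' sinusoidal background with random per-voxel loadings, then the site's
#' mean/scale shift; group effects are added inside their regions for
#' subjects of the designated group. All randomness derives from `seed`:
#' the same seed reproduces the run exactly.
#'
#' @param spec A [cohort_spec()].
#' @param subject One manifest row (needs `subject_id`, `site`, `label`).
#' @param effects List of [effect_spec()] objects.
#' @param seed Integer seed for this run.
#' @return A [bold_run()].
#' @export
generate_run <- function(spec, subject, effects = list(), seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  grid <- spec$grid_shape; n <- spec$n_timepoints
  mask <- ellipsoid_mask(grid)
  v <- prod(grid)
  tt <- (seq_len(n) - 1) * spec$tr
  # AR(1) noise, all voxels at once
  x <- ar1_matrix(n, v, spec$ar_coef)
  # shared low-frequency background with random voxel loadings
  for (j in seq_len(spec$n_background_osc)) {
    f <- runif(1, 0.015, 0.095)
    osc <- sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
    x <- x + osc %o% runif(v, 0.2, 0.8)
  }
  grp <- if (subject$label == 1L) "patient" else "control"
  for (ef in effects) {
    if (!identical(dim(ef$roi), grid)) abort("effect region outside the grid")
    if (ef$applies_to != grp || ef$magnitude == 0) next
    roi_idx <- which(as.vector(ef$roi))
    if (ef$kind == "local_synchrony") {
      # variance-preserving correlated mixture: region voxels share a
      # latent AR(1) component with weight sqrt(rho) -- raises local
      # synchrony (ReHo) without altering the amplitude spectrum family,
      # so spectral measures stay uninformative
      rho <- min(ef$magnitude, 0.95)
      s <- latent_signal(n, spec$ar_coef) * stats::sd(x[, roi_idx[1]])
      x[, roi_idx] <- sqrt(1 - rho) * x[, roi_idx] +
        sqrt(rho) * s
    } else if (ef$kind == "low_freq_amplitude") {
      # extra in-band oscillation with a random phase per voxel: raises
      # ALFF without synchronizing neighboring voxels
      f <- runif(1, 0.02, 0.08)
      ph <- runif(length(roi_idx), 0, 2 * pi)
      x[, roi_idx] <- x[, roi_idx] +
        ef$magnitude * sin(outer(2 * pi * f * tt, ph, "+"))
    } else { # homotopic_coupling
      mir <- as.vector(array(seq_len(v), grid)[grid[1]:1, , , drop = FALSE])
      rho <- min(ef$magnitude, 0.95)
      both <- union(roi_idx, mir[roi_idx])
      s <- latent_signal(n, spec$ar_coef) * stats::sd(x[, both[1]])
      x[, both] <- sqrt(1 - rho) * x[, both] + sqrt(rho) * s
    }
  }
  site <- spec$sites[spec$sites$name == subject$site, ]
  x <- site$mean_shift + site$scale_shift * x
  x[, !as.vector(mask)] <- 0
  arr <- array(t(x), c(grid, n))
  bold_run(subject$subject_id, arr, tr = spec$tr, brain_mask = mask,
           min_timepoints = min(100L, n))
}

# largest-remainder allocation of n into proportions
allocate_counts <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic cohort
#'
#' Builds the manifest (site proportions and patient prevalence respected
#' to rounding, patients stratified across sites) and generates every run.
#' With `dir` set, runs are written as NIfTI plus a `manifest.csv`;
#' otherwise runs are returned in memory. Regeneration with the same seed
#' is identical.
#'
#' @param spec A [cohort_spec()].
#' @param effects List of [effect_spec()] objects.
#' @param dir Optional output directory (created if missing).
#' @return A list with `manifest` (tibble) and either `runs` (in-memory
#'   list of [bold_run()]) or `dir`.
#' @export
generate_cohort <- function(spec, effects = list(), dir = NULL) {
  ns <- allocate_counts(spec$n_subjects, spec$sites$proportion)
  rows <- list()
  for (i in seq_len(nrow(spec$sites))) {
    n_pat <- allocate_counts(ns[i], c(spec$prevalence, 1 - spec$prevalence))[1]
    lab <- c(rep(1L, n_pat), rep(0L, ns[i] - n_pat))
    rows[[i]] <- tibble(site = spec$sites$name[i], label = lab)
  }
  manifest <- dplyr::bind_rows(rows)
  manifest$subject_id <- sprintf("sub-%03d", seq_len(nrow(manifest)))
  manifest$path <- NA_character_
  manifest$n_timepoints <- spec$n_timepoints
  manifest <- manifest[, c("subject_id", "site", "label", "path",
                           "n_timepoints")]
  runs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    runs[[i]] <- generate_run(spec, manifest[i, ], effects,
                              seed = spec$seed + i)
  }
  if (is.null(dir)) {
    return(list(manifest = manifest, runs = runs))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(runs)) {
    p <- file.path(dir, paste0(manifest$subject_id[i], "_bold.nii.gz"))
    img <- RNifti::asNifti(runs[[i]]$data)
    RNifti::pixdim(img) <- c(4, 4, 4, spec$tr)
    RNifti::writeNifti(img, p)
    manifest$path[i] <- p
  }
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  list(manifest = manifest, dir = dir)
}

#' A simple block-parcellation atlas for synthetic grids
#'
#' Divides the grid into `k^3` equal rectangular blocks and labels those
#' intersecting the ellipsoidal brain mask with consecutive region ids --
#' a stand-in parcellation for occlusion experiments on synthetic cohorts.
#'
#' @param grid_shape Integer triple.
#' @param k Blocks per axis; default 2 (8 regions).
#' @return A [label_atlas()].
#' @export
block_atlas <- function(grid_shape, k = 2L) {
  grid <- as.integer(grid_shape)
  cuts <- lapply(grid, function(g) pmin(((seq_len(g) - 1L) * k) %/% g, k - 1L))
  lab <- array(0L, grid)
  idx <- arrayInd(seq_len(prod(grid)), grid)
  lab[] <- cuts[[1]][idx[, 1]] + k * cuts[[2]][idx[, 2]] +
    k * k * cuts[[3]][idx[, 3]] + 1L
  mask <- ellipsoid_mask(grid)
  lab[!mask] <- 0L
  # renumber to consecutive ids over blocks that survive masking
  ids <- sort(unique(lab[lab > 0L]))
  lab2 <- array(0L, grid)
  for (i in seq_along(ids)) lab2[lab == ids[i]] <- i
  label_atlas(lab2)
}
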