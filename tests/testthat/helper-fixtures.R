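# shared fixtures: all synthetic, built in code at test time

# a small random run; min_timepoints relaxed for toy sizes
toy_run <- function(grid = c(4, 4, 4), n = 40, tr = 2, seed = 1,
                    mask = NULL) {
  set.seed(seed)
  arr <- array(rnorm(prod(grid) * n), c(grid, n))
  bold_run(paste0("toy", seed), arr, tr = tr, brain_mask = mask,
           min_timepoints = 8)
}

# run with specified voxel series: `series` is a V x n matrix aligned with
# column-major voxel order
run_from_series <- function(series, grid, tr = 2, mask = NULL,
                            subject_id = "s1") {
  n <- ncol(series)
  arr <- array(0, c(grid, n))
  arr[] <- as.vector(series)
  bold_run(subject_id, arr, tr = tr, brain_mask = mask, min_timepoints = 8)
}

# quick manifest for split tests
toy_manifest <- function(n = 40, sites = c("A", "B"), seed = 1,
                         prevalence = 0.5) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    site = sample(rep_len(sites, n)),
    label = sample(rep_len(c(1L, 0L), n)),
    path = NA_character_)
}

# small effect cohort with its measures, shared by strategy/occlusion tests
effect_cohort <- function(n = 60, grid = c(12, 12, 12), magnitude = 0.7,
                          kind = "local_synchrony", seed = 1,
                          measures = c("reho", "alff"), n_timepoints = 100) {
  roi <- array(FALSE, grid)
  roi[4:8, 4:8, 4:8] <- TRUE
  spec <- cohort_spec(n_subjects = n, grid_shape = grid,
                      n_timepoints = n_timepoints, seed = seed)
  eff <- effect_spec(kind, roi, magnitude = magnitude)
  coh <- generate_cohort(spec, list(eff))
  list(manifest = coh$manifest, runs = coh$runs, roi = roi,
       measures = summarize_runs(coh$runs, measures = measures))
}
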