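test_that("cohort composition respects site proportions and prevalence", {
  spec <- cohort_spec(n_subjects = 60, grid_shape = c(6, 6, 6),
                      n_timepoints = 30, seed = 1)
  coh <- generate_cohort(spec)
  counts <- table(coh$manifest$site)
  expect_equal(as.integer(counts[c("siteA", "siteB", "siteC")]),
               c(30L, 18L, 12L))
  expect_equal(sum(coh$manifest$label), 30L)
  # every site contains both groups
  expect_true(all(table(coh$manifest$site, coh$manifest$label) > 0))
  expect_error(cohort_spec(n_subjects = 4, grid_shape = c(6, 6, 6),
                           n_timepoints = 30),
               "2 subjects per site")
})

test_that("generation is deterministic in the seed, subject by subject", {
  spec <- cohort_spec(n_subjects = 6, grid_shape = c(6, 6, 6),
                      n_timepoints = 30, seed = 5)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$runs[[3]]$data, c2$runs[[3]]$data)
  sub <- c1$manifest[1, ]
  r1 <- generate_run(spec, sub, list(), seed = 9)
  r2 <- generate_run(spec, sub, list(), seed = 9)
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data, generate_run(spec, sub, list(), seed = 10)$data))
})

test_that("zero-magnitude effects leave the groups exchangeable", {
  grid <- c(8, 8, 8)
  roi <- array(FALSE, grid); roi[3:6, 3:6, 3:6] <- TRUE
  spec <- cohort_spec(n_subjects = 40, grid_shape = grid, n_timepoints = 40,
                      sites = tibble::tibble(name = "s", proportion = 1,
                                             mean_shift = 0, scale_shift = 1),
                      seed = 2)
  eff <- effect_spec("local_synchrony", roi, magnitude = 0)
  coh <- generate_cohort(spec, list(eff))
  # voxel means inside the region, patients vs controls
  roi_means <- vapply(coh$runs, function(r) {
    mean(r$data[array(roi, dim(r$data)[1:3])])
  }, 0)
  grp <- coh$manifest$label
  ks <- stats::ks.test(roi_means[grp == 1], roi_means[grp == 0])
  expect_gt(ks$p.value, 0.01)
})

test_that("the synchrony effect raises in-region ReHo for patients", {
  grid <- c(8, 8, 8)
  roi <- array(FALSE, grid); roi[3:6, 3:6, 3:6] <- TRUE
  spec <- cohort_spec(n_subjects = 8, grid_shape = grid, n_timepoints = 60,
                      seed = 3)
  eff <- effect_spec("local_synchrony", roi, magnitude = 0.7)
  coh <- generate_cohort(spec, list(eff))
  core <- array(FALSE, grid); core[4:5, 4:5, 4:5] <- TRUE  # interior of roi
  for (i in seq_along(coh$runs)) {
    r <- coh$runs[[i]]
    reho <- compute_reho(r)$data
    msk <- r$brain_mask & !roi
    inside_m <- mean(reho[core])
    outside_m <- mean(reho[msk])
    if (coh$manifest$label[i] == 1L) {
      expect_gt(inside_m, outside_m)
    } else {
      expect_lt(abs(inside_m - outside_m), 0.15)
    }
  }
})

test_that("the amplitude effect raises in-region ALFF, not ReHo", {
  grid <- c(8, 8, 8)
  roi <- array(FALSE, grid); roi[3:6, 3:6, 3:6] <- TRUE
  spec <- cohort_spec(n_subjects = 8, grid_shape = grid, n_timepoints = 80,
                      seed = 4)
  eff <- effect_spec("low_freq_amplitude", roi, magnitude = 2)
  coh <- generate_cohort(spec, list(eff))
  core <- array(FALSE, grid); core[4:5, 4:5, 4:5] <- TRUE
  for (i in which(coh$manifest$label == 1L)) {
    r <- coh$runs[[i]]
    alff <- compute_alff(r)$data
    expect_gt(mean(alff[core]), mean(alff[r$brain_mask & !roi]))
  }
})

test_that("homotopic coupling raises VMHC in the region and its mirror", {
  grid <- c(8, 8, 8)
  roi <- array(FALSE, grid); roi[2:3, 3:6, 3:6] <- TRUE   # one hemisphere
  spec <- cohort_spec(n_subjects = 8, grid_shape = grid, n_timepoints = 60,
                      seed = 6)
  eff <- effect_spec("homotopic_coupling", roi, magnitude = 0.8)
  coh <- generate_cohort(spec, list(eff))
  for (i in seq_along(coh$runs)) {
    r <- coh$runs[[i]]
    vm <- compute_vmhc(r)$data
    msk <- r$brain_mask
    inside <- mean(vm[roi & msk])
    outside <- mean(vm[msk & !roi & !roi[8:1, , ]])
    if (coh$manifest$label[i] == 1L) {
      expect_gt(inside, outside + 0.2)
    }
  }
})

test_that("cohorts write to disk with a readable manifest and NIfTI runs", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_subjects = 6, grid_shape = c(6, 6, 6),
                      n_timepoints = 110, seed = 7)
  out <- generate_cohort(spec, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 6L)
  run <- read_bold(m$path[1])
  expect_equal(run$tr, spec$tr)
  expect_equal(dim(run$data)[4], 110L)
})

test_that("the block atlas covers the brain mask with labeled regions", {
  at <- block_atlas(c(12, 12, 12), k = 2)
  expect_s3_class(at, "label_atlas")
  expect_gte(length(at$roi_ids), 6L)
  msk <- ellipsoid_mask_ref <- boldnine:::ellipsoid_mask(c(12, 12, 12))
  expect_true(all(at$labels[!msk] == 0L))
  expect_true(all(at$labels[msk] > 0L))
})
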