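mk_vols <- function(values_list, measure = "reho", grid = c(3, 3, 3)) {
  lapply(seq_along(values_list), function(i) {
    summary_volume(sprintf("s%02d", i), measure,
                   array(values_list[[i]], grid))
  })
}

test_that("scaler uses training subjects only, population sd convention", {
  g <- c(2, 2, 2)
  vols <- mk_vols(list(rep(0, 8), rep(2, 8), rep(100, 8)), grid = g)
  sc <- fit_scaler(vols, ids = c("s01", "s02"))
  expect_equal(as.vector(sc$mean), rep(1, 8))
  expect_equal(as.vector(sc$std), rep(1, 8))   # population sd of {0, 2}
  expect_identical(sc$fitted_on, c("s01", "s02"))
  # the untouched third subject scales against the training statistics
  expect_equal(as.vector(apply_scaler(sc, vols[[3]])$data), rep(99, 8))
})

test_that("scaling its own training set gives mean 0, sd 1 per voxel", {
  set.seed(1)
  g <- c(3, 3, 3)
  vols <- mk_vols(lapply(1:6, function(i) rnorm(27)), grid = g)
  sc <- fit_scaler(vols)
  z <- vapply(vols, function(v) as.vector(apply_scaler(sc, v)$data),
              numeric(27))
  expect_equal(rowMeans(z), rep(0, 27), tolerance = 1e-12)
  expect_equal(sqrt(rowMeans(z^2)), rep(1, 27), tolerance = 1e-12)
  # z-scoring is not idempotent: applying twice differs
  z2 <- apply_scaler(sc, apply_scaler(sc, vols[[1]]))
  expect_false(isTRUE(all.equal(z2$data, apply_scaler(sc, vols[[1]])$data)))
})

test_that("zero-variance voxels map to 0 and mismatches error", {
  g <- c(2, 2, 2)
  vols <- mk_vols(list(rep(1, 8), rep(1, 8)), grid = g)
  sc <- fit_scaler(vols)
  out <- apply_scaler(sc, vols[[1]])
  expect_true(all(out$data == 0))
  wrong <- summary_volume("x", "alff", array(0, g))
  expect_error(apply_scaler(sc, wrong), "fitted on")
  expect_error(fit_scaler(vols[1]), "at least 2")
})

test_that("scaler and mask never see held-out subjects", {
  set.seed(2)
  g <- c(3, 3, 3)
  vals <- lapply(1:8, function(i) rnorm(27))
  vols <- mk_vols(vals, grid = g)
  train <- sprintf("s%02d", 1:5)
  sc <- fit_scaler(vols, train)
  gm <- build_group_mask(vols[1:5], 0.6)
  # perturb the held-out subjects wildly: fitted artifacts are unchanged
  vols2 <- vols
  for (i in 6:8) vols2[[i]]$data <- vols2[[i]]$data * 1e6 + 17
  expect_identical(fit_scaler(vols2, train)$mean, sc$mean)
  expect_identical(fit_scaler(vols2, train)$std, sc$std)
  expect_identical(build_group_mask(vols2[1:5], 0.6)$mask, gm$mask)
})

test_that("group mask applies the at-least-90% nonzero rule at the boundary", {
  g <- c(2, 2, 2)
  vals <- lapply(1:10, function(i) rep(1, 8))
  # voxel 1 nonzero in 9/10 subjects, voxel 2 in 8/10
  for (i in 1:1) vals[[i]][1] <- 0
  for (i in 1:2) vals[[i]][2] <- 0
  vols <- mk_vols(vals, grid = g)
  gm <- build_group_mask(vols, 0.9)
  expect_true(gm$mask[1])     # kept at exactly 90%
  expect_false(gm$mask[2])    # dropped at 80%
  expect_equal(gm$n_features, sum(gm$mask))
  # fraction 0 degenerates to the any-nonzero union
  vals0 <- lapply(1:4, function(i) c(0, rep(1, 7)))
  gm0 <- build_group_mask(mk_vols(vals0, grid = g), 0)
  expect_false(gm0$mask[1])
  expect_true(all(gm0$mask[2:8]))
})

test_that("group mask is monotone in the fraction", {
  set.seed(3)
  vols <- mk_vols(lapply(1:10, function(i) rbinom(27, 1, 0.7) * rnorm(27)))
  prev <- NULL
  for (f in c(0.2, 0.5, 0.8, 1)) {
    gm <- build_group_mask(vols, f)
    if (!is.null(prev)) expect_true(all(prev | !gm$mask))
    prev <- gm$mask
  }
})

test_that("flattening is subject-by-voxel with a fixed order and invertible", {
  set.seed(4)
  g <- c(3, 2, 2)
  vols <- mk_vols(list(rnorm(12), rnorm(12)), grid = g)
  mask <- array(FALSE, g); mask[c(1, 5, 9)] <- TRUE
  fm <- flatten_volumes(vols, mask)
  expect_equal(dim(fm$values), c(2L, 3L))
  expect_equal(fm$values[1, ], as.vector(vols[[1]]$data)[c(1, 5, 9)])
  # round trip back onto the grid
  rec <- array(0, g)
  rec[fm$voxel_idx] <- fm$values[2, ]
  expect_equal(rec[mask], vols[[2]]$data[mask])
  # permuting subjects permutes rows only
  fm2 <- flatten_volumes(vols[c(2, 1)], mask)
  expect_equal(fm2$values, fm$values[c(2, 1), ])
})

test_that("concatenation follows canonical measure order and checks subjects", {
  set.seed(5)
  g <- c(2, 2, 2)
  mk <- function(measure, w) {
    vols <- mk_vols(list(rnorm(8), rnorm(8)), measure = measure, grid = g)
    mask <- array(FALSE, g); mask[seq_len(w)] <- TRUE
    flatten_volumes(vols, mask)
  }
  per <- list(alff = mk("alff", 2), reho = mk("reho", 3), vmhc = mk("vmhc", 4))
  cc <- concat_measures(per)
  expect_equal(ncol(cc$values), 9L)
  expect_equal(cc$feature_origin, c(rep("reho", 3), rep("alff", 2),
                                    rep("vmhc", 4)))
  expect_equal(cc$values[, 4:5], per$alff$values)
  one <- concat_measures(per["reho"])
  expect_equal(one$values, per$reho$values)
  bad <- per
  bad$vmhc$subject_ids <- c("s01", "zz")
  expect_error(concat_measures(bad), "differs")
})

test_that("channel stacking is complete, ordered, and shape-correct", {
  set.seed(6)
  g <- c(4, 3, 2)
  per <- setNames(lapply(measure_names(), function(mm) {
    summary_volume("s1", mm, array(rnorm(24), g))
  }), measure_names())
  x <- stack_channels(per)
  expect_equal(dim(x), c(9L, g))
  for (i in seq_along(measure_names())) {
    expect_equal(x[i, , , ], per[[measure_names()[i]]]$data)
  }
  expect_error(stack_channels(per[-3]), "falff")
})

test_that("scaler, mask and model checkpoints round-trip through disk", {
  set.seed(7)
  g <- c(3, 3, 3)
  vols <- mk_vols(lapply(1:4, function(i) rnorm(27)), grid = g)
  sc <- fit_scaler(vols, sprintf("s%02d", 1:3))
  dir <- withr::local_tempdir()
  write_scaler(sc, dir)
  sc2 <- read_scaler(dir, "reho")
  expect_equal(sc2$mean, unclass(sc$mean), ignore_attr = TRUE)
  expect_equal(sc2$std, unclass(sc$std), ignore_attr = TRUE)
  expect_identical(sc2$fitted_on, sc$fitted_on)
  gm <- build_group_mask(vols, 0.5)
  write_group_mask(gm, dir)
  gm2 <- read_group_mask(dir)
  expect_equal(gm2$mask, gm$mask, ignore_attr = TRUE)
  expect_equal(gm2$n_features, gm$n_features)
  m <- build_cnn(cnn_spec(c(12, 12, 12)), seed = 1)
  p <- file.path(dir, "model.rds")
  write_model(m, p)
  m2 <- read_model(p)
  expect_identical(m2$weights, m$weights)
})
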