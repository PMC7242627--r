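# per-voxel series of a run as a V x n matrix
series_matrix <- function(run) {
  matrix(run$data, prod(run$grid_shape), dim(run$data)[4])
}

# --- ReHo -------------------------------------------------------------

# brute-force ReHo oracle: per voxel, collect the in-mask neighborhood
# series and apply the W oracle directly
oracle_reho <- function(run, nbhd = 27) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  if (nbhd == 7) offs <- offs[rowSums(abs(offs)) <= 1, ]
  if (nbhd == 19) offs <- offs[rowSums(abs(offs)) <= 2, ]
  d <- run$grid_shape
  m <- series_matrix(run)
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!run$brain_mask[i, j, k]) next
    nb <- cbind(i + offs$dx, j + offs$dy, k + offs$dz)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    nb <- nb[run$brain_mask[nb], , drop = FALSE]
    if (nrow(nb) < 2) next
    sm <- t(m[(nb[, 3] - 1) * d[1] * d[2] + (nb[, 2] - 1) * d[1] + nb[, 1],
              , drop = FALSE])
    if (any(apply(sm, 2, function(x) max(x) == min(x)))) next
    rk <- apply(sm, 2, rank)
    ri <- rowSums(rk)
    n <- nrow(sm); kk <- ncol(sm)
    out[i, j, k] <- 12 * sum((ri - mean(ri))^2) / (kk^2 * (n^3 - n))
  }
  out
}

test_that("ReHo matches the brute-force neighborhood oracle", {
  for (nbhd in c(7, 19, 27)) {
    run <- toy_run(c(4, 4, 4), n = 20, seed = nbhd)
    got <- compute_reho(run, measure_params(reho_neighborhood = nbhd))
    expect_equal(got$data, oracle_reho(run, nbhd), tolerance = 1e-10)
  }
})

test_that("a synchronized block has ReHo near 1 and noise stays low", {
  d <- c(3, 3, 3); n <- 100
  set.seed(5)
  base <- rnorm(n)
  m <- matrix(rep(base, each = 27), 27, n) + 1e-4 * matrix(rnorm(27 * n), 27)
  run <- run_from_series(m, d, tr = 2)
  reho <- compute_reho(run)
  expect_gt(reho$data[2, 2, 2], 0.99)
  # independent white noise: center voxel (K = 27) well below 0.5
  set.seed(6)
  vals <- replicate(30, {
    r <- run_from_series(matrix(rnorm(27 * n), 27, n), d)
    compute_reho(r)$data[2, 2, 2]
  })
  expect_true(all(vals < 0.5))
})

test_that("ReHo is invariant to monotone transforms and constant shifts", {
  run <- toy_run(c(4, 4, 4), n = 24, seed = 9)
  base <- compute_reho(run)$data
  cubed <- run; cubed$data <- run$data^3
  expect_equal(compute_reho(cubed)$data, base)
  shifted <- run; shifted$data <- run$data + 7
  expect_equal(compute_reho(shifted)$data, base)
})

# --- spectra: ALFF / fALFF --------------------------------------------

# naive O(n^2) DFT oracle with the same amplitude normalization
oracle_spectrum <- function(x, tr) {
  n <- length(x)
  k <- seq_len(n %/% 2)
  amp <- vapply(k, function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * (seq_len(n) - 1) / n))) / sqrt(n)
  }, 0)
  list(freqs = k / (n * tr), amplitudes = amp)
}

test_that("amplitude spectrum matches a naive DFT and locates a pure tone", {
  set.seed(3)
  x <- rnorm(16)
  got <- amplitude_spectrum(x, tr = 2)
  ora <- oracle_spectrum(x, tr = 2)
  expect_equal(got$freqs, ora$freqs)
  expect_equal(got$amplitudes, ora$amplitudes, tolerance = 1e-10)
  tt <- (0:199) * 2
  tone <- sin(2 * pi * 0.05 * tt)
  sp <- amplitude_spectrum(tone, tr = 2)
  expect_equal(sp$freqs[which.max(sp$amplitudes)], 0.05)
  expect_equal(amplitude_spectrum(rep(3, 64), 2)$amplitudes,
               rep(0, 32), tolerance = 1e-12)
  expect_error(amplitude_spectrum(rnorm(5), 2), "at least 8")
})

test_that("ALFF is linear, captures a whole in-band tone, matches the oracle", {
  tt <- (0:199) * 2
  tone <- sin(2 * pi * 0.05 * tt)
  mk <- function(x) run_from_series(matrix(rep(x, 8), 8, byrow = TRUE),
                                    c(2, 2, 2))
  a1 <- compute_alff(mk(tone))$data[1]
  expect_equal(compute_alff(mk(2 * tone))$data[1], 2 * a1)
  # the tone is the series' entire spectral content
  expect_equal(a1, sum(oracle_spectrum(tone, 2)$amplitudes), tolerance = 1e-8)
  set.seed(8)
  ar <- as.vector(stats::filter(rnorm(100), 0.5, method = "recursive"))
  ora <- oracle_spectrum(ar, 2)
  band <- ora$freqs >= 0.01 & ora$freqs <= 0.1
  expect_equal(compute_alff(mk(ar))$data[1], sum(ora$amplitudes[band]),
               tolerance = 1e-8)
})

test_that("fALFF is a unit-bounded scale-free band fraction", {
  tt <- (0:19) * 2
  mk <- function(x) run_from_series(matrix(rep(x, 8), 8, byrow = TRUE),
                                    c(2, 2, 2))
  inband <- sin(2 * pi * 0.05 * tt)
  outband <- sin(2 * pi * 0.2 * tt)
  expect_equal(compute_falff(mk(inband))$data[1], 1, tolerance = 1e-8)
  expect_equal(compute_falff(mk(outband))$data[1], 0, tolerance = 1e-8)
  set.seed(4)
  x <- rnorm(40)
  f1 <- compute_falff(mk(x))$data[1]
  expect_equal(compute_falff(mk(5 * x))$data[1], f1, tolerance = 1e-12)
  expect_gte(f1, 0); expect_lte(f1, 1)
})

test_that("an empty band on the frequency grid is an informative error", {
  run <- toy_run(c(2, 2, 2), n = 20, tr = 0.05, seed = 1)
  p <- measure_params(band = c(0.01, 0.1))
  # TR 0.05s, n 20: lowest positive frequency 1 Hz, band has no bins
  expect_error(compute_alff(run, p), "TR")
})

# --- degree centrality -------------------------------------------------

test_that("degree centrality matches the dense correlation oracle", {
  run <- toy_run(c(5, 1, 1), n = 30, seed = 10)
  p <- measure_params(r_threshold = 0.25)
  got <- compute_degree_centrality(run, p)
  r <- cor(t(series_matrix(run)))
  diag(r) <- 0
  ora <- rowSums(r * (r > 0.25))
  expect_equal(as.vector(got$data), ora, tolerance = 1e-10)
})

test_that("identical voxels connect, independent ones do not, r_thr 1 empties", {
  set.seed(11)
  base <- rnorm(50)
  m <- rbind(base, base, rnorm(50))
  mask <- array(TRUE, c(3, 1, 1))
  run <- run_from_series(m, c(3, 1, 1), mask = mask)
  dc <- compute_degree_centrality(run, measure_params(r_threshold = 0.25))
  expect_equal(dc$data[1, 1, 1], 1, tolerance = 0.3)
  expect_equal(dc$data[2, 1, 1], dc$data[1, 1, 1], tolerance = 1e-10)
  expect_lt(dc$data[3, 1, 1], 0.3)
  dc1 <- compute_degree_centrality(run, measure_params(r_threshold = 1))
  expect_true(all(dc1$data == 0))
})

test_that("blocked degree centrality equals the unblocked computation", {
  run <- toy_run(c(4, 4, 3), n = 25, seed = 12)
  a <- compute_degree_centrality(run, block = 7L)
  b <- compute_degree_centrality(run, block = 4096L)
  expect_identical(a$data, b$data)
})

# --- eigenvector centrality -------------------------------------------

test_that("eigenvector centrality matches a dense eigendecomposition", {
  run <- toy_run(c(4, 1, 1), n = 40, seed = 13)
  got <- compute_eigenvector_centrality(run)
  a <- (1 + cor(t(series_matrix(run)))) / 2
  ev <- eigen(a, symmetric = TRUE)$vectors[, 1]
  if (sum(ev) < 0) ev <- -ev
  expect_equal(as.vector(got$data), ev, tolerance = 1e-5)
})

test_that("a rank-one similarity gives the uniform unit vector", {
  base <- sin(seq(0, 8, length.out = 30))
  m <- matrix(rep(base, 8), 8, byrow = TRUE)
  run <- run_from_series(m, c(2, 2, 2), mask = array(TRUE, c(2, 2, 2)))
  got <- compute_eigenvector_centrality(run)
  expect_equal(as.vector(got$data), rep(1 / sqrt(8), 8), tolerance = 1e-5)
})

test_that("eigenvector centrality is permutation-equivariant and unit-norm", {
  run <- toy_run(c(3, 3, 1), n = 30, seed = 14)
  got <- compute_eigenvector_centrality(run)
  expect_equal(sum(got$data^2), 1, tolerance = 1e-8)
  expect_true(all(got$data >= 0))
  # permute voxel series: the map permutes with them
  perm <- sample(9)
  m <- series_matrix(run)[perm, ]
  run2 <- run_from_series(m, c(3, 3, 1), mask = run$brain_mask,
                          subject_id = "p")
  got2 <- compute_eigenvector_centrality(run2)
  expect_equal(as.vector(got2$data), as.vector(got$data)[perm],
               tolerance = 1e-4)
})

# --- LFCD --------------------------------------------------------------

# breadth-first growth oracle, written against the contract directly
oracle_lfcd <- function(run, thr, connectivity = 26) {
  d <- run$grid_shape
  m <- series_matrix(run)
  v <- prod(d)
  coords <- arrayInd(seq_len(v), d)
  nb_of <- function(i) {
    dd <- abs(sweep(coords, 2, coords[i, ], "-"))
    ok <- apply(dd, 1, max) == 1 & rowSums(dd) > 0
    if (connectivity == 6) ok <- ok & rowSums(dd) == 1
    which(ok & as.vector(run$brain_mask))
  }
  out <- numeric(v)
  for (seed in which(as.vector(run$brain_mask))) {
    if (sd(m[seed, ]) == 0) next
    admitted <- integer(); frontier <- seed; seen <- seed
    repeat {
      cand <- setdiff(unique(unlist(lapply(frontier, nb_of))), seen)
      if (!length(cand)) break
      seen <- c(seen, cand)
      rs <- vapply(cand, function(u) {
        if (sd(m[u, ]) == 0) return(0)
        cor(m[seed, ], m[u, ])
      }, 0)
      good <- cand[rs > thr]
      admitted <- c(admitted, good)
      frontier <- good
    }
    out[seed] <- sum(vapply(admitted, function(u) cor(m[seed, ], m[u, ]), 0))
  }
  array(out, d)
}

test_that("LFCD matches the breadth-first growth oracle on a 4^3 toy", {
  run <- toy_run(c(4, 4, 4), n = 30, seed = 15)
  p <- measure_params(r_threshold = 0.25)
  expect_equal(compute_lfcd(run, p)$data, oracle_lfcd(run, 0.25),
               tolerance = 1e-10)
  p6 <- measure_params(r_threshold = 0.25, lfcd_connectivity = 6)
  expect_equal(compute_lfcd(run, p6)$data, oracle_lfcd(run, 0.25, 6),
               tolerance = 1e-10)
})

test_that("LFCD accumulates seed correlations along a connected chain", {
  d <- c(4, 1, 1); n <- 60
  set.seed(16)
  s <- rnorm(n)
  m <- rbind(s,                        # seed at (1,1,1)
             s + 0.01 * rnorm(n),      # face neighbor, r ~ 1
             s + 0.45 * rnorm(n),      # neighbor's neighbor, r ~ 0.9
             rnorm(n))                 # far voxel, noise
  run <- run_from_series(m, d, mask = array(TRUE, d))
  p <- measure_params(r_threshold = 0.25)
  got <- compute_lfcd(run, p)$data[1, 1, 1]
  r12 <- cor(m[1, ], m[2, ]); r13 <- cor(m[1, ], m[3, ])
  expect_equal(got, r12 + r13, tolerance = 1e-10)
})

test_that("high thresholds and spatial disconnection block admission", {
  run <- toy_run(c(3, 3, 3), n = 50, seed = 17)
  p <- measure_params(r_threshold = 0.9)
  expect_true(all(compute_lfcd(run, p)$data < 0.5))
  # a highly correlated but spatially disconnected voxel never contributes
  d <- c(5, 1, 1); n <- 40
  set.seed(18)
  s <- rnorm(n)
  m <- rbind(s, rnorm(n), rnorm(n), rnorm(n), s + 0.01 * rnorm(n))
  mask <- array(TRUE, d); mask[3, 1, 1] <- FALSE  # break the chain
  run2 <- run_from_series(m, d, mask = mask)
  got <- compute_lfcd(run2, measure_params(r_threshold = 0.25))$data[1, 1, 1]
  expect_lt(got, cor(m[1, ], m[5, ]))  # the mirror twin was unreachable
})

# --- entropy -----------------------------------------------------------

oracle_entropy <- function(x, bins) {
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  cut_id <- pmin(floor((x - rng[1]) / diff(rng) * bins) + 1, bins)
  p <- as.vector(table(factor(cut_id, levels = 1:bins))) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

test_that("histogram entropy hits its bounds and matches the count oracle", {
  d <- c(2, 2, 2)
  mk <- function(x) run_from_series(matrix(rep(x, 8), 8, byrow = TRUE), d,
                                    mask = array(TRUE, d))
  expect_equal(compute_entropy(mk(rep(1, 32)))$data[1], 0)
  bins <- 8
  filled <- rep(seq(0, 1, length.out = bins), each = 4)
  got <- compute_entropy(mk(filled), measure_params(entropy_bins = bins))
  expect_equal(got$data[1], log(bins), tolerance = 1e-10)
  set.seed(19)
  x <- rnorm(100)
  got2 <- compute_entropy(mk(x), measure_params(entropy_bins = 32))
  expect_equal(got2$data[1], oracle_entropy(x, 32), tolerance = 1e-10)
  expect_error(measure_params(entropy_bins = 1), "at least 2")
})

test_that("entropy is shift-invariant", {
  run <- toy_run(c(3, 3, 3), n = 50, seed = 20)
  e1 <- compute_entropy(run)$data
  run2 <- run; run2$data <- run$data + 100
  expect_equal(compute_entropy(run2)$data, e1, tolerance = 1e-10)
})

# --- VMHC --------------------------------------------------------------

test_that("a mirror-symmetric brain has VMHC 1 and the map self-mirrors", {
  d <- c(6, 3, 3); n <- 40
  set.seed(21)
  half <- array(rnorm(3 * 3 * 3 * n), c(3, 3, 3, n))
  arr <- array(0, c(d, n))
  arr[1:3, , , ] <- half
  arr[6:4, , , ] <- half          # exact mirrored copy
  run <- bold_run("s", arr, tr = 2, min_timepoints = 8)
  vm <- compute_vmhc(run)
  expect_true(all(abs(vm$data[run$brain_mask] - 1) < 1e-10))
  # generic map equals its own mirror
  run2 <- toy_run(c(6, 3, 3), n = 40, seed = 22)
  vm2 <- compute_vmhc(run2)$data
  expect_equal(vm2, vm2[6:1, , ])
})

test_that("independent hemispheres give VMHC centered at zero", {
  set.seed(23)
  vals <- replicate(40, {
    r <- toy_run(c(4, 2, 2), n = 60, seed = sample.int(1e6, 1))
    compute_vmhc(r)$data[r$brain_mask]
  })
  expect_lt(abs(mean(vals)), 0.05)
  expect_lt(mean(abs(vals)), 0.25)
})

test_that("VMHC also matches a direct per-voxel correlation oracle", {
  run <- toy_run(c(4, 3, 2), n = 30, seed = 24)
  vm <- compute_vmhc(run)$data
  m <- series_matrix(run)
  d <- run$grid_shape
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    mi <- d[1] + 1 - i
    expect_equal(vm[i, j, k], cor(m[(k - 1) * 12 + (j - 1) * 4 + i, ],
                                  m[(k - 1) * 12 + (j - 1) * 4 + mi, ]),
                 tolerance = 1e-10)
  }
})

# --- autocorrelation ---------------------------------------------------

test_that("lag autocorrelation spans anti-persistence to persistence", {
  d <- c(2, 2, 2)
  mk <- function(x) run_from_series(matrix(rep(x, 8), 8, byrow = TRUE), d,
                                    mask = array(TRUE, d))
  alt <- rep(c(1, -1), 25)
  expect_equal(compute_autocorr(mk(alt))$data[1], -1, tolerance = 1e-10)
  ramp <- seq_len(100)
  expect_gte(compute_autocorr(mk(ramp))$data[1], 0.99)
  set.seed(25)
  ar <- as.vector(stats::filter(rnorm(500), 0.6, method = "recursive"))
  expect_equal(compute_autocorr(mk(ar))$data[1], 0.6, tolerance = 0.1)
  expect_error(compute_autocorr(mk(rnorm(10)),
                                measure_params(autocorr_lag = 9)),
               "lag")
})

test_that("the decorrelation-lag mode finds the 1/e crossing", {
  d <- c(2, 2, 2)
  set.seed(26)
  # white noise decorrelates immediately
  run <- run_from_series(matrix(rnorm(8 * 200), 8, 200), d,
                         mask = array(TRUE, d))
  got <- compute_autocorr(run, mode = "decorrelation_lag")
  expect_true(all(got$data[run$brain_mask] <= 2))
})

# --- compute_all and global properties ---------------------------------

test_that("compute_all returns the nine measures consistent with the parts", {
  run <- toy_run(c(4, 4, 4), n = 30, seed = 27)
  maps <- compute_all(run)
  expect_named(maps, measure_names())
  expect_equal(maps$reho$data, compute_reho(run)$data)
  expect_equal(maps$vmhc$data, compute_vmhc(run)$data)
  expect_equal(maps$alff$data, compute_alff(run)$data)
})

test_that("constant voxels are flagged to zero without crashing", {
  d <- c(3, 3, 3); n <- 30
  set.seed(28)
  m <- matrix(rnorm(27 * n), 27, n)
  m[14, ] <- 5                       # constant center voxel
  run <- run_from_series(m, d, mask = array(TRUE, d))
  maps <- compute_all(run)
  for (mm in measure_names()) {
    expect_true(all(is.finite(maps[[mm]]$data)), info = mm)
  }
  expect_equal(maps$reho$data[2, 2, 2], 0)
  expect_equal(maps$autocorr$data[2, 2, 2], 0)
})

test_that("range invariants hold across randomized runs", {
  set.seed(29)
  for (i in 1:25) {
    run <- toy_run(c(4, 4, 4), n = sample(16:40, 1), seed = 1000 + i)
    maps <- compute_all(run)
    msk <- run$brain_mask
    expect_true(all(maps$reho$data >= 0 & maps$reho$data <= 1))
    expect_true(all(maps$falff$data >= 0 & maps$falff$data <= 1))
    expect_true(all(maps$vmhc$data >= -1 & maps$vmhc$data <= 1))
    expect_true(all(maps$autocorr$data >= -1 & maps$autocorr$data <= 1))
    expect_true(all(maps$ec$data >= 0))
    expect_true(all(maps$lfcd$data >= 0))
    expect_true(all(maps$entropy$data >= 0))
    expect_equal(sum(maps$ec$data[msk]^2), 1, tolerance = 1e-6)
  }
})

test_that("scale-free measures ignore per-voxel positive affine rescaling", {
  run <- toy_run(c(4, 2, 2), n = 40, seed = 30)
  m <- series_matrix(run)
  slope <- runif(nrow(m), 0.5, 3)
  icept <- rnorm(nrow(m))
  run2 <- run_from_series(m * slope + icept, run$grid_shape,
                          mask = run$brain_mask, subject_id = "r")
  for (f in list(compute_falff, compute_vmhc,
                 compute_eigenvector_centrality, compute_autocorr)) {
    expect_equal(f(run2)$data, f(run)$data, tolerance = 1e-6)
  }
})
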