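#' Kendall's coefficient of concordance W
#'
#' Agreement among K rankings of n timepoints, the statistic underlying
#' regional homogeneity: each time series ranks the timepoints, and
#' \deqn{W = 12 S / (K^2 (n^3 - n)), \quad S = \sum_i (R_i - \bar R)^2,}
#' where \eqn{R_i} is the sum over series of the rank of timepoint i.
#' Ties receive mid-ranks; no tie correction is applied.
#'
#' @param series_set Numeric matrix with one column per series (n timepoints
#'   by K series), or a list of equal-length numeric vectors.
#' @return W in \[0, 1\]. If any series is constant the statistic is not
#'   defined and the contract value 0 is returned, with attribute
#'   `constant = TRUE`.
#' @export
#' @examples
#' s <- cbind(1:4, 1:4, 4:1)
#' kendalls_w(s) # 60/540
kendalls_w <- function(series_set) {
  if (is.list(series_set)) series_set <- do.call(cbind, series_set)
  n <- nrow(series_set); k <- ncol(series_set)
  if (k < 2L) abort("need at least 2 series")
  if (n < 3L) abort("need at least 3 timepoints")
  rng <- matrixwise_var(t(series_set))
  if (any(rng == 0)) return(structure(0, constant = TRUE))
  rk <- apply(series_set, 2L, rank)
  ri <- rowSums(rk)
  s <- sum((ri - mean(ri))^2)
  12 * s / (k^2 * (n^3 - n))
}

# offsets of the 7/19/27 neighborhood, including the center voxel
neighborhood_offsets <- function(size) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  switch(as.character(size),
         "7"  = g[rowSums(abs(g)) <= 1L, , drop = FALSE],
         "19" = g[rowSums(abs(g)) <= 2L, , drop = FALSE],
         "27" = g,
         abort("neighborhood must be 7, 19 or 27"))
}

# add the +1/-1 shifts of `a` along one spatial axis to `a` itself
# (zero-padded); works for 3D and 4D arrays
box_shift_add <- function(a, axis) {
  d <- dim(a)[axis]
  out <- a
  lo <- 1:(d - 1); hi <- 2:d
  if (length(dim(a)) == 3L) {
    switch(axis,
           { out[lo, , ] <- out[lo, , ] + a[hi, , ]
             out[hi, , ] <- out[hi, , ] + a[lo, , ] },
           { out[, lo, ] <- out[, lo, ] + a[, hi, ]
             out[, hi, ] <- out[, hi, ] + a[, lo, ] },
           { out[, , lo] <- out[, , lo] + a[, , hi]
             out[, , hi] <- out[, , hi] + a[, , lo] })
  } else {
    switch(axis,
           { out[lo, , , ] <- out[lo, , , ] + a[hi, , , ]
             out[hi, , , ] <- out[hi, , , ] + a[lo, , , ] },
           { out[, lo, , ] <- out[, lo, , ] + a[, hi, , ]
             out[, hi, , ] <- out[, hi, , ] + a[, lo, , ] },
           { out[, , lo, ] <- out[, , lo, ] + a[, , hi, ]
             out[, , hi, ] <- out[, , hi, ] + a[, , lo, ] })
  }
  out
}

# sum of an array over the full 27-voxel box neighborhood (separable:
# three axis-wise passes)
box_sum <- function(a) {
  box_shift_add(box_shift_add(box_shift_add(a, 1L), 2L), 3L)
}

# shift a 3D or 4D array spatially by (dx,dy,dz), zero-padding the border
shift_spatial <- function(arr, off) {
  d <- dim(arr)
  out <- array(0, d)
  src <- dst <- vector("list", length(d))
  for (a in 1:3) {
    lo <- max(1L, 1L - off[a]); hi <- min(d[a], d[a] - off[a])
    if (lo > hi) return(out)
    src[[a]] <- lo:hi
    dst[[a]] <- (lo + off[a]):(hi + off[a])
  }
  if (length(d) == 3L) {
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  } else {
    out[dst[[1]], dst[[2]], dst[[3]], ] <- arr[src[[1]], src[[2]], src[[3]], ]
  }
  out
}

#' Regional homogeneity (ReHo)
#'
#' Kendall's W between each in-mask voxel's time series and those of its
#' spatial neighbors (neighborhood of 7, 19 or 27 voxels including the
#' center). Edge voxels use the neighbors available inside the grid and
#' mask. Voxels whose neighborhood contains a constant series, or with
#' fewer than two usable series, get 0.
#'
#' @param run A [bold_run()].
#' @param params A [measure_params()].
#' @return A [summary_volume()] with values in \[0, 1\], 0 outside the mask.
#' @export
compute_reho <- function(run, params = measure_params()) {
  d <- run$grid_shape; n <- dim(run$data)[4]; v <- prod(d)
  mat <- matrix(run$data, v, n)
  maskv <- as.vector(run$brain_mask)
  const <- matrixwise_var(mat) == 0
  usable <- maskv & !const
  rk <- matrix(0, v, n)
  if (any(usable)) {
    rk[usable, ] <- t(apply(mat[usable, , drop = FALSE], 1L, rank))
  }
  rk_arr <- array(rk, c(d, n))
  use_arr <- array(as.numeric(usable), d)
  bad_arr <- array(as.numeric(maskv & const), d)
  if (params$reho_neighborhood == 27L) {
    # the full-box neighborhood sum is separable along the axes
    rsum <- box_sum(rk_arr)
    kcnt <- box_sum(use_arr)
    bcnt <- box_sum(bad_arr)
  } else {
    offs <- neighborhood_offsets(params$reho_neighborhood)
    rsum <- array(0, c(d, n)); kcnt <- array(0, d); bcnt <- array(0, d)
    for (i in seq_len(nrow(offs))) {
      o <- offs[i, ]
      rsum <- rsum + shift_spatial(rk_arr, o)
      kcnt <- kcnt + shift_spatial(use_arr, o)
      bcnt <- bcnt + shift_spatial(bad_arr, o)
    }
  }
  kv <- as.vector(kcnt)
  rmat <- matrix(rsum, v, n)
  s <- rowSums((rmat - kv * (n + 1) / 2)^2)
  denom <- kv^2 * (n^3 - n)
  w <- ifelse(denom > 0, 12 * s / denom, 0)
  w[!maskv | as.vector(bcnt) > 0 | kv < 2 | const] <- 0
  summary_volume(run$subject_id, "reho", array(w, d),
                 list(neighborhood = params$reho_neighborhood))
}

#' One-sided amplitude spectrum of a time series
#'
#' Frequencies `k / (n * tr)` for `k = 1, ..., floor(n/2)` (DC excluded)
#' with amplitudes defined as the square root of the periodogram power,
#' `|X_k| / sqrt(n)` for the discrete Fourier transform `X`.
#'
#' @param series Numeric vector, length at least 8.
#' @param tr Sampling interval in seconds.
#' @param detrend Remove a linear trend first.
#' @return A list with `freqs` (Hz) and `amplitudes`.
#' @export
amplitude_spectrum <- function(series, tr, detrend = FALSE) {
  n <- length(series)
  if (n < 8L) abort("need at least 8 timepoints for a spectrum")
  if (detrend) series <- detrend_linear(series)
  f <- fft(series)
  k <- seq_len(n %/% 2)
  list(freqs = k / (n * tr), amplitudes = Mod(f)[k + 1L] / sqrt(n))
}

detrend_linear <- function(x) {
  t <- seq_along(x)
  stats::residuals(stats::lm.fit(cbind(1, t), x))
}

# voxelwise one-sided amplitude matrix (bins x voxels) for a run
run_spectrum <- function(run, detrend = FALSE) {
  d <- run$grid_shape; n <- dim(run$data)[4]
  x <- t(matrix(run$data, prod(d), n))           # n x V
  if (detrend) x <- apply(x, 2L, detrend_linear)
  f <- stats::mvfft(x)
  k <- seq_len(n %/% 2)
  list(freqs = k / (n * run$tr), amp = Mod(f[k + 1L, , drop = FALSE]) / sqrt(n))
}

band_bins <- function(freqs, band, tr, n) {
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel) == 0L) {
    abort(sprintf(
      "band %.3f-%.3f Hz contains no frequency bins for TR=%.3fs, n=%d",
      band[1], band[2], tr, n))
  }
  sel
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Sum of one-sided amplitude-spectrum values over the low-frequency band
#' (default 0.01--0.1 Hz), per voxel. DC is excluded; no detrending or
#' windowing is applied unless requested via `params$detrend`.
#'
#' @inheritParams compute_reho
#' @return A [summary_volume()], 0 outside the mask.
#' @export
compute_alff <- function(run, params = measure_params()) {
  sp <- run_spectrum(run, params$detrend)
  sel <- band_bins(sp$freqs, params$band, run$tr, dim(run$data)[4])
  a <- colSums(sp$amp[sel, , drop = FALSE])
  a[!as.vector(run$brain_mask)] <- 0
  summary_volume(run$subject_id, "alff", array(a, run$grid_shape),
                 list(band = params$band))
}

#' Fractional ALFF (fALFF)
#'
#' Band amplitude sum divided by the total amplitude sum over all positive
#' frequency bins; a voxel with no spectral energy (0/0) gets 0. Bounded in
#' \[0, 1\] and invariant to amplitude rescaling.
#'
#' @inheritParams compute_reho
#' @return A [summary_volume()] with values in \[0, 1\].
#' @export
compute_falff <- function(run, params = measure_params()) {
  sp <- run_spectrum(run, params$detrend)
  sel <- band_bins(sp$freqs, params$band, run$tr, dim(run$data)[4])
  num <- colSums(sp$amp[sel, , drop = FALSE])
  den <- colSums(sp$amp)
  r <- ifelse(den > 0, num / den, 0)
  r[!as.vector(run$brain_mask)] <- 0
  summary_volume(run$subject_id, "falff", array(r, run$grid_shape),
                 list(band = params$band))
}

# standardized voxel matrix: columns have zero mean and unit Euclidean norm,
# so crossprod() yields Pearson correlations; constant voxels become zero
# columns (correlation contract value 0)
standardized_series <- function(run, voxels = NULL) {
  d <- run$grid_shape; n <- dim(run$data)[4]
  m <- matrix(run$data, prod(d), n)
  if (!is.null(voxels)) m <- m[voxels, , drop = FALSE]
  m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(m^2))
  m[nrm > 0, ] <- m[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
  m[nrm == 0, ] <- 0
  t(m)                                          # n x V, unit-norm columns
}

#' Weighted degree centrality
#'
#' For each in-mask voxel, the sum of Pearson correlations with every other
#' in-mask voxel exceeding the threshold `r_threshold` (positive edges
#' only). Computation streams over voxel blocks so memory stays bounded;
#' the result is identical to the dense computation.
#'
#' @inheritParams compute_reho
#' @param block Number of voxels per correlation block.
#' @return A [summary_volume()] with nonnegative values.
#' @export
compute_degree_centrality <- function(run, params = measure_params(),
                                      block = 2048L) {
  maskv <- which(run$brain_mask)
  if (length(maskv) < 2L) abort("degree centrality needs at least 2 in-mask voxels")
  z <- standardized_series(run, maskv)
  nonconst <- colSums(z^2) > 0
  vv <- length(maskv)
  dc <- numeric(vv)
  thr <- params$r_threshold
  for (st in seq(1L, vv, by = block)) {
    en <- min(st + block - 1L, vv)
    r <- crossprod(z, z[, st:en, drop = FALSE])   # vv x b
    r[r <= thr] <- 0
    dc[st:en] <- colSums(r)
  }
  dc <- dc - as.numeric(nonconst) * (1 > thr)     # remove self-edge r = 1
  out <- numeric(prod(run$grid_shape))
  out[maskv] <- pmax(dc, 0)
  summary_volume(run$subject_id, "dc", array(out, run$grid_shape),
                 list(r_threshold = thr))
}

#' Weighted eigenvector centrality
#'
#' Leading eigenvector of the nonnegative similarity matrix
#' \eqn{A = (1 + r)/2} over in-mask voxels, computed matrix-free by power
#' iteration (the Perron-Frobenius eigenvector of a nonnegative matrix),
#' normalized to unit Euclidean norm and oriented nonnegative.
#'
#' @inheritParams compute_reho
#' @param tol Convergence tolerance (infinity norm of successive normalized
#'   iterates). Default 1e-6.
#' @param max_iter Iteration cap; exceeding it is an error reporting an
#'   eigengap estimate.
#' @return A [summary_volume()] with unit-norm nonnegative in-mask values.
#' @export
compute_eigenvector_centrality <- function(run, params = measure_params(),
                                           tol = 1e-6, max_iter = 1000L) {
  maskv <- which(run$brain_mask)
  if (length(maskv) < 2L) abort("eigenvector centrality needs at least 2 in-mask voxels")
  z <- standardized_series(run, maskv)
  vv <- length(maskv)
  v0 <- rep(1 / sqrt(vv), vv)
  amul <- function(v) 0.5 * (sum(v) + as.vector(crossprod(z, z %*% v)))
  v <- v0
  lam <- NA_real_
  for (it in seq_len(max_iter)) {
    av <- amul(v)
    lam <- sqrt(sum(av^2))
    vn <- av / lam
    if (max(abs(vn - v)) < tol) { v <- vn; break }
    v <- vn
    if (it == max_iter) {
      av2 <- amul(v)
      abort(sprintf(
        "power iteration did not converge in %d steps (Rayleigh quotient %.6g, residual %.3g); eigengap likely tiny",
        max_iter, sum(v * av2), max(abs(av2 / sqrt(sum(av2^2)) - v))))
    }
  }
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v <- v / sqrt(sum(v^2))
  out <- numeric(prod(run$grid_shape))
  out[maskv] <- v
  summary_volume(run$subject_id, "ec", array(out, run$grid_shape),
                 list(tol = tol))
}

# neighbor linear indices for every voxel under 6/26 connectivity
spatial_neighbors <- function(grid, connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  coords <- arrayInd(seq_len(prod(grid)), grid)
  lapply(seq_len(nrow(g)), function(i) {
    nb <- sweep(coords, 2L, g[i, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= grid[1] &
      nb[, 2] >= 1 & nb[, 2] <= grid[2] &
      nb[, 3] >= 1 & nb[, 3] <= grid[3]
    idx <- rep(NA_integer_, prod(grid))
    idx[ok] <- (nb[ok, 3] - 1L) * grid[1] * grid[2] +
      (nb[ok, 2] - 1L) * grid[1] + nb[ok, 1]
    idx
  })
}

#' Local functional connectivity density (weighted)
#'
#' For each in-mask seed voxel, grow a spatially connected cluster outward
#' from the seed (6- or 26-connectivity): a voxel joins the cluster when it
#' is a spatial neighbor of an already-admitted voxel (or the seed) and its
#' correlation with the *seed* exceeds `r_threshold`. The map value is the
#' sum of seed correlations over admitted voxels, seed excluded. The
#' admitted set is by construction a connected component containing the
#' seed: spatially disconnected voxels never contribute, however correlated.
#'
#' @inheritParams compute_reho
#' @return A [summary_volume()] with nonnegative values.
#' @export
compute_lfcd <- function(run, params = measure_params()) {
  d <- run$grid_shape
  maskv <- as.vector(run$brain_mask)
  z <- standardized_series(run)                  # n x V, zero cols = constant
  nonconst <- colSums(z^2) > 0
  nbrs <- spatial_neighbors(d, params$lfcd_connectivity)
  nbr_mat <- do.call(cbind, nbrs)                # V x n_nbr
  v <- prod(d)
  out <- numeric(v)
  thr <- params$r_threshold
  stamp <- integer(v)
  for (seed in which(maskv & nonconst)) {
    zs <- z[, seed]
    acc <- 0
    stamp[seed] <- seed
    # breadth-first growth in waves: each wave's seed-correlations are
    # computed in one vectorized crossprod
    wave <- nbr_mat[seed, ]
    wave <- wave[!is.na(wave)]
    wave <- wave[maskv[wave] & stamp[wave] != seed]
    while (length(wave)) {
      stamp[wave] <- seed
      rs <- as.vector(crossprod(z[, wave, drop = FALSE], zs))
      hit <- rs > thr
      if (!any(hit)) break
      acc <- acc + sum(rs[hit])
      cand <- as.vector(nbr_mat[wave[hit], , drop = FALSE])
      cand <- unique(cand[!is.na(cand)])
      wave <- cand[maskv[cand] & stamp[cand] != seed]
    }
    out[seed] <- acc
  }
  summary_volume(run$subject_id, "lfcd", array(out, d),
                 list(r_threshold = thr,
                      connectivity = params$lfcd_connectivity))
}

#' Histogram Shannon entropy
#'
#' Per voxel, the Shannon entropy (natural log) of the histogram of the
#' voxel's values over `entropy_bins` equal-width bins spanning the voxel's
#' own range. Empty bins contribute 0; a constant voxel has entropy 0.
#' Maximum value is `log(entropy_bins)`.
#'
#' @inheritParams compute_reho
#' @return A [summary_volume()] with nonnegative values.
#' @export
compute_entropy <- function(run, params = measure_params()) {
  if (params$entropy_bins < 2L) abort("`entropy_bins` must be at least 2")
  d <- run$grid_shape; n <- dim(run$data)[4]
  m <- matrix(run$data, prod(d), n)
  maskv <- as.vector(run$brain_mask)
  b <- params$entropy_bins
  ent_one <- function(x) {
    rng <- range(x)
    if (rng[2] == rng[1]) return(0)
    bin <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * b) + 1L, b)
    p <- tabulate(bin, b) / length(x)
    p <- p[p > 0]
    -sum(p * log(p))
  }
  out <- numeric(prod(d))
  idx <- which(maskv)
  out[idx] <- apply(m[idx, , drop = FALSE], 1L, ent_one)
  summary_volume(run$subject_id, "entropy", array(out, d),
                 list(bins = b))
}

#' Voxel-mirrored homotopic connectivity (VMHC)
#'
#' Pearson correlation between each voxel's time series and that of its
#' left-right mirror counterpart: voxel (i, j, k) pairs with
#' (X - 1 - i, j, k) on the 0-based first axis. Voxels whose mirror falls
#' outside the mask, or where either series is constant, get 0. The map
#' equals its own mirror image.
#'
#' @inheritParams compute_reho
#' @return A [summary_volume()] with values in \[-1, 1\].
#' @export
compute_vmhc <- function(run, params = measure_params()) {
  d <- run$grid_shape
  z <- standardized_series(run)                  # n x V, unit-norm cols
  maskv <- as.vector(run$brain_mask)
  nonconst <- colSums(z^2) > 0
  mir <- as.vector(array(seq_len(prod(d)), d)[d[1]:1, , , drop = FALSE])
  r <- colSums(z * z[, mir, drop = FALSE])
  r[!maskv | !maskv[mir] | !nonconst | !nonconst[mir]] <- 0
  summary_volume(run$subject_id, "vmhc",
                 array(pmin(pmax(r, -1), 1), d), list())
}

#' Lag autocorrelation
#'
#' Pearson correlation between each voxel's series and its copy shifted by
#' `autocorr_lag` timepoints: high values mean the signal state persists.
#' With `mode = "decorrelation_lag"` the map instead holds the smallest lag
#' at which the autocorrelation falls below 1/e (an alternative reading of
#' an "autocorrelation lag" summary).
#'
#' @inheritParams compute_reho
#' @param mode `"lag_corr"` (default) or `"decorrelation_lag"`.
#' @param max_lag Search cap for the decorrelation-lag mode.
#' @return A [summary_volume()]; values in \[-1, 1\] for the default mode.
#' @export
compute_autocorr <- function(run, params = measure_params(),
                             mode = c("lag_corr", "decorrelation_lag"),
                             max_lag = 20L) {
  mode <- match.arg(mode)
  d <- run$grid_shape; n <- dim(run$data)[4]
  maskv <- as.vector(run$brain_mask)
  m <- matrix(run$data, prod(d), n)
  lag_r <- function(l) {
    if (l >= n - 2L) abort(sprintf("lag %d too large for %d timepoints", l, n))
    a <- m[, 1:(n - l), drop = FALSE]
    b <- m[, (1 + l):n, drop = FALSE]
    a <- a - rowMeans(a); b <- b - rowMeans(b)
    na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
    r <- rowSums(a * b)
    ok <- na > 0 & nb > 0
    r[ok] <- r[ok] / (na[ok] * nb[ok])
    r[!ok] <- 0
    pmin(pmax(r, -1), 1)
  }
  if (mode == "lag_corr") {
    r <- lag_r(params$autocorr_lag)
    r[!maskv] <- 0
    return(summary_volume(run$subject_id, "autocorr", array(r, d),
                          list(lag = params$autocorr_lag, mode = mode)))
  }
  out <- rep(as.numeric(max_lag), prod(d))
  remaining <- maskv
  for (l in seq_len(min(max_lag, n - 3L))) {
    r <- lag_r(l)
    hit <- remaining & r < exp(-1)
    out[hit] <- l
    remaining <- remaining & !hit
  }
  out[!maskv] <- 0
  summary_volume(run$subject_id, "autocorr", array(out, d),
                 list(mode = mode, max_lag = max_lag))
}

#' Compute all nine summary measures for a run
#'
#' @inheritParams compute_reho
#' @param measures Subset of [measure_names()] to compute; defaults to all
#'   nine.
#' @return Named list of [summary_volume()] objects keyed by measure name.
#' @export
#' @examples
#' run <- bold_run("s1", array(rnorm(5^3 * 100), c(5, 5, 5, 100)), tr = 2,
#'                 min_timepoints = 50)
#' maps <- compute_all(run, measures = c("alff", "vmhc"))
#' names(maps)
compute_all <- function(run, params = measure_params(),
                        measures = measure_names()) {
  stopifnot(all(measures %in% measure_names()))
  fns <- list(reho = compute_reho, alff = compute_alff,
              falff = compute_falff, dc = compute_degree_centrality,
              ec = compute_eigenvector_centrality, lfcd = compute_lfcd,
              entropy = compute_entropy,
              vmhc = function(r, p) compute_vmhc(r, p),
              autocorr = compute_autocorr)
  out <- lapply(measures, function(mm) {
    tryCatch(fns[[mm]](run, params),
             error = function(e) {
               abort(sprintf("measure '%s' failed for %s: %s",
                             mm, run$subject_id, conditionMessage(e)))
             })
  })
  setNames(out, measures)
}
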