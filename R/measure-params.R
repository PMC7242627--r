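#' Parameters controlling the nine summary measures
#'
#' Bundles every tunable setting of the voxel-wise summary measures. The
#' low-frequency band (0.01--0.1 Hz) is the conventional ALFF/fALFF band.
#' The remaining knobs are conventions of the connectivity literature rather
#' than physical constants; all are recorded in each output volume so a map
#' is self-describing.
#'
#' @param band Numeric length-2, low and high band edges in Hz. Must satisfy
#'   `0 < band[1] < band[2]`; the upper edge must not exceed the Nyquist
#'   frequency `1/(2 * tr)` of the run it is applied to.
#' @param reho_neighborhood Neighborhood size for regional homogeneity: 7
#'   (faces), 19 (faces + edges) or 27 (full cube). Default 27, the most
#'   common ReHo convention.
#' @param r_threshold Correlation threshold in (0, 1) for weighted degree
#'   centrality and LFCD edge admission; only positive correlations above
#'   this value count. Default 0.25 (the preprocessed-connectomes default).
#' @param lfcd_connectivity Spatial connectivity for LFCD cluster growth:
#'   6 (faces) or 26 (full cube). Default 26.
#' @param entropy_bins Number of equal-width histogram bins for the entropy
#'   map; must be at least 2. Default 32.
#' @param autocorr_lag Lag (in timepoints) for the autocorrelation map.
#'   Default 1. See [compute_autocorr()] for the decorrelation-lag mode.
#' @param detrend Logical; linearly detrend each series before the spectral
#'   measures. Off by default: detrending belongs to preprocessing.
#'
#' @return A list of class `measure_params`.
#' @export
#' @examples
#' p <- measure_params(entropy_bins = 16)
#' p$band
measure_params <- function(band = c(0.01, 0.1),
                           reho_neighborhood = 27,
                           r_threshold = 0.25,
                           lfcd_connectivity = 26,
                           entropy_bins = 32,
                           autocorr_lag = 1,
                           detrend = FALSE) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  if (!reho_neighborhood %in% c(7, 19, 27)) {
    abort("`reho_neighborhood` must be 7, 19 or 27")
  }
  if (!is.numeric(r_threshold) || r_threshold <= 0 || r_threshold > 1) {
    abort("`r_threshold` must lie in (0, 1]")
  }
  if (!lfcd_connectivity %in% c(6, 26)) {
    abort("`lfcd_connectivity` must be 6 or 26")
  }
  if (entropy_bins < 2) abort("`entropy_bins` must be at least 2")
  if (autocorr_lag < 1) abort("`autocorr_lag` must be a positive integer")
  structure(
    list(band = as.numeric(band),
         reho_neighborhood = as.integer(reho_neighborhood),
         r_threshold = as.numeric(r_threshold),
         lfcd_connectivity = as.integer(lfcd_connectivity),
         entropy_bins = as.integer(entropy_bins),
         autocorr_lag = as.integer(autocorr_lag),
         detrend = isTRUE(detrend)),
    class = "measure_params")
}

#' @export
print.measure_params <- function(x, ...) {
  cat("<measure_params>\n")
  cat(sprintf("  band: %.3f-%.3f Hz | ReHo nbhd: %d | r_thr: %.2f\n",
              x$band[1], x$band[2], x$reho_neighborhood, x$r_threshold))
  cat(sprintf("  LFCD connectivity: %d | entropy bins: %d | autocorr lag: %d | detrend: %s\n",
              x$lfcd_connectivity, x$entropy_bins, x$autocorr_lag, x$detrend))
  invisible(x)
}
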