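#' Names of the fingerprint features
#'
#' The canonical 11-dimensional IC fingerprint: four spatial features
#' (clustering, |skewness|, excess kurtosis, histogram entropy of the
#' z values), two temporal features (lag-1 autocorrelation, histogram
#' entropy of the timecourse), and five spectral power fractions in the
#' bands 0-0.008, 0.008-0.02, 0.02-0.05, 0.05-0.1 and 0.1-Nyquist Hz.
#'
#' @return Character vector of length 11.
#' @export
fingerprint_feature_names <- function() {
  c("clustering", "skewness", "kurtosis", "spatial_entropy",
    "temporal_autocorr", "temporal_entropy",
    "bp_very_low", "bp_low", "bp_mid", "bp_high", "bp_above")
}

#' Frequency bands of the fingerprint's spectral features
#' @param tr_s repetition time in seconds (fixes the Nyquist frequency).
#' @return List of `c(lo, hi)` half-open intervals in Hz; the last band
#'   closes at Nyquist.
#' @export
fingerprint_bands <- function(tr_s) {
  nyq <- 1 / (2 * tr_s)
  list(c(0, 0.008), c(0.008, 0.02), c(0.02, 0.05), c(0.05, 0.1), c(0.1, nyq))
}

# Shannon entropy (nats) of a 64-bin histogram of standardized values over
# mean +/- 4 SD; out-of-range values are clamped into the edge bins so the
# histogram always sums to 1. Empty bins contribute 0.
histogram_entropy <- function(x, n_bins = 64) {
  z <- (x - mean(x)) / sd(x)
  z <- pmin(pmax(z, -4 + 1e-12), 4 - 1e-12)
  counts <- tabulate(findInterval(z, seq(-4, 4, length.out = n_bins + 1),
                                  rightmost.closed = TRUE), nbins = n_bins)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Spectral power fractions per frequency band
#'
#' Discrete periodogram power summed per band and divided by the total power
#' over all nonzero frequencies up to Nyquist (the zero frequency is excluded
#' from the normalization: signals are detrended). Bands are half-open
#' `[lo, hi)`; a band whose upper edge reaches Nyquist is closed.
#'
#' @param timecourse numeric vector, length >= 4, non-constant.
#' @param tr_s repetition time in seconds.
#' @param bands_hz list of `c(lo, hi)` intervals within `[0, Nyquist]`.
#' @return Numeric vector of fractions in `[0, 1]`, one per band.
#' @export
band_power_fractions <- function(timecourse, tr_s,
                                 bands_hz = fingerprint_bands(tr_s)) {
  n <- length(timecourse)
  if (n < 4) stop("timecourse too short for a periodogram")
  if (sd(timecourse) < .Machine$double.eps) {
    stop("constant timecourse: band power normalization undefined")
  }
  nyq <- 1 / (2 * tr_s)
  for (b in bands_hz) {
    if (b[1] < 0 || b[2] > nyq + 1e-9 || b[2] <= b[1]) {
      stop("band [", b[1], ", ", b[2], "] Hz is not a valid interval within [0, ",
           signif(nyq, 6), "] Hz")
    }
  }
  x <- timecourse - mean(timecourse)
  pw <- Mod(fft(x))^2
  kmax <- floor(n / 2)
  freqs <- (1:kmax) / (n * tr_s)
  pw <- pw[2:(kmax + 1)]
  total <- sum(pw)
  vapply(bands_hz, function(b) {
    inband <- if (b[2] >= nyq - 1e-9) freqs >= b[1] & freqs <= b[2] + 1e-12
              else freqs >= b[1] & freqs < b[2]
    sum(pw[inband]) / total
  }, numeric(1))
}

#' Spatial clustering of a thresholded z-map
#'
#' Fraction of supra-threshold voxels (`|z| >= z_threshold`, inside the mask)
#' that have at least one supra-threshold 6-neighbor. Returns 0 when no voxel
#' is supra-threshold: high values mean contiguous activation patches, low
#' values scattered voxels.
#'
#' @param zmap a [volume3d()] of z-scores.
#' @param mask a [mask_volume()].
#' @param z_threshold threshold on `|z|`, default 2.
#' @return A scalar in `[0, 1]`.
#' @export
spatial_clustering <- function(zmap, mask, z_threshold = 2) {
  stopifnot(inherits(zmap, "volume3d"), inherits(mask, "mask_volume"))
  check_same_grid(zmap, mask)
  supra <- abs(zmap$data) >= z_threshold & mask$data == 1L
  n_supra <- sum(supra)
  if (n_supra == 0) return(0)
  d <- dim(supra)
  has_nb <- array(FALSE, d)
  shift_or <- function(acc, ax, by) {
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by > 0) { idx_dst[[ax]] <- (1 + by):d[ax]; idx_src[[ax]] <- 1:(d[ax] - by) }
    else { idx_dst[[ax]] <- 1:(d[ax] + by); idx_src[[ax]] <- (1 - by):d[ax] }
    acc[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      acc[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] |
      supra[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    acc
  }
  for (ax in 1:3) for (by in c(-1, 1)) has_nb <- shift_or(has_nb, ax, by)
  sum(supra & has_nb) / n_supra
}

#' Compute the spatio-temporal fingerprint of one component
#'
#' All features are invariant to flipping the component's sign (spatial
#' skewness is reported as an absolute value; histograms use symmetric bins
#' of standardized values) and to multiplying the timecourse by a positive
#' constant.
#'
#' @param zmap a [volume3d()] z-scored spatial map.
#' @param timecourse numeric vector (length >= 16).
#' @param mask a [mask_volume()] with >= 32 in-mask voxels.
#' @param tr_s repetition time in seconds.
#' @return An object of class `ic_fingerprint`: a named numeric vector with
#'   the 11 features of [fingerprint_feature_names()].
#' @export
compute_fingerprint <- function(zmap, timecourse, mask, tr_s) {
  stopifnot(inherits(zmap, "volume3d"), inherits(mask, "mask_volume"))
  if (length(timecourse) < 16) stop("timecourse must have at least 16 frames")
  if (sum(mask$data) < 32) stop("mask must contain at least 32 voxels")
  if (sd(timecourse) < .Machine$double.eps) {
    stop("constant timecourse: fingerprint spectrum undefined")
  }
  z <- zmap$data[mask$data == 1L]
  n <- length(timecourse)
  bp <- band_power_fractions(timecourse, tr_s)
  out <- c(
    clustering = spatial_clustering(zmap, mask),
    skewness = abs(e1071::skewness(z, type = 1)),
    kurtosis = e1071::kurtosis(z, type = 1),
    spatial_entropy = histogram_entropy(z),
    temporal_autocorr = cor(timecourse[-1], timecourse[-n]),
    temporal_entropy = histogram_entropy(timecourse),
    bp
  )
  names(out) <- fingerprint_feature_names()
  class(out) <- c("ic_fingerprint", "numeric")
  out
}

#' Fingerprints of every component in a decomposition
#'
#' @param decomposition an `ic_decomposition` from [decompose()].
#' @param subject_id optional identifier attached to every row.
#' @return A `data.frame` with `subject_id`, `component_index` and the 11
#'   feature columns, one row per component.
#' @export
fingerprint_table <- function(decomposition, subject_id = "subject") {
  rows <- lapply(seq_len(decomposition$n_components), function(i) {
    fp <- compute_fingerprint(decomposition$spatial_zmaps[[i]],
                              decomposition$timecourses[, i],
                              decomposition$mask, decomposition$tr_s)
    as.data.frame(as.list(unclass(fp)))
  })
  out <- do.call(rbind, rows)
  data.frame(subject_id = subject_id,
             component_index = seq_len(decomposition$n_components),
             out, check.names = FALSE, stringsAsFactors = FALSE)
}
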