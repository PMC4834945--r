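#' Specify a synthetic BOLD phantom
#'
#' The phantom emulates a resting-state acquisition: a handful of sparse
#' low-frequency "neuronal" sources mixed with high-frequency structured
#' artifacts concentrated on the brain boundary, plus Gaussian sensor noise.
#' Defaults mirror a typical 3T protocol (TR = 2 s, 300 frames, 3 mm voxels)
#' and the neuronal 0.01-0.1 Hz signature.
#'
#' @param grid_shape voxel counts per axis, default `c(20, 20, 12)`.
#' @param voxel_size_mm positive voxel edge lengths, default 3 mm isotropic.
#' @param n_frames number of time points, default 300.
#' @param tr_s repetition time in seconds, default 2.
#' @param n_neuronal number of neuronal sources (>= 1), default 4.
#' @param n_artifact number of artifact sources (>= 0), default 3.
#' @param neuronal_band_hz frequency interval of neuronal timecourses,
#'   default `c(0.01, 0.1)`.
#' @param artifact_band_hz frequency interval of artifact timecourses,
#'   default `c(0.15, 0.25)`.
#' @param sparsity fraction of in-brain voxels active per neuronal map,
#'   default 0.05.
#' @param noise_sd Gaussian sensor noise SD, default 0.5.
#' @param seed integer seed; all phantom randomness flows from it.
#' @return A validated object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(20, 20, 12), voxel_size_mm = c(3, 3, 3),
                         n_frames = 300, tr_s = 2, n_neuronal = 4, n_artifact = 3,
                         neuronal_band_hz = c(0.01, 0.1),
                         artifact_band_hz = c(0.15, 0.25),
                         sparsity = 0.05, noise_sd = 0.5, seed = 1) {
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    n_frames = as.integer(n_frames), tr_s = tr_s,
    n_neuronal = as.integer(n_neuronal), n_artifact = as.integer(n_artifact),
    neuronal_band_hz = neuronal_band_hz, artifact_band_hz = artifact_band_hz,
    sparsity = sparsity, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  fail <- function(field, why) stop("invalid phantom spec: `", field, "` ", why)
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 4)) {
    fail("grid_shape", "must be 3 positive counts (>= 4 voxels per axis)")
  }
  if (any(spec$voxel_size_mm <= 0)) fail("voxel_size_mm", "must be positive")
  if (spec$n_frames < 2) fail("n_frames", "must be >= 2")
  if (spec$tr_s <= 0) fail("tr_s", "must be positive")
  if (spec$n_neuronal < 1) fail("n_neuronal", "must be >= 1")
  if (spec$n_artifact < 0) fail("n_artifact", "must be >= 0")
  if (spec$neuronal_band_hz[1] <= 0 || diff(spec$neuronal_band_hz) <= 0) {
    fail("neuronal_band_hz", "must be an increasing interval above 0")
  }
  if (diff(spec$artifact_band_hz) <= 0) fail("artifact_band_hz", "must be increasing")
  nyq <- 1 / (2 * spec$tr_s)
  if (spec$artifact_band_hz[2] > nyq + 1e-12) {
    fail("artifact_band_hz", paste0("exceeds the Nyquist frequency ", nyq, " Hz"))
  }
  if (spec$n_frames < 2 / (spec$tr_s * spec$neuronal_band_hz[1])) {
    fail("n_frames", "too short to observe one full cycle of the slowest neuronal frequency")
  }
  if (spec$n_neuronal + spec$n_artifact >= spec$n_frames) {
    fail("n_neuronal", "+ n_artifact must be < n_frames")
  }
  if (spec$sparsity <= 0 || spec$sparsity >= 1) fail("sparsity", "must be in (0, 1)")
  if (spec$noise_sd < 0) fail("noise_sd", "must be >= 0")
  invisible(spec)
}

# Ellipsoid inscribed in the grid; returns logical arrays for the brain mask
# and its one-voxel-thick boundary shell (6-neighborhood).
phantom_geometry <- function(grid_shape) {
  d <- grid_shape
  ctr <- (d + 1) / 2
  semi <- (d - 1) / 2
  ix <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  iy <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  iz <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  r2 <- ((ix - ctr[1]) / semi[1])^2 + ((iy - ctr[2]) / semi[2])^2 +
    ((iz - ctr[3]) / semi[3])^2
  mask <- r2 <= 1
  shell <- mask & !erode6(mask)
  list(mask = mask, shell = shell, coords = cbind(as.vector(ix), as.vector(iy), as.vector(iz)))
}

# 6-neighborhood erosion: TRUE where the voxel and all face neighbors are in.
erode6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, ax, by) {
    r <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by > 0) { idx_dst[[ax]] <- (1 + by):d[ax]; idx_src[[ax]] <- 1:(d[ax] - by) }
    else { idx_dst[[ax]] <- 1:(d[ax] + by); idx_src[[ax]] <- (1 - by):d[ax] }
    r[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    r
  }
  for (ax in 1:3) for (by in c(-1, 1)) out <- out & shift(mask, ax, by)
  out
}

# Timecourse as a sum of 3-5 sinusoids whose frequencies sit on the discrete
# Fourier grid inside `band_hz` (on-grid frequencies keep spectral leakage
# out of the band-power contracts); standardized to mean 0, SD 1.
phantom_timecourse <- function(n_frames, tr_s, band_hz) {
  df <- 1 / (n_frames * tr_s)
  bins <- seq_len(floor(n_frames / 2))
  freqs <- bins * df
  ok <- which(freqs >= band_hz[1] & freqs <= band_hz[2])
  if (length(ok) == 0) stop("no Fourier bin inside the band [", band_hz[1], ", ", band_hz[2], "] Hz")
  k <- sample(3:5, 1)
  pick <- sample(ok, min(k, length(ok)), replace = length(ok) < k)
  t_s <- (seq_len(n_frames) - 1) * tr_s
  amp <- 1 + runif(length(pick), 0, 0.5)
  ph <- runif(length(pick), 0, 2 * pi)
  x <- rowSums(sapply(seq_along(pick), function(j) {
    amp[j] * sin(2 * pi * freqs[pick[j]] * t_s + ph[j])
  }))
  as.vector(scale(x))
}

#' Generate a synthetic phantom dataset
#'
#' Builds the BOLD 4-D volume as the outer-product mixture of the ground-truth
#' spatial maps and timecourses plus i.i.d. Gaussian noise, a gray-matter
#' probability map (0.9 inside the brain, 0.05 on the boundary shell, 0
#' outside), a metabolic surrogate defined as the 16-mm-smoothed voxelwise
#' sum of the square root of the absolute ground-truth neuronal maps (so the
#' pipeline's ideal output is known by construction), and a motion trace.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_dataset` with fields `bold`,
#'   `gm_probability`, `brain_mask`, `true_maps`, `true_timecourses`,
#'   `true_labels`, `metabolic_surrogate`, `motion_trace`, `spec`.
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    d <- spec$grid_shape
    geo <- phantom_geometry(d)
    interior <- geo$mask & !geo$shell
    n_inbrain <- sum(geo$mask)
    aff <- diag(c(spec$voxel_size_mm, 1))

    gm <- array(0, d)
    gm[interior] <- 0.9
    gm[geo$shell] <- 0.05

    k_active <- max(1L, round(spec$sparsity * n_inbrain))
    int_idx <- which(interior)
    coords <- geo$coords

    # Farthest-point sampling keeps the sparse sources well separated so
    # they are (near-)uncorrelated, as spatial ICA assumes.
    pick_spread <- function(pool_idx, n_pick) {
      picked <- pool_idx[sample.int(length(pool_idx), 1)]
      while (length(picked) < n_pick) {
        dmin <- rep(Inf, length(pool_idx))
        for (p in picked) {
          dp <- rowSums((coords[pool_idx, , drop = FALSE] -
                           matrix(coords[p, ], length(pool_idx), 3, byrow = TRUE))^2)
          dmin <- pmin(dmin, dp)
        }
        picked <- c(picked, pool_idx[which.max(dmin)])
      }
      picked
    }

    maps <- vector("list", spec$n_neuronal + spec$n_artifact)
    labels <- c(rep("neuronal", spec$n_neuronal), rep("artifact", spec$n_artifact))
    centers <- pick_spread(int_idx, spec$n_neuronal)
    for (i in seq_len(spec$n_neuronal)) {
      dist2 <- rowSums((coords[int_idx, , drop = FALSE] -
                          matrix(coords[centers[i], ], length(int_idx), 3, byrow = TRUE))^2)
      ord <- order(dist2)
      blob <- int_idx[ord][seq_len(min(k_active, length(int_idx)))]
      m <- array(0, d)
      r0 <- max(1, sqrt(max(dist2[ord][seq_along(blob)])))
      m[blob] <- 5 * exp(-0.5 * dist2[ord][seq_along(blob)] / r0^2)
      maps[[i]] <- m
    }
    # Artifacts: contiguous same-sign patches on the boundary shell,
    # mimicking motion/scalp artifacts ("patches of connected regions in
    # the scalp periphery").
    shell_idx <- which(geo$shell)
    if (spec$n_artifact > 0) {
      patch_frac <- min(0.4, 0.8 / spec$n_artifact)
      seeds <- pick_spread(shell_idx, spec$n_artifact)
      for (i in seq_len(spec$n_artifact)) {
        m <- array(0, d)
        dist2 <- rowSums((coords[shell_idx, , drop = FALSE] -
                            matrix(coords[seeds[i], ], length(shell_idx), 3, byrow = TRUE))^2)
        take <- shell_idx[order(dist2)][seq_len(max(2L, round(patch_frac * length(shell_idx))))]
        m[take] <- 3 + abs(rnorm(length(take)))
        maps[[spec$n_neuronal + i]] <- m
      }
    }

    tcs <- sapply(seq_along(maps), function(i) {
      band <- if (labels[i] == "neuronal") spec$neuronal_band_hz else spec$artifact_band_hz
      phantom_timecourse(spec$n_frames, spec$tr_s, band)
    })

    nvox <- prod(d)
    bold_mat <- matrix(0, nvox, spec$n_frames)
    for (i in seq_along(maps)) {
      bold_mat <- bold_mat + as.vector(maps[[i]]) %o% tcs[, i]
    }
    if (spec$noise_sd > 0) {
      bold_mat <- bold_mat + rnorm(length(bold_mat), sd = spec$noise_sd)
    }
    bold <- volume4d(array(bold_mat, c(d, spec$n_frames)), affine = aff, tr_s = spec$tr_s)

    # Metabolic surrogate: what the pipeline would produce from perfectly
    # recovered components — the smoothed voxelwise sum of sqrt(|z|) over
    # the z-scored ground-truth neuronal maps (z-scored over the brain
    # mask, exactly as ICA components are).
    brain_mask <- mask_volume(geo$mask * 1L, affine = aff)
    surro_raw <- Reduce(`+`, lapply(maps[labels == "neuronal"], function(m) {
      z <- zscore_spatial_map(volume3d(m, affine = aff), brain_mask)
      sqrt(abs(z$data))
    }))
    surro <- gaussian_smooth(volume3d(surro_raw, affine = aff), fwhm_mm = 16)

    structure(list(
      bold = bold,
      gm_probability = volume3d(gm, affine = aff),
      brain_mask = brain_mask,
      true_maps = lapply(maps, volume3d, affine = aff),
      true_timecourses = tcs,
      true_labels = labels,
      metabolic_surrogate = scalar_map(surro, subject_id = paste0("phantom", spec$seed),
                                       modality = "metabolic",
                                       processing = list(smooth_fwhm_mm = 16, scaled = FALSE)),
      motion_trace = make_motion_trace(spec$n_frames, "still", tr_s = spec$tr_s),
      spec = spec
    ), class = "phantom_dataset")
  })
}

#' Generate a labeled synthetic fingerprint corpus
#'
#' Emulates an expert-labeled training corpus of independent-component
#' fingerprints grouped by subject. Class-conditional feature distributions
#' are Gaussian around calibrated "neuronal" and "non-neuronal" fingerprint
#' prototypes; their means differ by `class_separation` standard-deviation
#' units (Mahalanobis distance under the per-feature noise SDs), and
#' "undefined" samples sit at the class midpoint with inflated variance.
#' With `geometry = "radial"` the two classes are instead separable only by
#' a nonlinear (radial) boundary, which a linear kernel cannot express.
#'
#' @param n_subjects number of subjects, default 19.
#' @param n_components_per_subject components per subject, default 30.
#' @param class_separation standardized distance between class means, >= 0.
#' @param label_fractions named or ordered triple of fractions for
#'   (neuronal, non_neuronal, undefined); must sum to 1. Defaults to the
#'   proportions 224:248:98.
#' @param seed integer seed.
#' @param geometry `"linear"` (default) or `"radial"`.
#' @return A `data.frame` (class `fingerprint_corpus`) with columns
#'   `subject_id`, `component_index`, `label` and the 11 fingerprint features.
#' @export
make_fingerprint_corpus <- function(n_subjects = 19, n_components_per_subject = 30,
                                    class_separation = 3,
                                    label_fractions = c(neuronal = 224, non_neuronal = 248,
                                                        undefined = 98) / 570,
                                    seed = 1, geometry = c("linear", "radial")) {
  geometry <- match.arg(geometry)
  if (abs(sum(label_fractions) - 1) > 1e-9) {
    stop("`label_fractions` must sum to 1 (got ", sum(label_fractions), ")")
  }
  if (class_separation < 0) stop("`class_separation` must be >= 0")
  n_total <- n_subjects * n_components_per_subject
  feats <- fingerprint_feature_names()
  p <- length(feats)

  with_seed(seed, {
    counts <- floor(label_fractions * n_total)
    rem <- n_total - sum(counts)
    if (rem > 0) {
      bump <- order(label_fractions * n_total - counts, decreasing = TRUE)[seq_len(rem)]
      counts[bump] <- counts[bump] + 1
    }
    labels <- sample(rep(c("neuronal", "non_neuronal", "undefined"), counts))

    proto <- corpus_prototypes()
    m0 <- (proto$neuronal + proto$non_neuronal) / 2
    half_gap <- (class_separation / 3) * (proto$neuronal - m0)
    sds <- proto$sds

    x <- matrix(0, n_total, p)
    if (geometry == "linear") {
      mu <- matrix(rep(m0, each = n_total), n_total, p)
      sgn <- ifelse(labels == "neuronal", 1, ifelse(labels == "non_neuronal", -1, 0))
      mu <- mu + sgn %o% half_gap
      noise_sd <- ifelse(labels == "undefined", 1.5, 1)
      x <- mu + matrix(rnorm(n_total * p), n_total, p) *
        (noise_sd %o% sds)
    } else {
      # Radial geometry: neuronal samples cluster at the origin of the
      # standardized feature space, non-neuronal samples on a shell of
      # radius `class_separation`; anchored at the midpoint prototype.
      z <- matrix(rnorm(n_total * p), n_total, p)
      u <- z / sqrt(rowSums(z^2))
      r <- ifelse(labels == "neuronal", abs(rnorm(n_total, 0, 0.5)),
                  ifelse(labels == "non_neuronal", rnorm(n_total, class_separation, 0.3),
                         rnorm(n_total, class_separation / 2, 0.3)))
      x <- matrix(rep(m0, each = n_total), n_total, p) + (u * r) *
        matrix(rep(sds, each = n_total), n_total, p)
    }

    subj <- rep(sprintf("S%02d", seq_len(n_subjects)), each = n_components_per_subject)
    subj_shift <- matrix(rnorm(n_subjects * p, sd = 0.25), n_subjects, p) *
      matrix(rep(sds, each = n_subjects), n_subjects, p)
    x <- x + subj_shift[rep(seq_len(n_subjects), each = n_components_per_subject), ]

    colnames(x) <- feats
    out <- data.frame(subject_id = subj,
                      component_index = rep(seq_len(n_components_per_subject), n_subjects),
                      label = labels, x, check.names = FALSE,
                      stringsAsFactors = FALSE)
    class(out) <- c("fingerprint_corpus", "data.frame")
    out
  })
}

# Fingerprint prototypes for the two component classes, calibrated once
# against fingerprints measured on phantom-generated neuronal and artifact
# components (TR 2 s): neuronal sources are sparse, spatially clustered,
# heavy-tailed, slow (0.01-0.1 Hz, high lag-1 autocorrelation); artifacts are
# boundary-shell patterns dominated by 0.15-0.25 Hz power (negative lag-1
# autocorrelation at TR = 2 s).
corpus_prototypes <- function() {
  feats <- fingerprint_feature_names()
  neuronal <- c(clustering = 1.0, skewness = 3.8, kurtosis = 15.6, spatial_entropy = 1.75,
                temporal_autocorr = 0.74, temporal_entropy = 3.42,
                bp_very_low = 0.0, bp_low = 0.14, bp_mid = 0.49, bp_high = 0.31,
                bp_above = 0.05)
  non_neuronal <- c(clustering = 1.0, skewness = 1.8, kurtosis = 2.2, spatial_entropy = 2.4,
                    temporal_autocorr = -0.63, temporal_entropy = 3.42,
                    bp_very_low = 0.0, bp_low = 0.005, bp_mid = 0.02, bp_high = 0.015,
                    bp_above = 0.96)
  gap_true <- neuronal - non_neuronal
  gap <- abs(gap_true)
  gap[gap < 1e-3] <- median(gap) # non-discriminative features keep realistic spread
  # Per-feature SDs proportional to the prototype gap, rescaled so the
  # standardized class-mean distance is exactly 3 at the calibration point.
  sds <- gap * sqrt(length(feats)) / 3
  sds <- sds * sqrt(sum((gap_true / sds)^2)) / 3
  names(neuronal) <- names(non_neuronal) <- names(sds) <- feats
  list(neuronal = neuronal, non_neuronal = non_neuronal, sds = sds)
}

#' Generate a rigid-body motion trace
#'
#' @param n_frames number of frames (>= 2).
#' @param pattern `"still"` (all zeros), `"drift"` (linear translation of
#'   `magnitude_mm` per frame along x) or `"jump"` (a single step of
#'   `magnitude_mm` along x at the midpoint frame).
#' @param magnitude_mm drift rate (mm/frame) or jump size (mm).
#' @param tr_s repetition time carried with the trace.
#' @param seed unused for the deterministic patterns; accepted for interface
#'   uniformity.
#' @return An object of class `motion_trace` with `translations_mm`
#'   (n x 3), `rotations_rad` (n x 3) and `tr_s`.
#' @export
make_motion_trace <- function(n_frames, pattern = c("still", "drift", "jump"),
                              magnitude_mm = 0.1, tr_s = 2, seed = NULL) {
  pattern <- match.arg(pattern)
  if (n_frames < 2) stop("`n_frames` must be >= 2")
  tx <- switch(pattern,
    still = rep(0, n_frames),
    drift = (seq_len(n_frames) - 1) * magnitude_mm,
    jump = c(rep(0, floor(n_frames / 2)), rep(magnitude_mm, n_frames - floor(n_frames / 2)))
  )
  structure(list(
    translations_mm = cbind(x = tx, y = rep(0, n_frames), z = rep(0, n_frames)),
    rotations_rad = matrix(0, n_frames, 3, dimnames = list(NULL, c("rx", "ry", "rz"))),
    tr_s = tr_s
  ), class = "motion_trace")
}

#' Read / write a motion trace as a 6-column text table
#'
#' Plain whitespace-separated text, one row per frame: three translations in
#' millimetres then three rotations in radians.
#'
#' @param path file path.
#' @param tr_s repetition time to attach on read.
#' @return [read_motion_trace()] returns a `motion_trace`;
#'   [write_motion_trace()] returns `path` invisibly.
#' @export
read_motion_trace <- function(path, tr_s = 2) {
  if (!file.exists(path)) stop("cannot read motion trace: no such file: ", path)
  m <- as.matrix(read.table(path))
  if (ncol(m) != 6) stop("motion trace must have 6 columns, found ", ncol(m))
  structure(list(translations_mm = unname(m[, 1:3]),
                 rotations_rad = unname(m[, 4:6]), tr_s = tr_s),
            class = "motion_trace")
}

#' @rdname read_motion_trace
#' @param trace a `motion_trace`.
#' @export
write_motion_trace <- function(trace, path) {
  m <- cbind(trace$translations_mm, trace$rotations_rad)
  write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
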