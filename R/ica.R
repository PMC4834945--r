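#' Spatial ICA decomposition of a BOLD volume
#'
#' Per-frame Gaussian presmoothing, per-voxel mean removal, SVD reduction of
#' the frames-by-voxels matrix to `n_components`, then symmetric FastICA
#' (logcosh contrast) maximizing non-Gaussianity of the spatial maps. Each
#' spatial map is standardized to a z-map over the analysis mask (population
#' SD). Components are ordered by explained variance and sign-fixed so each
#' spatial map has positive skewness; the decomposition is deterministic
#' given `seed`, with up to `max_restarts` reseeded restarts on
#' non-convergence.
#'
#' @param bold a [volume4d()].
#' @param mask a [mask_volume()] defining the in-brain analysis support.
#' @param n_components number of components, default 30; must be smaller
#'   than the number of frames.
#' @param seed integer seed for the FastICA initialization.
#' @param presmooth_fwhm_mm per-frame Gaussian presmoothing, default 8 mm
#'   (0 disables).
#' @param max_restarts restart budget on FastICA non-convergence, default 5.
#' @param tol FastICA convergence tolerance, default 1e-6.
#' @param max_iter FastICA iteration cap per restart, default 1000.
#' @return An object of class `ic_decomposition`: `spatial_zmaps` (list of
#'   [volume3d()]), `timecourses` (frames x components matrix), `mask`,
#'   `tr_s`, `n_components`.
#' @export
decompose <- function(bold, mask, n_components = 30, seed = 1,
                      presmooth_fwhm_mm = 8, max_restarts = 5,
                      tol = 1e-6, max_iter = 1000) {
  stopifnot(inherits(bold, "volume4d"), inherits(mask, "mask_volume"))
  n_frames <- dim(bold$data)[4]
  if (n_components >= n_frames) {
    stop("`n_components` (", n_components, ") must be smaller than the number of frames (",
         n_frames, ")")
  }
  check_same_grid(list(data = bold$data[, , , 1], affine = bold$affine), mask)
  vox <- which(mask$data == 1L)
  if (length(vox) < n_components) stop("mask has fewer voxels than components")

  d3 <- dim(bold$data)[1:3]
  arr <- bold$data
  if (presmooth_fwhm_mm > 0) {
    sig <- fwhm_to_sigma_vox(presmooth_fwhm_mm, voxel_size(bold))
    for (t in seq_len(n_frames)) {
      arr[, , , t] <- smooth_array(arr[, , , t], sig)
    }
  }
  X <- t(matrix(arr, prod(d3), n_frames)[vox, , drop = FALSE]) # frames x voxels
  X <- sweep(X, 2, colMeans(X)) # per-voxel detrend (mean removal)

  sv <- svd(X, nu = n_components, nv = n_components)
  if (sv$d[n_components] < 1e-12 * sv$d[1]) {
    # Rank-deficient data: keep the leading subspace, ICA still runs on it.
    warning("data rank is lower than n_components; trailing components are noise-level")
  }
  nvox <- length(vox)
  Y <- t(sv$v[, seq_len(n_components), drop = FALSE]) * sqrt(nvox) # k x voxels, white

  fit <- NULL
  for (r in 0:max_restarts) {
    fit <- fastica_symm(Y, seed = seed + r, tol = tol, max_iter = max_iter)
    if (fit$converged) break
  }
  if (!fit$converged) {
    stop("FastICA failed to converge after ", max_restarts + 1,
         " restarts (base seed ", seed, ")")
  }
  S <- fit$W %*% Y # k x voxels spatial sources, unit variance
  A <- X %*% t(S) / nvox # frames x k timecourses

  # Deterministic presentation: order by explained variance, positive skewness.
  energy <- colSums(A^2) * rowSums(S^2)
  ord <- order(energy, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  for (i in seq_len(n_components)) {
    sk <- mean(S[i, ]^3)
    if (sk < 0) { S[i, ] <- -S[i, ]; A[, i] <- -A[, i] }
  }

  zmaps <- lapply(seq_len(n_components), function(i) {
    m <- array(0, d3)
    m[vox] <- S[i, ]
    zscore_spatial_map(volume3d(m, affine = bold$affine), mask)
  })
  structure(list(spatial_zmaps = zmaps, timecourses = A, mask = mask,
                 tr_s = bold$tr_s, n_components = n_components, seed = seed),
            class = "ic_decomposition")
}

# Symmetric FastICA with the logcosh (tanh) contrast on whitened rows of Y.
# The step toward the fixed point is adaptively damped (halved when the
# update distance grows): the plain symmetric iteration can enter a limit
# cycle between sign/permutation-equivalent solutions, while damping keeps
# the same fixed points and stabilizes convergence.
fastica_symm <- function(Y, seed, tol = 1e-6, max_iter = 1000) {
  k <- nrow(Y)
  nvox <- ncol(Y)
  W <- with_seed(seed, {
    qr.Q(qr(matrix(rnorm(k * k), k, k)))
  })
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*% t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  mu <- 1
  prev_delta <- Inf
  for (it in seq_len(max_iter)) {
    WY <- W %*% Y
    G <- tanh(WY)
    gprime <- rowMeans(1 - G^2)
    target <- sym_decorrelate(G %*% t(Y) / nvox - diag(gprime, k) %*% W)
    d <- rowSums(target * W)
    target[d < 0, ] <- -target[d < 0, , drop = FALSE] # align row signs to W
    delta <- max(1 - abs(d)) # distance of W from the full-step fixed point
    if (delta < tol) { converged <- TRUE; break }
    # Damp only when a near-converged iterate starts oscillating; early
    # non-monotone exploration keeps the full step (mu = 1 reproduces the
    # classic symmetric iteration).
    if (delta > prev_delta && prev_delta < 0.05) {
      mu <- max(mu / 2, 0.05)
    } else if (delta < prev_delta) {
      mu <- min(1, mu * 1.05)
    }
    prev_delta <- delta
    W <- sym_decorrelate(W + mu * (target - W))
  }
  list(W = W, converged = converged, iterations = it)
}

#' Standardize a spatial map to z-scores over a mask
#'
#' In-mask voxels become `(value - in-mask mean) / in-mask SD` using the
#' population SD; voxels outside the mask are set to 0.
#'
#' @param raw_map a [volume3d()].
#' @param mask a [mask_volume()] on the same grid.
#' @return A z-scored `volume3d`.
#' @export
zscore_spatial_map <- function(raw_map, mask) {
  stopifnot(inherits(raw_map, "volume3d"), inherits(mask, "mask_volume"))
  check_same_grid(raw_map, mask)
  inmask <- mask$data == 1L
  v <- raw_map$data[inmask]
  s <- sqrt(mean((v - mean(v))^2))
  if (s < .Machine$double.eps) stop("in-mask standard deviation is zero; z-scoring undefined")
  out <- array(0, dim(raw_map$data))
  out[inmask] <- (v - mean(v)) / s
  volume3d(out, affine = raw_map$affine)
}

#' Match decomposition components to reference maps
#'
#' Greedy best-|correlation| assignment of components to reference spatial
#' maps over the mask, used to identify which components carry known
#' (e.g. phantom ground-truth) sources.
#'
#' @param decomposition an `ic_decomposition`.
#' @param reference_maps list of [volume3d()] reference maps.
#' @return A data.frame with one row per reference map: `reference`,
#'   `component`, `abs_correlation`.
#' @export
match_components <- function(decomposition, reference_maps) {
  mask <- decomposition$mask$data == 1L
  comp <- sapply(decomposition$spatial_zmaps, function(z) z$data[mask])
  ref <- sapply(reference_maps, function(m) m$data[mask])
  cc <- abs(cor(ref, comp))
  n_ref <- ncol(ref)
  out <- data.frame(reference = seq_len(n_ref), component = NA_integer_,
                    abs_correlation = NA_real_)
  used <- integer(0)
  for (step in seq_len(n_ref)) {
    cc_work <- cc
    cc_work[out$reference[!is.na(out$component)], ] <- -Inf
    cc_work[, used] <- -Inf
    best <- arrayInd(which.max(cc_work), dim(cc_work))
    out$component[best[1]] <- best[2]
    out$abs_correlation[best[1]] <- cc[best[1], best[2]]
    used <- c(used, best[2])
  }
  out
}
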