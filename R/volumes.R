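#' Construct a 3-D volume
#'
#' A `volume3d` bundles a 3-D numeric array with its 4x4 voxel-to-world
#' affine (NIfTI convention, millimetres). Voxel sizes are derived from the
#' column norms of the affine's rotation block.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 invertible voxel-to-mm matrix. Defaults to a diagonal
#'   affine with the given voxel size.
#' @param voxel_size_mm length-3 positive numeric, used only when `affine`
#'   is not supplied.
#' @return An object of class `volume3d` with fields `data` and `affine`.
#' @export
volume3d <- function(data, affine = NULL, voxel_size_mm = c(3, 3, 3)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array")
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  check_affine(affine)
  structure(list(data = data, affine = affine), class = "volume3d")
}

#' Construct a 4-D (BOLD) volume
#'
#' @param data 4-D numeric array (3 space + 1 time).
#' @param affine 4x4 voxel-to-mm matrix.
#' @param tr_s repetition time in seconds (> 0).
#' @param voxel_size_mm used only when `affine` is missing.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(data, affine = NULL, tr_s = 2, voxel_size_mm = c(3, 3, 3)) {
  if (length(dim(data)) != 4L) stop("`data` must be a 4-D array")
  if (dim(data)[4] < 2L) stop("a 4-D volume needs at least 2 frames")
  if (!is.numeric(tr_s) || tr_s <= 0) stop("`tr_s` must be positive")
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  check_affine(affine)
  structure(list(data = data, affine = affine, tr_s = tr_s), class = "volume4d")
}

#' Construct a binary mask volume
#'
#' @param data 3-D array coercible to 0/1; must contain at least one voxel.
#' @param affine 4x4 voxel-to-mm matrix.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, affine = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array")
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1))) stop("mask values must be 0 or 1")
  if (sum(data) < 1) stop("mask has no nonzero voxel")
  if (is.null(affine)) affine <- diag(c(3, 3, 3, 1))
  check_affine(affine)
  storage.mode(data) <- "integer"
  structure(list(data = data, affine = affine), class = "mask_volume")
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4))) {
    stop("`affine` must be a 4x4 matrix")
  }
  if (abs(det(affine)) < .Machine$double.eps) stop("`affine` must be invertible")
  invisible(affine)
}

#' Voxel size in millimetres
#' @param vol a `volume3d`, `volume4d` or `mask_volume`.
#' @return length-3 numeric vector of voxel edge lengths.
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

# Maps are never silently resampled: grids must agree (affine entries within
# `tol`, identical array dimensions) or the operation fails.
check_same_grid <- function(a, b, tol = 1e-4) {
  if (!all(dim(a$data)[1:3] == dim(b$data)[1:3])) {
    stop("volumes are on different grids (dimension mismatch)")
  }
  if (max(abs(a$affine - b$affine)) > tol) {
    stop("volumes are on different grids (affine mismatch beyond ", tol, ")")
  }
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' 3-D files become [volume3d()] objects; 4-D files become [volume4d()]
#' objects with the repetition time taken from `pixdim[4]` of the header.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A `volume3d` or `volume4d`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  aff <- structure(unclass(RNifti::xform(img)), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  if (nd == 3L) {
    volume3d(array(as.numeric(img), dim(img)), affine = aff)
  } else if (nd == 4L) {
    tr <- RNifti::niftiHeader(img)$pixdim[5]
    if (!is.finite(tr) || tr <= 0) tr <- 1
    volume4d(array(as.numeric(img), dim(img)), affine = aff, tr_s = tr)
  } else {
    stop("unsupported dimensionality (", nd, "-D) in ", path,
         "; only 3-D and 4-D NIfTI volumes are handled")
  }
}

#' Write a volume to NIfTI-1
#'
#' Masks are stored as unsigned 8-bit integers, other volumes as 32-bit
#' floats. Round trips through [read_volume()] preserve the affine exactly
#' and data to storage precision.
#'
#' @param vol a `volume3d`, `volume4d` or `mask_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path))) stop("cannot write volume: no such directory: ", dirname(path))
  img <- RNifti::asNifti(vol$data)
  vs <- voxel_size(vol)
  pd <- if (inherits(vol, "volume4d")) c(vs, vol$tr_s) else vs
  RNifti::`pixdim<-`(img, pd) -> img
  RNifti::`sform<-`(img, structure(vol$affine, code = 2L)) -> img
  dtype <- if (inherits(vol, "mask_volume")) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Binarize a gray-matter probability map
#'
#' A voxel enters the mask iff its probability is greater than or equal to
#' `threshold` (the comparison convention is documented and configurable via
#' the threshold itself).
#'
#' @param prob `volume3d` with values in \[0, 1\].
#' @param threshold probability cutoff, default 0.1.
#' @return A [mask_volume()].
#' @export
gray_matter_mask <- function(prob, threshold = 0.1) {
  stopifnot(inherits(prob, "volume3d"))
  v <- prob$data
  if (min(v) < 0 || max(v) > 1) stop("probabilities must lie in [0, 1]")
  m <- (v >= threshold) * 1L
  if (sum(m) == 0) stop("no voxel reached the threshold ", threshold, "; mask is empty")
  mask_volume(array(m, dim(v)), affine = prob$affine)
}

# FWHM (mm) -> per-axis Gaussian SD in voxels.
fwhm_to_sigma_vox <- function(fwhm_mm, voxel_size_mm) {
  (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))
}

# Separable 1-D Gaussian convolution along each array axis with zero padding,
# realized as a banded-matrix product per axis (grids here are small).
smooth_array <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in seq_along(d)) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- d[ax]
    r <- max(1L, ceiling(4 * s))
    g <- exp(-((-r:r)^2) / (2 * s^2))
    g <- g / sum(g)
    K <- matrix(0, n, n)
    for (off in -r:r) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- g[off + r + 1]
    }
    perm <- c(ax, setdiff(seq_along(d), ax))
    x <- aperm(arr, perm)
    dp <- dim(x)
    x <- K %*% matrix(x, nrow = n)
    dim(x) <- dp
    arr <- aperm(x, order(perm))
  }
  arr
}

#' Gaussian smoothing in millimetres
#'
#' Separable Gaussian convolution with per-axis SD
#' `sigma = (fwhm_mm / voxel_size) / (2 sqrt(2 log 2))` voxels and zero
#' padding at the grid faces (SPM-like; mass is not conserved at edges).
#'
#' @param vol a `volume3d`.
#' @param fwhm_mm positive full width at half maximum in mm.
#' @return A smoothed `volume3d` on the same grid.
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "volume3d"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1 || fwhm_mm <= 0) {
    stop("`fwhm_mm` must be a positive scalar")
  }
  sig <- fwhm_to_sigma_vox(fwhm_mm, voxel_size(vol))
  volume3d(smooth_array(vol$data, sig), affine = vol$affine)
}

#' Proportional scaling by the in-mask mean
#'
#' Divides every voxel by the mean over in-mask voxels and multiplies by
#' `target`, so the scaled in-mask mean equals `target` exactly. This is the
#' global-signal normalization applied before group statistics.
#'
#' @param vol a `volume3d`.
#' @param mask a `mask_volume` on the same grid.
#' @param target the scaled in-mask mean, default 100.
#' @return A scaled `volume3d`.
#' @export
proportional_scale <- function(vol, mask, target = 100) {
  stopifnot(inherits(vol, "volume3d"), inherits(mask, "mask_volume"))
  check_same_grid(vol, mask)
  m <- mean(vol$data[mask$data == 1L])
  if (!is.finite(m) || abs(m) < .Machine$double.eps) {
    stop("in-mask mean is zero; proportional scaling undefined")
  }
  volume3d(vol$data / m * target, affine = vol$affine)
}
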