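#' Construct a scalar map object
#'
#' A `scalar_map` wraps a [volume3d()] with subject/modality metadata and a
#' processing record (smoothing FWHM and proportional-scaling state).
#'
#' @param map a [volume3d()].
#' @param subject_id identifier.
#' @param modality `"fmri_total"` or `"metabolic"`.
#' @param n_neuronal_components for fMRI total maps, the number of
#'   components summed.
#' @param processing list with `smooth_fwhm_mm` (NULL if unsmoothed) and
#'   `scaled` (logical).
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(map, subject_id = "subject",
                       modality = c("fmri_total", "metabolic"),
                       n_neuronal_components = NA_integer_,
                       processing = list(smooth_fwhm_mm = NULL, scaled = FALSE)) {
  modality <- match.arg(modality)
  stopifnot(inherits(map, "volume3d"))
  if (modality == "fmri_total") {
    if (is.na(n_neuronal_components) || n_neuronal_components < 1) {
      stop("an fMRI total map needs n_neuronal_components >= 1")
    }
    if (min(map$data) < -1e-12) stop("an fMRI total map must be nonnegative")
  }
  structure(list(map = map, subject_id = subject_id, modality = modality,
                 n_neuronal_components = as.integer(n_neuronal_components),
                 processing = processing), class = "scalar_map")
}

#' fMRI total neuronal activity map
#'
#' Voxelwise sum of `|z_i|^exponent` (default: the square root of the
#' absolute z value) over the components selected as neuronal, inside the
#' decomposition's analysis mask; exactly 0 outside. The square root
#' de-sparsifies the summed map, moving its voxel distribution toward the
#' near-normal shape of metabolic maps.
#'
#' @param decomposition an `ic_decomposition` from [decompose()].
#' @param neuronal_indices integer indices of the neuronal components
#'   (nonempty; a subject with no neuronal component cannot produce a total
#'   map).
#' @param exponent exponent on `|z|`, default 0.5.
#' @param subject_id identifier recorded on the map.
#' @return A `scalar_map` with modality `"fmri_total"`, unsmoothed and
#'   unscaled.
#' @export
total_neuronal_map <- function(decomposition, neuronal_indices, exponent = 0.5,
                               subject_id = "subject") {
  if (length(neuronal_indices) == 0) {
    stop("no component selected as neuronal: the subject cannot produce a total map")
  }
  if (any(neuronal_indices < 1 | neuronal_indices > decomposition$n_components)) {
    stop("neuronal_indices out of range 1..", decomposition$n_components)
  }
  inmask <- decomposition$mask$data == 1L
  acc <- array(0, dim(decomposition$mask$data))
  for (i in neuronal_indices) {
    z <- decomposition$spatial_zmaps[[i]]$data
    acc[inmask] <- acc[inmask] + abs(z[inmask])^exponent
  }
  scalar_map(volume3d(acc, affine = decomposition$spatial_zmaps[[1]]$affine),
             subject_id = subject_id, modality = "fmri_total",
             n_neuronal_components = length(neuronal_indices),
             processing = list(smooth_fwhm_mm = NULL, scaled = FALSE))
}

#' Smooth and proportionally scale a scalar map
#'
#' Gaussian smoothing (default FWHM 16 mm) followed by optional proportional
#' scaling to an in-mask mean of 100. Refuses to process a map whose record
#' already shows smoothing, so the 16-mm kernel cannot be applied twice.
#'
#' @param raw a `scalar_map` (unsmoothed).
#' @param mask a [mask_volume()] used for the scaling statistics.
#' @param smooth_fwhm_mm kernel FWHM in mm, default 16.
#' @param scale logical; proportionally scale after smoothing, default TRUE.
#' @return The processed `scalar_map` with its processing record updated.
#' @export
finalize_map <- function(raw, mask, smooth_fwhm_mm = 16, scale = TRUE) {
  stopifnot(inherits(raw, "scalar_map"), inherits(mask, "mask_volume"))
  if (!is.null(raw$processing$smooth_fwhm_mm)) {
    stop("map was already smoothed (FWHM ", raw$processing$smooth_fwhm_mm,
         " mm); refusing to smooth twice")
  }
  out <- raw
  out$map <- gaussian_smooth(raw$map, smooth_fwhm_mm)
  unscaled_mean <- mean(raw$map$data[mask$data == 1L])
  if (isTRUE(scale)) out$map <- proportional_scale(out$map, mask)
  out$processing <- list(smooth_fwhm_mm = smooth_fwhm_mm, scaled = isTRUE(scale),
                         unscaled_mean = unscaled_mean,
                         sigma_vox = fwhm_to_sigma_vox(smooth_fwhm_mm, voxel_size(raw$map)))
  out
}
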