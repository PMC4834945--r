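#' Gray-matter correlation between an fMRI total map and a metabolic map
#'
#' Pearson correlation over in-mask voxels, with a two-sided p-value. The
#' statistic is symmetric in the two maps and invariant to separate affine
#' rescaling of either map.
#'
#' @param fmri_map a `scalar_map` (modality `"fmri_total"`).
#' @param metabolic_map a `scalar_map` (modality `"metabolic"`).
#' @param mask a [mask_volume()] on the same grid (>= 3 voxels).
#' @param group optional group tag carried into the result.
#' @return An object of class `subject_comparison`: `subject_id`, `group`,
#'   `rho`, `p_value`, `n_voxels`, `n_neuronal_components`,
#'   `mean_fmri_total`, `mean_metabolic`.
#' @export
gm_correlation <- function(fmri_map, metabolic_map, mask, group = NA_character_) {
  stopifnot(inherits(fmri_map, "scalar_map"), inherits(metabolic_map, "scalar_map"),
            inherits(mask, "mask_volume"))
  check_same_grid(fmri_map$map, mask)
  check_same_grid(metabolic_map$map, mask)
  inmask <- mask$data == 1L
  a <- fmri_map$map$data[inmask]
  b <- metabolic_map$map$data[inmask]
  if (length(a) < 3) stop("need at least 3 in-mask voxels")
  if (sd(a) < .Machine$double.eps || sd(b) < .Machine$double.eps) {
    stop("zero variance inside the mask; correlation undefined")
  }
  ct <- cor.test(a, b)
  structure(list(
    subject_id = fmri_map$subject_id, group = group,
    rho = unname(ct$estimate), p_value = ct$p.value, n_voxels = length(a),
    n_neuronal_components = fmri_map$n_neuronal_components,
    mean_fmri_total = mean(a), mean_metabolic = mean(b)
  ), class = "subject_comparison")
}

#' @export
print.subject_comparison <- function(x, ...) {
  cat(sprintf("Subject %s%s: rho = %.3f (p = %.3g) over %d gray-matter voxels\n",
              x$subject_id, if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              x$rho, x$p_value, x$n_voxels))
  cat(sprintf("  neuronal components: %s; mean fMRI total = %.3f; mean metabolic = %.3f\n",
              ifelse(is.na(x$n_neuronal_components), "?", x$n_neuronal_components),
              x$mean_fmri_total, x$mean_metabolic))
  invisible(x)
}

#' Compare per-subject correlations between two groups
#'
#' Welch two-sample t-test on Fisher z-transformed correlations; means and
#' SDs are reported on the original correlation scale.
#'
#' @param group_a,group_b numeric vectors of correlations (each >= 2 values).
#' @return A list: `mean_a`, `sd_a`, `mean_b`, `sd_b`, `difference`
#'   (`mean_a - mean_b`), `p_value`, `statistic`, `df`.
#' @export
correlation_group_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) stop("each group needs >= 2 values")
  if (any(abs(c(group_a, group_b)) >= 1)) stop("correlations must lie in (-1, 1)")
  za <- atanh(group_a)
  zb <- atanh(group_b)
  if (sd(za) < .Machine$double.eps && sd(zb) < .Machine$double.eps) {
    if (abs(mean(za) - mean(zb)) < .Machine$double.eps) {
      return(list(mean_a = mean(group_a), sd_a = sd(group_a),
                  mean_b = mean(group_b), sd_b = sd(group_b),
                  difference = 0, p_value = 1, statistic = 0, df = NA_real_))
    }
    stop("both groups are degenerate (zero variance); test undefined")
  }
  tt <- t.test(za, zb)
  list(mean_a = mean(group_a), sd_a = sd(group_a),
       mean_b = mean(group_b), sd_b = sd(group_b),
       difference = mean(group_a) - mean(group_b),
       p_value = tt$p.value, statistic = unname(tt$statistic),
       df = unname(tt$parameter))
}

#' Summary motion metrics of a rigid-body trace
#'
#' Displacement is the mean over frames of the Euclidean norm of the
#' translation relative to the first frame; speed is the mean over
#' consecutive frame pairs of the norm of the frame-to-frame translation
#' difference (per frame by default). Rotations are carried in the trace but
#' enter only when `rotation_radius_mm` is positive, as arc lengths at that
#' radius added in quadrature.
#'
#' @param trace a `motion_trace`.
#' @param rotation_radius_mm radius converting rotations to arc
#'   displacement; 0 (default) ignores rotations.
#' @param per_second report speed per second instead of per frame.
#' @return A list with `displacement_mm` and `speed_mm_per_frame` (or
#'   `speed_mm_per_s`).
#' @export
motion_summary <- function(trace, rotation_radius_mm = 0, per_second = FALSE) {
  tr <- trace$translations_mm
  ro <- trace$rotations_rad
  if (!all(is.finite(tr)) || !all(is.finite(ro))) stop("non-finite motion parameters")
  if (nrow(tr) < 2) stop("need at least 2 frames")
  eff <- tr
  if (rotation_radius_mm > 0) eff <- cbind(tr, ro * rotation_radius_mm)
  rel <- sweep(eff, 2, eff[1, ])
  displacement <- mean(sqrt(rowSums(rel^2)))
  step <- diff(eff)
  speed <- mean(sqrt(rowSums(step^2)))
  if (per_second) {
    list(displacement_mm = displacement, speed_mm_per_s = speed / trace$tr_s)
  } else {
    list(displacement_mm = displacement, speed_mm_per_frame = speed)
  }
}
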