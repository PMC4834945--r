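#' Assemble a 2x2 factorial group design
#'
#' Two factors with two levels each: machine (PET-like metabolic vs fMRI
#' total neuronal) and consciousness group (control vs patient). Each cell
#' holds the proportionally scaled scalar maps of its subjects.
#'
#' @param pet_control,pet_patient,fmri_control,fmri_patient lists of
#'   `scalar_map` (or bare [volume3d()]) objects, each cell nonempty.
#' @param mask a [mask_volume()]; all maps must share its grid.
#' @return An object of class `group_design`.
#' @export
group_design <- function(pet_control, pet_patient, fmri_control, fmri_patient, mask) {
  cells <- list(pet_control = pet_control, pet_patient = pet_patient,
                fmri_control = fmri_control, fmri_patient = fmri_patient)
  stopifnot(inherits(mask, "mask_volume"))
  cells <- lapply(cells, function(cell) {
    lapply(cell, function(m) if (inherits(m, "scalar_map")) m$map else m)
  })
  for (nm in names(cells)) {
    if (length(cells[[nm]]) == 0) stop("cell `", nm, "` is empty")
    for (m in cells[[nm]]) check_same_grid(m, mask)
  }
  structure(list(cells = cells, mask = mask), class = "group_design")
}

contrast_definitions <- function() {
  # Cell order: pet_control, pet_patient, fmri_control, fmri_patient.
  list(
    pet_ctrl_gt_patient = c(1, -1, 0, 0),
    pet_preserved_in_patient = c(-1, 1, 0, 0),
    fmri_ctrl_gt_patient = c(0, 0, 1, -1),
    fmri_preserved_in_patient = c(0, 0, -1, 1),
    pet_decrease_gt_fmri = c(1, -1, -1, 1),
    fmri_decrease_gt_pet = c(-1, 1, 1, -1)
  )
}

#' Voxelwise factorial contrasts with FDR control
#'
#' Fits a voxelwise cell-means linear model (4 parameters) over the in-mask
#' voxels and evaluates the six directed contrasts of the machine x
#' consciousness design: metabolic and fMRI decreases in patients
#' (`pet_ctrl_gt_patient`, `fmri_ctrl_gt_patient`), their reversed
#' "preserved" directions, and the two signs of the interaction
#' (`pet_decrease_gt_fmri`, `fmri_decrease_gt_pet`). Statistics are pooled-
#' variance t values with `df = N - 4`; one-sided p-values are thresholded by
#' Benjamini-Hochberg FDR at level `q` per contrast. Conjunctions of two
#' contrasts are obtained with [conjunction_mask()].
#'
#' @param design a [group_design()]; every cell needs >= 2 maps.
#' @param q FDR level, default 0.05.
#' @return A named list of `contrast_result` objects with fields
#'   `contrast_name`, `t_map`, `p_map`, `fdr_threshold_p`,
#'   `significance_mask`, `df`, `peak_table`.
#' @export
factorial_contrasts <- function(design, q = 0.05) {
  stopifnot(inherits(design, "group_design"))
  mask <- design$mask
  inmask <- mask$data == 1L
  nvox <- sum(inmask)
  cell_mats <- lapply(design$cells, function(cell) {
    t(sapply(cell, function(m) m$data[inmask]))
  })
  n_c <- vapply(cell_mats, nrow, integer(1))
  if (any(n_c < 2)) {
    stop("cells with fewer than 2 maps (variance inestimable): ",
         paste(names(n_c)[n_c < 2], collapse = ", "))
  }
  N <- sum(n_c)
  df <- N - 4L
  means <- t(sapply(cell_mats, colMeans)) # 4 x nvox
  ss <- Reduce(`+`, lapply(seq_along(cell_mats), function(i) {
    colSums(sweep(cell_mats[[i]], 2, means[i, ])^2)
  }))
  s2 <- ss / df

  out <- list()
  for (nm in names(contrast_definitions())) {
    cvec <- contrast_definitions()[[nm]]
    est <- as.vector(cvec %*% means)
    se <- sqrt(pmax(s2, .Machine$double.eps) * sum(cvec^2 / n_c))
    tval <- est / se
    pval <- pt(tval, df, lower.tail = FALSE)
    fdr <- fdr_threshold(pval, q)
    t_map <- array(0, dim(mask$data)); t_map[inmask] <- tval
    p_map <- array(1, dim(mask$data)); p_map[inmask] <- pval
    sig <- array(0L, dim(mask$data)); sig[inmask] <- as.integer(fdr$reject)
    res <- structure(list(
      contrast_name = nm,
      t_map = volume3d(t_map, affine = mask$affine),
      p_map = volume3d(p_map, affine = mask$affine),
      fdr_threshold_p = fdr$threshold_p,
      significance_mask = structure(list(data = sig, affine = mask$affine),
                                    class = "mask_volume"),
      df = df, n_significant = sum(sig)
    ), class = "contrast_result")
    res$peak_table <- peak_table(res)
    out[[nm]] <- res
  }
  out
}

# Local maxima of t inside the significance mask with a minimum separation
# of 2 voxels (Euclidean), in world coordinates via the affine (0-based
# voxel indices).
peak_table <- function(result, min_separation_vox = 2) {
  sig <- which(result$significance_mask$data == 1L, arr.ind = TRUE)
  if (nrow(sig) == 0) {
    return(data.frame(x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                      t = numeric(0), p_fdr_significant = logical(0)))
  }
  tv <- result$t_map$data[result$significance_mask$data == 1L]
  ord <- order(tv, decreasing = TRUE)
  sig <- sig[ord, , drop = FALSE]
  tv <- tv[ord]
  keep <- integer(0)
  for (i in seq_len(nrow(sig))) {
    if (length(keep) == 0 ||
        min(sqrt(rowSums(sweep(sig[keep, , drop = FALSE], 2, sig[i, ])^2))) > min_separation_vox) {
      keep <- c(keep, i)
    }
  }
  vox0 <- sig[keep, , drop = FALSE] - 1
  world <- t(result$t_map$affine %*% rbind(t(vox0), 1))[, 1:3, drop = FALSE]
  data.frame(x_mm = world[, 1], y_mm = world[, 2], z_mm = world[, 3],
             t = tv[keep], p_fdr_significant = TRUE)
}

#' Conjunction of two FDR-thresholded contrasts
#'
#' Conjunction-null logic: a voxel survives only if it is individually
#' significant in both contrasts (intersection of the two significance
#' masks).
#'
#' @param result_a,result_b `contrast_result` objects on the same grid.
#' @return A `mask_volume` (possibly empty) of jointly significant voxels.
#' @export
conjunction_mask <- function(result_a, result_b) {
  check_same_grid(result_a$t_map, result_b$t_map)
  both <- (result_a$significance_mask$data == 1L) &
    (result_b$significance_mask$data == 1L)
  structure(list(data = array(as.integer(both), dim(both)),
                 affine = result_a$t_map$affine), class = "mask_volume")
}

#' Benjamini-Hochberg FDR threshold
#'
#' Step-up procedure: with ordered p-values `p_(1) <= ... <= p_(m)`, reject
#' the `k` smallest where `k` is the largest index with
#' `p_(k) <= k q / m`; the reported `threshold_p` is `p_(k)` (0 when
#' nothing is rejected).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param q FDR level in (0, 1), default 0.05.
#' @return A list with `threshold_p` and logical `reject_flags` (alias
#'   `reject`) aligned with the input.
#' @export
fdr_threshold <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || any(is.na(p_values))) {
    stop("p-values must lie in [0, 1]")
  }
  if (q <= 0 || q >= 1) stop("`q` must be in (0, 1)")
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0) {
    return(list(threshold_p = 0, reject_flags = rep(FALSE, m), reject = rep(FALSE, m)))
  }
  k <- max(ok)
  thr <- ps[k]
  reject <- p_values <= thr
  list(threshold_p = thr, reject_flags = reject, reject = reject)
}
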