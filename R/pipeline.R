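#' Default pipeline options
#'
#' The option set mirrors the acquisition/analysis defaults of the method:
#' 30 components, 8-mm presmoothing before ICA, 16-mm smoothing of the total
#' map, gray-matter threshold 0.1, exponent 0.5 on `|z|`, FDR level 0.05.
#'
#' @param n_components,presmooth_fwhm_mm,final_smooth_fwhm_mm,gm_threshold,brain_threshold,exponent,q,seed
#'   see Details of [run_subject()] / [run_group()].
#' @return A named list of options.
#' @export
pipeline_options <- function(n_components = 30, presmooth_fwhm_mm = 8,
                             final_smooth_fwhm_mm = 16, gm_threshold = 0.1,
                             brain_threshold = 0.01, exponent = 0.5,
                             q = 0.05, seed = 1) {
  stopifnot(n_components >= 1, presmooth_fwhm_mm >= 0, final_smooth_fwhm_mm > 0,
            gm_threshold >= 0, gm_threshold <= 1, exponent > 0, q > 0, q < 1)
  list(n_components = n_components, presmooth_fwhm_mm = presmooth_fwhm_mm,
       final_smooth_fwhm_mm = final_smooth_fwhm_mm, gm_threshold = gm_threshold,
       brain_threshold = brain_threshold, exponent = exponent, q = q,
       seed = as.integer(seed))
}

#' Run the single-subject pipeline
#'
#' BOLD to total neuronal activity map: spatial ICA over the brain support
#' (gray-matter probability above `brain_threshold`), fingerprinting of
#' every component, neuronal/non-neuronal labeling with the supplied
#' classifier (or explicit `neuronal_indices` bypassing it), voxelwise
#' summation of the square-root absolute z maps, 16-mm smoothing
#' with proportional scaling, and, when a metabolic map is given, the
#' gray-matter correlation against it.
#'
#' @param bold a [volume4d()].
#' @param gm_probability a [volume3d()] of gray-matter probabilities.
#' @param classifier a fitted `neuronal_svm`, or NULL when
#'   `neuronal_indices` is given.
#' @param neuronal_indices optional integer vector of known neuronal
#'   component indices (bypasses the classifier).
#' @param metabolic_map optional `scalar_map` of modality `"metabolic"`;
#'   when absent the comparison is skipped and the total map still produced.
#' @param motion_trace optional `motion_trace`, summarized into the result.
#' @param subject_id identifier.
#' @param group optional group tag.
#' @param options a [pipeline_options()] list.
#' @return A list of class `subject_result`: `total_map` (processed
#'   `scalar_map`), `comparison` (`subject_comparison` or NULL),
#'   `fingerprints`, `labels`, `neuronal_indices`,
#'   `n_neuronal_components`, `motion`, `provenance`.
#' @export
run_subject <- function(bold, gm_probability, classifier = NULL,
                        neuronal_indices = NULL, metabolic_map = NULL,
                        motion_trace = NULL, subject_id = "subject",
                        group = NA_character_, options = pipeline_options()) {
  if (is.null(classifier) && is.null(neuronal_indices)) {
    stop("either a trained classifier or explicit neuronal_indices is required")
  }
  brain <- gray_matter_mask(gm_probability, threshold = options$brain_threshold)
  gm <- gray_matter_mask(gm_probability, threshold = options$gm_threshold)

  decomp <- decompose(bold, brain, n_components = options$n_components,
                      seed = options$seed,
                      presmooth_fwhm_mm = options$presmooth_fwhm_mm)
  fp <- fingerprint_table(decomp, subject_id = subject_id)
  labels <- if (is.null(neuronal_indices)) {
    predict(classifier, fp)
  } else {
    ifelse(seq_len(decomp$n_components) %in% neuronal_indices,
           "neuronal", "non_neuronal")
  }
  idx <- which(labels == "neuronal")
  if (length(idx) == 0) {
    stop("subject ", subject_id,
         " failed: no component was selected as neuronal, no total map can be built")
  }
  raw <- total_neuronal_map(decomp, idx, exponent = options$exponent,
                            subject_id = subject_id)
  mean_unscaled <- mean(raw$map$data[gm$data == 1L])
  total <- finalize_map(raw, gm, smooth_fwhm_mm = options$final_smooth_fwhm_mm,
                        scale = TRUE)

  comparison <- NULL
  if (!is.null(metabolic_map)) {
    comparison <- gm_correlation(total, metabolic_map, gm, group = group)
  }
  motion <- if (!is.null(motion_trace)) motion_summary(motion_trace) else NULL

  structure(list(
    total_map = total, comparison = comparison, fingerprints = fp,
    labels = labels, neuronal_indices = idx, n_neuronal_components = length(idx),
    mean_unscaled_total = mean_unscaled, motion = motion,
    provenance = list(subject_id = subject_id, group = group, options = options,
                      package_version = as.character(utils::packageVersion("neurotot")),
                      classifier_kernel = if (!is.null(classifier)) classifier$kernel else NA)
  ), class = "subject_result")
}

#' Run the group-level analysis
#'
#' Proportionally scales every map that is not already scaled, runs the
#' voxelwise 2x2 factorial contrasts with FDR control, the impaired and
#' preserved conjunctions (metabolic AND fMRI), and summarizes the
#' dependence of mean (unscaled) total activity on the number of neuronal
#' components across the fMRI subjects.
#'
#' @param pet_control,pet_patient,fmri_control,fmri_patient lists of
#'   `scalar_map` objects (each cell >= 2 subjects).
#' @param mask gray-matter [mask_volume()].
#' @param q FDR level, default 0.05.
#' @return A list of class `group_report`: `contrasts` (list of
#'   `contrast_result`), `impaired_conjunction`, `preserved_conjunction`
#'   (mask volumes), `activity_vs_components` (correlation of mean unscaled
#'   activity with component count, or NULL if counts are unavailable).
#' @export
run_group <- function(pet_control, pet_patient, fmri_control, fmri_patient,
                      mask, q = 0.05) {
  cells <- list(pet_control = pet_control, pet_patient = pet_patient,
                fmri_control = fmri_control, fmri_patient = fmri_patient)
  small <- names(cells)[vapply(cells, length, integer(1)) < 2]
  if (length(small)) stop("cells with fewer than 2 subjects: ", paste(small, collapse = ", "))

  fmri_maps <- c(fmri_control, fmri_patient)
  ncomp <- vapply(fmri_maps, function(m) {
    if (inherits(m, "scalar_map")) m$n_neuronal_components else NA_integer_
  }, integer(1))
  mean_act <- vapply(fmri_maps, function(m) {
    if (inherits(m, "scalar_map") && !is.null(m$processing$unscaled_mean)) {
      return(m$processing$unscaled_mean)
    }
    mm <- if (inherits(m, "scalar_map")) m$map else m
    mean(mm$data[mask$data == 1L])
  }, numeric(1))
  activity_vs_components <- NULL
  if (all(!is.na(ncomp)) && sd(ncomp) > 0) {
    ct <- cor.test(mean_act, ncomp)
    activity_vs_components <- list(rho = unname(ct$estimate), p_value = ct$p.value,
                                   n = length(ncomp))
  }

  scale_cell <- function(cell) lapply(cell, function(m) {
    sm <- if (inherits(m, "scalar_map")) m else scalar_map(m, modality = "metabolic")
    if (!isTRUE(sm$processing$scaled)) {
      sm$map <- proportional_scale(sm$map, mask)
      sm$processing$scaled <- TRUE
    }
    sm
  })
  cells <- lapply(cells, scale_cell)
  design <- group_design(cells$pet_control, cells$pet_patient,
                         cells$fmri_control, cells$fmri_patient, mask)
  contrasts <- factorial_contrasts(design, q = q)

  structure(list(
    contrasts = contrasts,
    impaired_conjunction = conjunction_mask(contrasts$pet_ctrl_gt_patient,
                                            contrasts$fmri_ctrl_gt_patient),
    preserved_conjunction = conjunction_mask(contrasts$pet_preserved_in_patient,
                                             contrasts$fmri_preserved_in_patient),
    activity_vs_components = activity_vs_components,
    q = q, n_subjects = sum(vapply(cells, length, integer(1)))
  ), class = "group_report")
}
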