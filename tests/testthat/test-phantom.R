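test_that("phantom generation is bitwise deterministic given the seed", {
  a <- make_phantom(small_spec(seed = 4))
  b <- make_phantom(small_spec(seed = 4))
  expect_identical(a, b)
  c_ <- make_phantom(small_spec(seed = 5))
  expect_false(identical(a$bold$data, c_$bold$data))
})

test_that("noiseless artifact-free phantom is exactly the outer-product mixture", {
  spec <- small_spec(seed = 2, noise_sd = 0, n_artifact = 0)
  ph <- make_phantom(spec)
  recon <- Reduce(`+`, lapply(seq_along(ph$true_maps), function(i) {
    as.vector(ph$true_maps[[i]]$data) %o% ph$true_timecourses[, i]
  }))
  expect_equal(as.vector(ph$bold$data), as.vector(recon), tolerance = 1e-12)
})

test_that("neuronal maps have the requested sparsity and artifacts live on the shell", {
  spec <- small_spec(seed = 3)
  ph <- make_phantom(spec)
  n_inbrain <- sum(ph$brain_mask$data)
  target <- round(spec$sparsity * n_inbrain)
  for (i in which(ph$true_labels == "neuronal")) {
    expect_lte(abs(sum(ph$true_maps[[i]]$data != 0) - target), 1)
  }
  interior <- neurotot:::erode6(ph$brain_mask$data == 1L)
  shell <- (ph$brain_mask$data == 1L) & !interior
  for (i in which(ph$true_labels == "artifact")) {
    active <- ph$true_maps[[i]]$data != 0
    expect_true(all(active[!shell] == FALSE))
    expect_gt(sum(active), 0)
  }
})

test_that("neuronal and artifact timecourses obey the spectral contract", {
  spec <- phantom_spec(seed = 6) # default bands, 300 frames, TR 2
  ph <- make_phantom(spec)
  frac_in_band <- function(tc, band) {
    band_power_fractions(tc, spec$tr_s, list(band))
  }
  neu <- which(ph$true_labels == "neuronal")
  art <- which(ph$true_labels == "artifact")
  f_neu <- sapply(neu, function(i) frac_in_band(ph$true_timecourses[, i], c(0.01, 0.1)))
  f_art <- sapply(art, function(i) frac_in_band(ph$true_timecourses[, i], c(0.01, 0.1)))
  expect_true(all(f_neu >= 0.8))
  f_art_own <- sapply(art, function(i) frac_in_band(ph$true_timecourses[, i], c(0.15, 0.25)))
  expect_true(all(f_art_own >= 0.8))
  expect_gte(mean(f_neu) - mean(f_art), 0.5)
})

test_that("metabolic surrogate is self-consistent with the ground-truth construction", {
  ph <- make_phantom(small_spec(seed = 9))
  gm <- gray_matter_mask(ph$gm_probability, 0.1)
  rebuilt <- Reduce(`+`, lapply(which(ph$true_labels == "neuronal"), function(i) {
    z <- zscore_spatial_map(ph$true_maps[[i]], ph$brain_mask)
    sqrt(abs(z$data))
  }))
  sm <- gaussian_smooth(volume3d(rebuilt, affine = ph$bold$affine), 16)
  gmv <- gm$data == 1L
  expect_equal(cor(sm$data[gmv], ph$metabolic_surrogate$map$data[gmv]), 1)
})

test_that("invalid phantom specs are rejected with the offending field named", {
  expect_error(small_spec(sparsity = 0), "sparsity")
  expect_error(small_spec(n_neuronal = 0), "n_neuronal")
  expect_error(phantom_spec(n_frames = 50), "n_frames")
  expect_error(small_spec(tr_s = -1), "tr_s")
  expect_error(phantom_spec(artifact_band_hz = c(0.2, 0.4)), "artifact_band_hz")
})

test_that("fingerprint corpus has the requested group structure and label counts", {
  corp <- make_fingerprint_corpus(n_subjects = 19, n_components_per_subject = 30, seed = 1)
  expect_equal(nrow(corp), 570)
  expect_equal(length(unique(corp$subject_id)), 19)
  expect_true(all(table(corp$subject_id) == 30))
  counts <- table(corp$label)
  expect_equal(unname(counts[c("neuronal", "non_neuronal", "undefined")]),
               c(224, 248, 98), ignore_attr = TRUE)
  expect_true(all(fingerprint_feature_names() %in% names(corp)))

  expect_error(make_fingerprint_corpus(label_fractions = c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("corpus class separation scales the standardized mean distance", {
  corp <- make_fingerprint_corpus(n_subjects = 40, n_components_per_subject = 40,
                                  class_separation = 3, seed = 8)
  X <- as.matrix(corp[, fingerprint_feature_names()])
  proto <- neurotot:::corpus_prototypes()
  gap <- colMeans(X[corp$label == "neuronal", ]) - colMeans(X[corp$label == "non_neuronal", ])
  d_prime <- sqrt(sum((gap / proto$sds)^2))
  expect_equal(d_prime, 3, tolerance = 0.1)

  corp0 <- make_fingerprint_corpus(class_separation = 0, seed = 8)
  X0 <- as.matrix(corp0[, fingerprint_feature_names()])
  gap0 <- colMeans(X0[corp0$label == "neuronal", ]) -
    colMeans(X0[corp0$label == "non_neuronal", ])
  expect_lt(sqrt(sum((gap0 / proto$sds)^2)), 0.5)
})

test_that("motion traces follow their closed-form patterns", {
  still <- make_motion_trace(100, "still")
  expect_true(all(still$translations_mm == 0) && all(still$rotations_rad == 0))

  drift <- make_motion_trace(300, "drift", magnitude_mm = 0.1)
  expect_equal(drift$translations_mm[, 1], seq(0, 29.9, by = 0.1))

  jump <- make_motion_trace(300, "jump", magnitude_mm = 5)
  steps <- sqrt(rowSums(diff(jump$translations_mm)^2))
  expect_equal(sum(steps > 0), 1)
  expect_equal(max(steps), 5)

  expect_error(make_motion_trace(1, "still"), ">= 2")
})

test_that("motion traces round-trip through the 6-column text format", {
  dir <- withr::local_tempdir()
  tr <- make_motion_trace(50, "drift", magnitude_mm = 0.2, tr_s = 2)
  p <- file.path(dir, "motion.txt")
  write_motion_trace(tr, p)
  back <- read_motion_trace(p, tr_s = 2)
  expect_equal(back$translations_mm, unname(tr$translations_mm))
  expect_equal(ncol(as.matrix(read.table(p))), 6)
})
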