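# Build a 4-cell design of small random maps with optional per-cell offsets.
build_design <- function(n_per_cell = 4, d = c(8, 8, 6), noise_sd = 1,
                         offsets = list(), seed = 1) {
  set.seed(seed)
  aff <- diag(c(3, 3, 3, 1))
  mask <- mask_volume(array(1L, d), affine = aff)
  cells <- lapply(c("pet_control", "pet_patient", "fmri_control", "fmri_patient"),
                  function(nm) {
    off <- offsets[[nm]] %||% array(0, d)
    lapply(seq_len(n_per_cell), function(i) {
      volume3d(array(100 + rnorm(prod(d), sd = noise_sd), d) + off, affine = aff)
    })
  })
  names(cells) <- c("pet_control", "pet_patient", "fmri_control", "fmri_patient")
  list(cells = cells, mask = mask, aff = aff, d = d)
}

test_that("BH step-up matches worked examples", {
  r <- fdr_threshold(c(0.01, 0.02, 0.03, 0.04, 0.2), q = 0.05)
  expect_equal(sum(r$reject), 4)
  expect_equal(r$threshold_p, 0.04)

  r1 <- fdr_threshold(rep(1, 10), 0.05)
  expect_equal(sum(r1$reject), 0)
  expect_equal(r1$threshold_p, 0)

  expect_true(fdr_threshold(0.04, 0.05)$reject)
  expect_error(fdr_threshold(c(0.2, 1.3), 0.05), "0, 1")
})

test_that("BH equals the brute-force oracle and p.adjust on random vectors", {
  set.seed(60)
  brute_force_bh <- function(p, q) {
    m <- length(p)
    ps <- sort(p)
    k <- 0
    for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
    if (k == 0) rep(FALSE, m) else p <= ps[k]
  }
  for (i in 1:300) {
    m <- sample(1:50, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    r <- fdr_threshold(p, q)
    expect_identical(r$reject, brute_force_bh(p, q))
    expect_true(all(r$reject == (stats::p.adjust(p, "BH") <= q)))
  }
})

test_that("enlarging q never shrinks the BH rejection set", {
  set.seed(61)
  for (i in 1:30) {
    p <- runif(sample(5:40, 1))^2
    r1 <- fdr_threshold(p, 0.02)
    r2 <- fdr_threshold(p, 0.1)
    expect_true(all(r2$reject[r1$reject]))
  }
})

test_that("identical cells produce null t-maps and no significant voxels", {
  b <- build_design(seed = 2)
  # make all cells literally identical
  b$cells$pet_patient <- b$cells$pet_control
  b$cells$fmri_control <- b$cells$pet_control
  b$cells$fmri_patient <- b$cells$pet_control
  des <- group_design(b$cells$pet_control, b$cells$pet_patient,
                      b$cells$fmri_control, b$cells$fmri_patient, b$mask)
  res <- factorial_contrasts(des)
  for (r in res) {
    expect_lt(max(abs(r$t_map$data)), 1e-9)
    expect_equal(sum(r$significance_mask$data), 0)
    expect_equal(nrow(r$peak_table), 0)
  }
})

test_that("contrast t values agree with a cell-means lm oracle per voxel", {
  b <- build_design(n_per_cell = 3, d = c(4, 4, 3), seed = 3)
  des <- group_design(b$cells$pet_control, b$cells$pet_patient,
                      b$cells$fmri_control, b$cells$fmri_patient, b$mask)
  res <- factorial_contrasts(des)
  expect_equal(res[[1]]$df, 4 * 3 - 4)

  vox <- c(2, 3, 1)
  y <- unlist(lapply(b$cells, function(cell) {
    sapply(cell, function(m) m$data[vox[1], vox[2], vox[3]])
  }))
  cell <- factor(rep(names(b$cells), each = 3), levels = names(b$cells))
  fit <- lm(y ~ 0 + cell)
  cvec <- c(1, -1, 0, 0)
  est <- sum(coef(fit) * cvec)
  se <- sqrt(sum(diag(vcov(fit)) * cvec^2))
  expect_equal(res$pet_ctrl_gt_patient$t_map$data[vox[1], vox[2], vox[3]],
               est / se, tolerance = 1e-10)
  inter <- c(1, -1, -1, 1)
  est_i <- sum(coef(fit) * inter)
  se_i <- sqrt(sum(diag(vcov(fit)) * inter^2))
  expect_equal(res$pet_decrease_gt_fmri$t_map$data[vox[1], vox[2], vox[3]],
               est_i / se_i, tolerance = 1e-10)

  # preserved contrasts are exact negations
  expect_equal(res$pet_preserved_in_patient$t_map$data,
               -res$pet_ctrl_gt_patient$t_map$data)
  expect_equal(res$fmri_preserved_in_patient$t_map$data,
               -res$fmri_ctrl_gt_patient$t_map$data)
})

test_that("implanted deficits land in the expected contrasts", {
  d <- c(10, 10, 6)
  blob <- array(0, d)
  blob[4:7, 4:7, 3:4] <- -3 # deficit in patients
  shared <- build_design(n_per_cell = 8, d = d, noise_sd = 1, seed = 4,
                         offsets = list(pet_patient = blob, fmri_patient = blob))
  des <- group_design(shared$cells$pet_control, shared$cells$pet_patient,
                      shared$cells$fmri_control, shared$cells$fmri_patient,
                      shared$mask)
  res <- factorial_contrasts(des)
  truth <- blob != 0
  expect_gte(dice(res$pet_ctrl_gt_patient$significance_mask$data == 1, truth), 0.5)
  expect_gte(dice(res$fmri_ctrl_gt_patient$significance_mask$data == 1, truth), 0.5)
  expect_equal(sum(res$pet_decrease_gt_fmri$significance_mask$data), 0)
  expect_equal(sum(res$fmri_decrease_gt_pet$significance_mask$data), 0)
  conj <- conjunction_mask(res$pet_ctrl_gt_patient, res$fmri_ctrl_gt_patient)
  expect_gte(dice(conj$data == 1, truth), 0.5)

  pet_only <- build_design(n_per_cell = 8, d = d, noise_sd = 1, seed = 5,
                           offsets = list(pet_patient = blob))
  des2 <- group_design(pet_only$cells$pet_control, pet_only$cells$pet_patient,
                       pet_only$cells$fmri_control, pet_only$cells$fmri_patient,
                       pet_only$mask)
  res2 <- factorial_contrasts(des2)
  expect_gte(dice(res2$pet_decrease_gt_fmri$significance_mask$data == 1, truth), 0.5)
  expect_equal(sum(res2$fmri_ctrl_gt_patient$significance_mask$data), 0)
})

test_that("conjunctions intersect significance masks", {
  b <- build_design(n_per_cell = 3, d = c(5, 5, 4), seed = 6)
  des <- group_design(b$cells$pet_control, b$cells$pet_patient,
                      b$cells$fmri_control, b$cells$fmri_patient, b$mask)
  res <- factorial_contrasts(des)
  r1 <- res[[1]]
  # identical masks conjoin to themselves
  self <- conjunction_mask(r1, r1)
  expect_equal(self$data, r1$significance_mask$data)
  # disjoint masks conjoin to empty
  r_a <- r1; r_b <- r1
  r_a$significance_mask$data[] <- 0L; r_a$significance_mask$data[1, 1, 1] <- 1L
  r_b$significance_mask$data[] <- 0L; r_b$significance_mask$data[5, 5, 4] <- 1L
  expect_equal(sum(conjunction_mask(r_a, r_b)$data), 0)
})

test_that("cells with fewer than two maps are rejected", {
  b <- build_design(n_per_cell = 2, d = c(4, 4, 3), seed = 7)
  des <- group_design(b$cells$pet_control[1], b$cells$pet_patient,
                      b$cells$fmri_control, b$cells$fmri_patient, b$mask)
  expect_error(factorial_contrasts(des), "pet_control")
})
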