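test_that("ROC-AUC matches hand-worked and degenerate cases", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("ROC-AUC equals exhaustive pairwise counting with ties at one half", {
  set.seed(20)
  pairwise_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    gr <- outer(pos, neg, ">")
    eq <- outer(pos, neg, "==")
    (sum(gr) + 0.5 * sum(eq)) / (length(pos) * length(neg))
  }
  for (i in 1:50) {
    n <- sample(5:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE) # ties likely
    expect_equal(roc_auc(s, y), pairwise_auc(s, y))
  }
})

test_that("parameter grids have the documented sizes", {
  rbf <- neurotot:::svm_param_grid("RBF", -1:8, seq(0.1, 1, by = 0.1))
  expect_equal(nrow(rbf), 100)
  lin <- neurotot:::svm_param_grid("LIN", -1:8, seq(0.1, 1, by = 0.1))
  expect_equal(nrow(lin), 10)
})

test_that("the dual coordinate-descent solver agrees with libsvm", {
  set.seed(21)
  n <- 160; p <- 6
  x <- matrix(rnorm(n * p), n, p)
  y <- factor(rep(c("neuronal", "non_neuronal"), each = n / 2))
  x[y == "neuronal", ] <- x[y == "neuronal", ] + 0.8
  xs <- scale(x)
  yn <- ifelse(y == "neuronal", 1, -1)

  oriented_dv <- function(m) {
    dv <- attr(predict(m, xs, decision.values = TRUE), "decision.values")
    if (strsplit(colnames(dv), "/")[[1]][1] != "neuronal") dv <- -dv
    as.vector(dv)
  }
  fit_l <- neurotot:::svm_fit_lin(xs, yn, C = 1, seed = 1, eps = 1e-4, max_epochs = 2000)
  dec_l <- neurotot:::svm_decision_lin(fit_l, xs)
  ref_l <- oriented_dv(e1071::svm(xs, y, kernel = "linear", cost = 1, scale = FALSE))
  expect_gt(cor(dec_l, ref_l), 0.999)
  expect_equal(mean((dec_l > 0) == (ref_l > 0)), 1)

  K <- exp(-0.4 * neurotot:::sqdist(xs, xs)) + 1
  al <- neurotot:::svm_fit_rbf_path(K, yn, 1, seed = 1, eps = 1e-4, max_epochs = 2000)[, 1]
  dec_r <- as.vector(K %*% (al * yn))
  ref_r <- oriented_dv(e1071::svm(xs, y, kernel = "radial", gamma = 0.4, cost = 1,
                                  scale = FALSE))
  expect_gt(cor(dec_r, ref_r), 0.999)
  expect_equal(roc_auc(dec_r, y), roc_auc(ref_r, y), tolerance = 1e-3)
})

test_that("nested LOO-CV keeps subjects apart and is deterministic", {
  corp <- make_fingerprint_corpus(n_subjects = 6, n_components_per_subject = 12,
                                  class_separation = 2.5, seed = 30)
  fit1 <- fit_nested_loocv(corp, kernels = "RBF", c_grid_log10 = c(0, 2),
                           gamma_grid = c(0.2, 0.6), seed = 9)
  fit2 <- fit_nested_loocv(corp, kernels = "RBF", c_grid_log10 = c(0, 2),
                           gamma_grid = c(0.2, 0.6), seed = 9)
  expect_identical(fit1$cv$RBF$per_fold_auc, fit2$cv$RBF$per_fold_auc)
  expect_identical(fit1$cv$RBF$selected_params_per_fold,
                   fit2$cv$RBF$selected_params_per_fold)
  expect_identical(fit1$C, fit2$C)

  fa <- fit1$cv$RBF$fold_assignments
  expect_equal(nrow(fa), 6) # one outer fold per subject
  expect_true(all(table(fa$subject_id) == 1)) # no subject in two folds
  expect_equal(sort(unique(fa$subject_id)), sort(unique(corp$subject_id)))
  # undefined samples never enter fitting
  expect_equal(fit1$n_samples, sum(corp$label != "undefined"))
})

test_that("prediction is stateless, resubstitution-sane and NA-guarded", {
  corp <- make_fingerprint_corpus(n_subjects = 6, n_components_per_subject = 12,
                                  class_separation = 3, seed = 31)
  fit <- fit_nested_loocv(corp, kernels = "RBF", c_grid_log10 = c(0, 2),
                          gamma_grid = c(0.2, 0.6), seed = 9)
  lab <- corp$label[corp$label != "undefined"]
  train <- corp[corp$label != "undefined", ]
  pred <- predict(fit, train)
  expect_gte(mean(pred == lab), fit$cv$RBF$mean_auc - 0.1) # resubstitution bound direction

  idx <- sample(nrow(train))
  pred_perm <- predict(fit, train[idx, ])
  expect_identical(pred_perm, pred[idx])

  bad <- train[1:2, ]
  bad$kurtosis[2] <- NA
  expect_error(predict(fit, bad), "component\\(s\\): 2")
})

test_that("a single-class subject's outer fold is excluded with a warning", {
  corp <- make_fingerprint_corpus(n_subjects = 5, n_components_per_subject = 8,
                                  class_separation = 3, seed = 33)
  one <- unique(corp$subject_id)[1]
  corp$label[corp$subject_id == one] <- "neuronal"
  expect_warning(
    fit <- fit_nested_loocv(corp, kernels = "RBF", c_grid_log10 = c(0, 2),
                            gamma_grid = c(0.3), seed = 2),
    "single class"
  )
  expect_true(is.na(fit$cv$RBF$per_fold_auc[one]))
  expect_equal(sum(!is.na(fit$cv$RBF$per_fold_auc)), 4)
})

test_that("label permutation within subjects destroys the signal", {
  corp <- make_fingerprint_corpus(n_subjects = 8, n_components_per_subject = 14,
                                  class_separation = 3, seed = 34)
  set.seed(77)
  for (s in unique(corp$subject_id)) {
    rows <- which(corp$subject_id == s)
    corp$label[rows] <- sample(corp$label[rows])
  }
  fit <- suppressWarnings(
    fit_nested_loocv(corp, kernels = "RBF", c_grid_log10 = c(0, 2, 4),
                     gamma_grid = c(0.2, 0.6), seed = 3)
  )
  expect_gte(fit$cv$RBF$mean_auc, 0.35)
  expect_lte(fit$cv$RBF$mean_auc, 0.65)
})
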