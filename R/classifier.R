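#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' positive sample scores above a randomly chosen negative one, with ties
#' counted one half.
#'
#' @param scores numeric decision scores.
#' @param binary_labels labels with exactly two classes; `1`/`TRUE`/
#'   `"neuronal"` is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, binary_labels) {
  lab <- as.character(binary_labels)
  classes <- unique(lab)
  if (length(classes) != 2) {
    stop("AUC needs both classes present (found ", length(classes), ")")
  }
  positive <- if ("neuronal" %in% classes) "neuronal" else {
    if (all(classes %in% c("0", "1"))) "1" else if (all(classes %in% c("TRUE", "FALSE"))) "TRUE"
    else sort(classes)[2]
  }
  pos <- lab == positive
  r <- rank(scores)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# --- SVM engine -------------------------------------------------------------
# Dual coordinate-descent L1-loss SVM (compiled); the bias is regularized by
# feature/kernel augmentation. Labels: +1 = neuronal, -1 = non_neuronal.

svm_label_num <- function(label) ifelse(label == "neuronal", 1, -1)

sqdist <- function(a, b) {
  # rows of a vs rows of b
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

svm_fit_lin <- function(x, y_num, C, seed = 1, eps = 1e-2, max_epochs = 300) {
  xb <- cbind(x, 1)
  fit <- .cpp_linsvm_cd(xb, y_num, C, eps, max_epochs, seed)
  list(kernel = "LIN", w = fit$w, C = C)
}

# Path version: one fit per C on a fixed Gram matrix with warm starts.
svm_fit_rbf_path <- function(K_aug, y_num, Cs, seed = 1, eps = 1e-2, max_epochs = 300) {
  .cpp_ksvm_cd_path(K_aug, y_num, Cs, eps, max_epochs, seed)$alpha
}

svm_decision_lin <- function(fit, x) as.vector(cbind(x, 1) %*% fit$w)

# --- Grid search machinery --------------------------------------------------

svm_param_grid <- function(kernel, c_grid_log10, gamma_grid) {
  Cs <- 10^sort(c_grid_log10)
  if (kernel == "LIN") {
    data.frame(C = Cs, gamma = NA_real_)
  } else {
    expand.grid(C = Cs, gamma = gamma_grid)[, c("C", "gamma")]
  }
}

standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(std, x) {
  sweep(sweep(x, 2, std$center), 2, std$scale, "/")
}

# Decision scores of every grid point for one train/test split.
# Returns a matrix n_test x n_combos, columns in grid order.
grid_decisions <- function(x_tr, y_tr, x_te, kernel, Cs, gamma_grid, seed) {
  y_num <- svm_label_num(y_tr)
  res <- if (kernel == "LIN") {
    do.call(cbind, lapply(Cs, function(C) {
      svm_decision_lin(svm_fit_lin(x_tr, y_num, C, seed = seed), x_te)
    }))
  } else {
    D_tr <- sqdist(x_tr, x_tr)
    D_te <- sqdist(x_te, x_tr)
    do.call(cbind, lapply(gamma_grid, function(g) {
      K_aug <- exp(-g * D_tr) + 1
      alpha <- svm_fit_rbf_path(K_aug, y_num, Cs, seed = seed)
      (exp(-g * D_te) + 1) %*% (alpha * y_num)
    }))
  }
  matrix(res, nrow = nrow(x_te))
}

#' Fit the neuronal/non-neuronal SVM with nested leave-one-subject-out CV
#'
#' "undefined" samples are excluded from all fitting and scoring. The outer
#' loop holds out one subject at a time; the inner loop leave-one-subject-out
#' over the remaining subjects selects the regularization C (and, for the
#' RBF kernel, gamma) maximizing the mean inner ROC-AUC, with ties broken
#' toward the smallest C then the smallest gamma. Outer AUC is computed on
#' the held-out subject's components; folds whose test subject carries only
#' one class are excluded with a warning. Features are standardized with
#' training-fold statistics only. The deployed model is refit on all
#' non-undefined samples with the modal selected parameters of the winning
#' kernel (the one with the higher mean outer AUC).
#'
#' @param corpus a `data.frame` with columns `subject_id`, `label`
#'   (neuronal / non_neuronal / undefined) and the fingerprint features
#'   (see [fingerprint_feature_names()]).
#' @param kernels subset of `c("LIN", "RBF")`.
#' @param c_grid_log10 integer exponents of the C grid, default `-1:8`.
#' @param gamma_grid RBF gamma grid, default `seq(0.1, 1, by = 0.1)`.
#' @param seed integer seed (solver permutation streams).
#' @param feature_names columns used as features.
#' @return An object of class `neuronal_svm` with the fitted deployment
#'   model and one CV report per kernel (`$cv`), each with `per_fold_auc`,
#'   `mean_auc`, `auc_sd`, `selected_params_per_fold`, `fold_assignments`.
#' @export
fit_nested_loocv <- function(corpus, kernels = c("LIN", "RBF"),
                             c_grid_log10 = -1:8,
                             gamma_grid = seq(0.1, 1, by = 0.1),
                             seed = 1,
                             feature_names = fingerprint_feature_names()) {
  kernels <- match.arg(kernels, several.ok = TRUE)
  stopifnot(all(c("subject_id", "label") %in% names(corpus)))
  missing_feats <- setdiff(feature_names, names(corpus))
  if (length(missing_feats)) stop("corpus lacks feature columns: ",
                                  paste(missing_feats, collapse = ", "))
  keep <- corpus$label %in% c("neuronal", "non_neuronal")
  data <- corpus[keep, , drop = FALSE]
  subjects <- unique(data$subject_id)
  if (length(subjects) < 3) stop("need at least 3 subjects with labeled components")
  if (length(unique(data$label)) < 2) stop("need both classes after dropping undefined samples")

  X <- as.matrix(data[, feature_names, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite feature values in the corpus")
  y <- data$label
  subj <- data$subject_id
  Cs <- 10^sort(c_grid_log10)

  reports <- list()
  for (kernel in kernels) {
    grid <- svm_param_grid(kernel, c_grid_log10, gamma_grid)
    per_fold_auc <- rep(NA_real_, length(subjects))
    sel <- grid[0, ]
    for (oi in seq_along(subjects)) {
      s_out <- subjects[oi]
      rest_subj <- setdiff(subjects, s_out)
      # Inner leave-one-subject-out over the remaining subjects.
      auc_sum <- rep(0, nrow(grid))
      auc_n <- rep(0L, nrow(grid))
      for (v in rest_subj) {
        tr <- subj %in% setdiff(rest_subj, v)
        va <- subj == v
        if (length(unique(y[va])) < 2) next
        std <- standardizer(X[tr, , drop = FALSE])
        dec <- grid_decisions(apply_standardizer(std, X[tr, , drop = FALSE]), y[tr],
                              apply_standardizer(std, X[va, , drop = FALSE]),
                              kernel, Cs, gamma_grid, seed)
        aucs <- apply(dec, 2, roc_auc, binary_labels = y[va])
        auc_sum <- auc_sum + aucs
        auc_n <- auc_n + 1L
      }
      mean_inner <- auc_sum / pmax(auc_n, 1L)
      # Tie-break: highest AUC, then smallest C, then smallest gamma.
      best <- order(-mean_inner, grid$C, grid$gamma)[1]
      sel <- rbind(sel, grid[best, ])
      # Outer fold: train on all remaining subjects, score the held-out one.
      tr <- subj %in% rest_subj
      te <- subj == s_out
      if (length(unique(y[te])) < 2) {
        warning("outer fold for subject ", s_out,
                " has a single class; its AUC is undefined and excluded")
        next
      }
      std <- standardizer(X[tr, , drop = FALSE])
      dec <- grid_decisions(apply_standardizer(std, X[tr, , drop = FALSE]), y[tr],
                            apply_standardizer(std, X[te, , drop = FALSE]),
                            kernel, grid$C[best],
                            if (kernel == "RBF") grid$gamma[best] else gamma_grid, seed)
      per_fold_auc[oi] <- roc_auc(dec[, 1], y[te])
    }
    if (all(is.na(per_fold_auc))) stop("all outer folds were undefined; cannot evaluate")
    reports[[kernel]] <- list(
      kernel = kernel,
      per_fold_auc = stats::setNames(per_fold_auc, subjects),
      mean_auc = mean(per_fold_auc, na.rm = TRUE),
      auc_sd = sd(per_fold_auc, na.rm = TRUE),
      selected_params_per_fold = sel,
      fold_assignments = data.frame(subject_id = subjects, fold = seq_along(subjects))
    )
  }

  winning <- kernels[which.max(vapply(reports, `[[`, numeric(1), "mean_auc"))]
  sel <- reports[[winning]]$selected_params_per_fold
  key <- paste(sel$C, sel$gamma)
  tab <- table(key)
  modal_keys <- names(tab)[tab == max(tab)]
  modal_rows <- sel[match(modal_keys, key), , drop = FALSE]
  modal <- modal_rows[order(modal_rows$C, modal_rows$gamma)[1], ]

  std <- standardizer(X)
  Xs <- apply_standardizer(std, X)
  y_num <- svm_label_num(y)
  fit <- if (winning == "LIN") {
    svm_fit_lin(Xs, y_num, modal$C, seed = seed)
  } else {
    K_aug <- exp(-modal$gamma * sqdist(Xs, Xs)) + 1
    alpha <- svm_fit_rbf_path(K_aug, y_num, modal$C, seed = seed)[, 1]
    list(kernel = "RBF", alpha = alpha, x_train = Xs, y_num = y_num, gamma = modal$gamma)
  }
  structure(list(
    kernel = winning, C = modal$C,
    gamma = if (winning == "RBF") modal$gamma else NA_real_,
    feature_names = feature_names, standardization = std, fit = fit,
    cv = reports, n_subjects = length(subjects), n_samples = nrow(X), seed = seed
  ), class = "neuronal_svm")
}

svm_decision <- function(object, x_std) {
  if (object$fit$kernel == "LIN") {
    svm_decision_lin(object$fit, x_std)
  } else {
    K <- exp(-object$fit$gamma * sqdist(x_std, object$fit$x_train)) + 1
    as.vector(K %*% (object$fit$alpha * object$fit$y_num))
  }
}

#' Predict component labels from fingerprints
#'
#' @param object a fitted `neuronal_svm`.
#' @param newdata a `data.frame` (or matrix) containing the model's feature
#'   columns; one row per component.
#' @param type `"class"` for neuronal / non_neuronal labels (decision
#'   threshold 0) or `"decision"` for signed distances to the boundary.
#' @param ... unused.
#' @return Character vector of labels, or numeric decision values.
#' @export
predict.neuronal_svm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  x <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  bad <- which(!stats::complete.cases(x) | apply(x, 1, function(r) any(!is.finite(r))))
  if (length(bad)) {
    stop("non-finite fingerprint feature(s) for component(s): ",
         paste(bad, collapse = ", "))
  }
  dec <- svm_decision(object, apply_standardizer(object$standardization, x))
  if (type == "decision") dec else ifelse(dec > 0, "neuronal", "non_neuronal")
}

#' @export
print.neuronal_svm <- function(x, ...) {
  cat("Neuronal-component SVM (", x$kernel, " kernel)\n", sep = "")
  cat("  C = ", format(x$C), if (!is.na(x$gamma)) paste0(", gamma = ", format(x$gamma)),
      "\n", sep = "")
  cat("  trained on ", x$n_samples, " labeled components from ", x$n_subjects,
      " subjects\n", sep = "")
  for (k in names(x$cv)) {
    cat(sprintf("  %s nested LOO-CV AUC: %.3f +/- %.3f (%d folds)\n", k,
                x$cv[[k]]$mean_auc, x$cv[[k]]$auc_sd,
                sum(!is.na(x$cv[[k]]$per_fold_auc))))
  }
  invisible(x)
}

#' @export
summary.neuronal_svm <- function(object, ...) {
  print(object)
  cat("\nSelected parameters per outer fold (winning kernel):\n")
  print(object$cv[[object$kernel]]$selected_params_per_fold, row.names = FALSE)
  invisible(object)
}

#' Serialize / restore a trained classifier as versioned JSON
#'
#' Stores the kernel, regularization parameters, feature standardization
#' statistics and the support data needed for prediction (the linear weight
#' vector, or the dual coefficients with their standardized training
#' features) in a plain-text JSON document.
#'
#' @param object a fitted `neuronal_svm`.
#' @param path output / input file path.
#' @return [read_classifier()] returns a `neuronal_svm` usable with
#'   [predict.neuronal_svm()]; `write_classifier` returns `path` invisibly.
#' @export
write_classifier <- function(object, path) {
  stopifnot(inherits(object, "neuronal_svm"))
  payload <- list(
    format = "neurotot_svm", version = 1L,
    kernel = object$kernel, C = object$C, gamma = object$gamma,
    feature_names = object$feature_names,
    standardization = object$standardization,
    cv_mean_auc = lapply(object$cv, `[[`, "mean_auc")
  )
  if (object$kernel == "LIN") {
    payload$w <- object$fit$w
  } else {
    payload$alpha <- object$fit$alpha
    payload$y_num <- object$fit$y_num
    payload$x_train <- object$fit$x_train
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "neurotot_svm")) stop("not a serialized classifier: ", path)
  fit <- if (p$kernel == "LIN") {
    list(kernel = "LIN", w = p$w, C = p$C)
  } else {
    list(kernel = "RBF", alpha = p$alpha, y_num = p$y_num,
         x_train = as.matrix(p$x_train), gamma = p$gamma)
  }
  structure(list(
    kernel = p$kernel, C = p$C, gamma = p$gamma %||% NA_real_,
    feature_names = p$feature_names,
    standardization = list(center = unlist(p$standardization$center),
                           scale = unlist(p$standardization$scale)),
    fit = fit, cv = NULL, n_subjects = NA_integer_, n_samples = NA_integer_
  ), class = "neuronal_svm")
}
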