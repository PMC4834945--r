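# Shared fixtures, all generated in code.

# Small, fast phantom used by most unit tests (full-size phantoms are
# exercised in the acceptance suite).
small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(grid_shape = c(14, 14, 10), n_frames = 120, n_neuronal = 3,
         n_artifact = 2, noise_sd = 0.1, seed = seed),
    list(...)
  )
  do.call(phantom_spec, args)
}

# A tiny hand-built decomposition whose z "maps" are arbitrary vectors laid
# out on an n x 1 x 1 grid; enough structure for total-map arithmetic.
toy_decomposition <- function(zvals_list, mask_vals = NULL) {
  n <- length(zvals_list[[1]])
  aff <- diag(c(3, 3, 3, 1))
  mask_vals <- mask_vals %||% rep(1L, n)
  mask <- mask_volume(array(mask_vals, c(n, 1, 1)), affine = aff)
  structure(list(
    spatial_zmaps = lapply(zvals_list, function(v) {
      volume3d(array(v, c(n, 1, 1)), affine = aff)
    }),
    timecourses = matrix(rnorm(20 * length(zvals_list)), 20),
    mask = mask, tr_s = 2, n_components = length(zvals_list)
  ), class = "ic_decomposition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive best-assignment oracle: maximize total |correlation| over all
# permutations mapping references to components (sign-blind).
exhaustive_match <- function(decomposition, reference_maps) {
  m <- decomposition$mask$data == 1L
  comp <- sapply(decomposition$spatial_zmaps, function(z) z$data[m])
  ref <- sapply(reference_maps, function(r) r$data[m])
  cc <- abs(cor(ref, comp))
  n <- ncol(ref)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL; best_val <- -Inf
  for (p in perms(seq_len(n))) {
    val <- sum(cc[cbind(seq_len(n), p)])
    if (val > best_val) { best_val <- val; best <- p }
  }
  cc[cbind(seq_len(n), best)]
}

# Dice coefficient of two binary 3-D arrays.
dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
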