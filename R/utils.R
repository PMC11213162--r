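# shared internal helpers

# symmetric to machine-ish tolerance; features and spectra assume this
check_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("%s must be a square matrix", what))
  }
  if (max(abs(m - t(m))) > tol) {
    abort(sprintf("%s must be symmetric (tolerance %g)", what, tol))
  }
  invisible(m)
}

check_fc <- function(fc) {
  check_symmetric(fc, tol = 1e-10, what = "FC matrix")
  if (any(!is.finite(fc))) abort("FC matrix contains non-finite entries")
  if (any(abs(diag(fc)) > 1e-12)) {
    abort("FC matrix must have a zero diagonal")
  }
  invisible(fc)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == floor(x) && x >= min
}

upper_tri_pairs <- function(m) {
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  tibble(roi_i = idx[, "row"], roi_j = idx[, "col"])
}
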