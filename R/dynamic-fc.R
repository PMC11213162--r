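#' Build the tapered sliding-window weight vector
#'
#' The window taper is the discrete convolution of a unit rectangle of
#' `rect_width` samples with a Gaussian kernel of standard deviation
#' `gauss_sigma` samples, truncated at +/- 4 sigma and normalized to sum to 1.
#' With the defaults (rectangle of 50 TRs, sigma = 3 TRs) the taper spans
#' 50 + 2 * ceiling(12) = 74 TRs.
#'
#' @param rect_width Rectangle width in samples (TRs); >= 2.
#' @param gauss_sigma Gaussian standard deviation in samples; > 0.
#' @return An object of class `gfc_taper`: list with `weights` (sums to 1)
#'   and the defining parameters.
#' @export
build_taper <- function(rect_width = 50, gauss_sigma = 3) {
  if (!is_count(rect_width, 2)) abort("rect_width must be an integer >= 2")
  if (!(is.numeric(gauss_sigma) && gauss_sigma > 0)) {
    abort("gauss_sigma must be > 0")
  }
  half <- ceiling(4 * gauss_sigma)
  kern <- dnorm(seq(-half, half), sd = gauss_sigma)
  w <- as.numeric(stats::convolve(rep(1, rect_width), rev(kern),
                                  type = "open"))
  w <- pmax(w, 0)
  w <- w / sum(w)
  structure(list(weights = w, width_tr = length(w),
                 rect_width = rect_width, gauss_sigma = gauss_sigma),
            class = "gfc_taper")
}

#' @export
print.gfc_taper <- function(x, ...) {
  cat(sprintf("<gfc_taper> %d TRs (rect %d * gaussian sigma %g)\n",
              x$width_tr, x$rect_width, x$gauss_sigma))
  invisible(x)
}

# weighted Pearson correlation matrix of the rows of x, weights w (sum 1);
# ROIs with (weighted) variance <= eps get NA rows/columns
weighted_cor <- function(x, w, eps = 1e-12) {
  mu <- as.numeric(x %*% w)
  xc <- (x - mu) * rep(sqrt(w), each = nrow(x))
  cv <- tcrossprod(xc)
  v <- diag(cv)
  bad <- v <= eps
  s <- sqrt(pmax(v, eps))
  r <- cv / outer(s, s)
  r[bad, ] <- NA_real_
  r[, bad] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  d <- diag(r)
  d[!bad] <- 1
  diag(r) <- d
  r
}

#' Median-aggregated tapered sliding-window functional connectivity
#'
#' Slides the taper across the time axis with a `shift`-TR step (only fully
#' contained windows are used, giving `floor((T - W) / shift) + 1` windows),
#' computes the taper-weighted Pearson correlation between every ROI pair in
#' each window, and aggregates each pair across windows by the median. The
#' diagonal of the result is set to zero.
#'
#' Windows in which an ROI has zero weighted variance contribute no
#' correlation for pairs involving that ROI (they are excluded from the
#' median). If every window is excluded for some pair the correlation is
#' undefined: by default this is an error; `undefined = "zero"` instead
#' records 0 for such pairs with a warning (used by the pipeline for
#' degenerate band-filtered signals, e.g. an ROI isolated in the sparse
#' adjacency whose band projection is identically zero).
#'
#' @param x An M x T numeric matrix of ROI time series (rows = ROIs), or a
#'   one-row cohort tibble's `data` entry.
#' @param taper A [build_taper()] object.
#' @param shift Window shift in TRs (default 1).
#' @param undefined Policy for pairs with no defined window: `"error"` or
#'   `"zero"`.
#' @return An M x M symmetric matrix with zero diagonal and entries in
#'   \[-1, 1\].
#' @export
sliding_window_fc <- function(x, taper, shift = 1,
                              undefined = c("error", "zero")) {
  undefined <- match.arg(undefined)
  stopifnot(inherits(taper, "gfc_taper"), is.matrix(x))
  w <- taper$weights
  W <- length(w)
  Tn <- ncol(x)
  if (Tn < W) {
    abort(sprintf("series length %d is shorter than the taper width %d",
                  Tn, W))
  }
  if (!is_count(shift, 1)) abort("shift must be a positive integer")
  starts <- seq(1, Tn - W + 1, by = shift)
  m <- nrow(x)
  acc <- array(NA_real_, c(m, m, length(starts)))
  for (k in seq_along(starts)) {
    s <- starts[k]
    acc[, , k] <- weighted_cor(x[, s:(s + W - 1), drop = FALSE], w)
  }
  fc <- apply(acc, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    median(v)
  })
  if (any(is.na(fc[upper.tri(fc)]))) {
    if (undefined == "error") {
      abort("some ROI pair has no window with defined correlation")
    }
    warn(sprintf(
      "%d ROI pair(s) have no window with defined correlation; set to 0",
      sum(is.na(fc[upper.tri(fc)]))))
    fc[is.na(fc)] <- 0
  }
  diag(fc) <- 0
  (fc + t(fc)) / 2
}

#' Sliding-window FC for every subject of a cohort
#'
#' @param cohort A cohort tibble (see [generate_cohort()]) or any tibble with
#'   `subject_id`, `group` and a list-column of M x T matrices named by
#'   `data_col`.
#' @param taper A [build_taper()] object.
#' @param shift Window shift in TRs.
#' @param band Band label attached to the output rows (default `"FFB"`).
#' @param data_col Name of the list-column holding the time-series matrices.
#' @return A tibble `subject_id`, `group`, `band`, `fc` (list of M x M
#'   matrices).
#' @export
cohort_fc <- function(cohort, taper = build_taper(), shift = 1,
                      band = "FFB", data_col = "data") {
  tibble(subject_id = cohort$subject_id, group = cohort$group, band = band,
         fc = map(cohort[[data_col]], sliding_window_fc, taper = taper,
                  shift = shift))
}

#' Group-informed sparse FC adjacency
#'
#' For every upper-triangle edge, the full-band FC values of the two groups
#' are compared with a two-sided Wilcoxon rank-sum test; edges with
#' `p < alpha` (optionally after Benjamini-Hochberg adjustment) form a mask
#' shared by all subjects. Each subject's sparse adjacency keeps its own FC
#' values on masked edges and is exactly zero elsewhere — this per-subject
#' sparse FC is the adjacency used for graph spectral analysis.
#'
#' @param fcs_a,fcs_b Lists of same-sized symmetric FC matrices (group A / B),
#'   each of length >= 2.
#' @param alpha Significance level (default 0.05, uncorrected).
#' @param fdr If `TRUE`, apply Benjamini-Hochberg adjustment before
#'   thresholding.
#' @return A list with `mask` (M x M logical, symmetric, FALSE diagonal),
#'   `tests` (tibble `roi_i`, `roi_j`, `statistic`, `p`), and `sparse_a`,
#'   `sparse_b` (lists of per-subject masked adjacencies).
#' @export
group_sparse_adjacency <- function(fcs_a, fcs_b, alpha = 0.05, fdr = FALSE) {
  if (length(fcs_a) < 2 || length(fcs_b) < 2) {
    abort("both groups need at least 2 subjects")
  }
  m <- nrow(fcs_a[[1]])
  ok <- all(map_lgl(c(fcs_a, fcs_b),
                    function(f) nrow(f) == m && ncol(f) == m))
  if (!ok) abort("all FC matrices must have identical dimensions")
  pairs <- upper_tri_pairs(m)
  edge_vals <- function(fcs, i, j) map_dbl(fcs, function(f) f[i, j])
  res <- pmap(pairs, function(roi_i, roi_j) {
    a <- edge_vals(fcs_a, roi_i, roi_j)
    b <- edge_vals(fcs_b, roi_i, roi_j)
    if (length(unique(c(a, b))) == 1) {
      c(statistic = NA_real_, p = 1)
    } else {
      ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
      c(statistic = unname(ht$statistic), p = unname(ht$p.value))
    }
  })
  tests <- mutate(pairs,
                  statistic = map_dbl(res, "statistic"),
                  p = map_dbl(res, "p"))
  p_use <- if (fdr) p.adjust(tests$p, method = "BH") else tests$p
  mask <- matrix(FALSE, m, m)
  sig <- which(p_use < alpha)
  for (k in sig) {
    mask[tests$roi_i[k], tests$roi_j[k]] <- TRUE
    mask[tests$roi_j[k], tests$roi_i[k]] <- TRUE
  }
  sparsify <- function(f) {
    out <- f * mask
    out
  }
  list(mask = mask, tests = tests,
       sparse_a = map(fcs_a, sparsify), sparse_b = map(fcs_b, sparsify))
}
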