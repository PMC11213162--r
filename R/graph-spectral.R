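#' Combinatorial graph Laplacian
#'
#' `L = D - A`, where `D` is the diagonal degree (strength) matrix
#' `D_kk = sum_j A_kj`. The sparse FC adjacency carries signed correlations;
#' by default their absolute values are used so the Laplacian is positive
#' semi-definite and the low/high graph-frequency ordering of its eigenvalues
#' is well defined. Set `signed = TRUE` to use the raw signed weights.
#'
#' @param adjacency Symmetric M x M matrix with zero diagonal.
#' @param signed Use signed weights as-is instead of their magnitudes.
#' @return The M x M Laplacian (rows sum to zero by construction).
#' @export
graph_laplacian <- function(adjacency, signed = FALSE) {
  check_symmetric(adjacency, tol = 1e-10, what = "adjacency")
  if (any(abs(diag(adjacency)) > 1e-12)) {
    abort("adjacency must have a zero diagonal")
  }
  a <- if (signed) adjacency else abs(adjacency)
  diag(rowSums(a)) - a
}

#' Eigendecompose a graph Laplacian into a graph spectrum
#'
#' Full symmetric eigendecomposition with eigenvalues in ascending order, so
#' the leading columns of the eigenvector matrix are the low graph-frequency
#' modes (smooth over the graph) and trailing columns the high-frequency
#' modes. A deterministic sign convention is applied: in each eigenvector the
#' entry of largest magnitude (first such index on ties) is made positive.
#'
#' For a non-negatively weighted connected graph the smallest eigenvalue is 0
#' with a constant eigenvector; one near-zero eigenvalue appears per connected
#' component, and a disconnected adjacency triggers a warning with the
#' component count.
#'
#' @param laplacian Symmetric M x M Laplacian matrix.
#' @return An object of class `gfc_spectrum`: list with `vectors` (M x M
#'   orthonormal, columns = modes), `values` (non-decreasing) and `n_modes`.
#' @export
graph_spectrum <- function(laplacian) {
  check_symmetric(laplacian, tol = 1e-8, what = "laplacian")
  if (any(!is.finite(laplacian))) abort("laplacian has non-finite entries")
  dec <- eigen(laplacian, symmetric = TRUE)
  ord <- rev(seq_along(dec$values))  # eigen() returns decreasing order
  values <- dec$values[ord]
  vectors <- dec$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(vectors))) {
    v <- vectors[, k]
    i <- which.max(abs(v))
    if (v[i] < 0) vectors[, k] <- -v
  }
  n_zero <- sum(abs(values) < 1e-8)
  if (n_zero > 1) {
    warn(sprintf(
      "graph has %d near-zero Laplacian eigenvalues (disconnected: %d components)",
      n_zero, n_zero))
  }
  structure(list(vectors = vectors, values = values,
                 n_modes = length(values)),
            class = "gfc_spectrum")
}

#' @export
print.gfc_spectrum <- function(x, ...) {
  cat(sprintf("<gfc_spectrum> %d modes, eigenvalues [%.3g, %.3g]\n",
              x$n_modes, min(x$values), max(x$values)))
  invisible(x)
}

#' Split graph-frequency modes into low / middle / high bands
#'
#' The low-frequency band (LFB) takes the first `floor(m/3)` modes, the
#' high-frequency band (HFB) the last `floor(m/3)`, and the middle band (MFB)
#' the remainder. For m = 136 ROIs this gives the 45 / 46 / 45 split.
#'
#' @param m Number of modes (ROIs); >= 3.
#' @return An object of class `gfc_bands`: list of mode index vectors
#'   `lfb`, `mfb`, `hfb`.
#' @examples
#' lengths(band_split(136))  # 45 46 45
#' @export
band_split <- function(m) {
  if (!is_count(m, 3)) abort("m must be an integer >= 3")
  k <- floor(m / 3)
  structure(list(lfb = seq_len(k),
                 mfb = seq(k + 1, m - k),
                 hfb = seq(m - k + 1, m)),
            class = "gfc_bands")
}

#' Graph Fourier transform and inverse
#'
#' `gft()` projects an ROI-by-time signal onto the Laplacian eigenvectors
#' (`x_tilde = V' x`); `igft()` reconstructs (`x = V x_tilde`). The transform
#' is orthonormal, so `igft(gft(x))` returns `x` and signal energy is
#' preserved (Parseval).
#'
#' @param x M x T numeric matrix (rows = ROIs / modes).
#' @param spectrum A [graph_spectrum()].
#' @return A matrix of the same dimension.
#' @export
gft <- function(x, spectrum) {
  stopifnot(inherits(spectrum, "gfc_spectrum"))
  x <- as.matrix(x)
  if (nrow(x) != spectrum$n_modes) {
    abort(sprintf("signal has %d rows but the spectrum has %d modes",
                  nrow(x), spectrum$n_modes))
  }
  crossprod(spectrum$vectors, x)
}

#' @rdname gft
#' @export
igft <- function(x, spectrum) {
  stopifnot(inherits(spectrum, "gfc_spectrum"))
  x <- as.matrix(x)
  if (nrow(x) != spectrum$n_modes) {
    abort(sprintf("signal has %d rows but the spectrum has %d modes",
                  nrow(x), spectrum$n_modes))
  }
  spectrum$vectors %*% x
}

#' Band-filter a graph signal
#'
#' Applies `x_F = V G V' x` with `G` diagonal, equal to 1 on the selected
#' band's modes and 0 elsewhere — an orthogonal projection onto the band's
#' eigenspace. The three band projectors (LFB/MFB/HFB) are idempotent and sum
#' to the identity.
#'
#' @param x M x T numeric matrix of ROI time series.
#' @param spectrum A [graph_spectrum()].
#' @param band Either a `gfc_bands` selector name (`"lfb"`, `"mfb"`,
#'   `"hfb"`) together with `bands`, or an explicit integer vector of mode
#'   indices.
#' @param bands A [band_split()] object (defaults to
#'   `band_split(spectrum$n_modes)`).
#' @return The filtered M x T matrix.
#' @export
band_filter <- function(x, spectrum, band, bands = NULL) {
  stopifnot(inherits(spectrum, "gfc_spectrum"))
  if (is.character(band)) {
    bands <- bands %||% band_split(spectrum$n_modes)
    band <- tolower(band)
    if (!band %in% names(bands)) {
      abort(sprintf("unknown band '%s' (use lfb/mfb/hfb or mode indices)",
                    band))
    }
    modes <- bands[[band]]
  } else {
    modes <- as.integer(band)
  }
  if (length(modes) == 0) abort("band has no modes")
  if (any(modes < 1 | modes > spectrum$n_modes)) {
    abort("band mode indices out of range")
  }
  v <- spectrum$vectors[, modes, drop = FALSE]
  v %*% crossprod(v, as.matrix(x))
}
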