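#' Specify a synthetic two-group rs-fMRI cohort
#'
#' A cohort specification captures the acquisition geometry of a resting-state
#' fMRI study (number of ROIs, volumes acquired, initial volumes discarded for
#' T1 equilibration, repetition time, retained BOLD frequency band) together
#' with the generative connectivity model: a base correlation matrix shared by
#' both groups and a set of edges whose correlation is shifted in group B to
#' plant a between-group difference.
#'
#' Group A plays the role of the stable group (e.g. sMCI) and group B the
#' progressive group (e.g. pMCI). Defaults mirror a typical ADNI-style
#' acquisition: 140 volumes at TR = 2 s with the first 5 discarded, signals
#' band-limited to 0.01-0.1 Hz, and group sizes 142 / 136.
#'
#' @param n_group_a,n_group_b Subjects per group.
#' @param n_rois Number of ROIs (M); at least 4.
#' @param n_volumes Volumes generated per subject before discarding.
#' @param n_discard Initial volumes dropped (T = `n_volumes - n_discard`).
#' @param tr_seconds Repetition time in seconds.
#' @param band_hz Length-2 retained frequency band in Hz; must sit strictly
#'   inside (0, Nyquist) with `band_hz[1] < band_hz[2]`.
#' @param base_covariance Either an `n_rois` x `n_rois` correlation matrix
#'   (symmetric, unit diagonal, positive semi-definite) or the name of a
#'   built-in template: `"modular"` (four equal communities, within-module
#'   correlation 0.35, between 0.05) or `"random"` (correlation matrix of a
#'   seeded Wishart draw).
#' @param effect_edges List of length-2 integer vectors: ROI pairs whose
#'   correlation is shifted by `effect_size` in group B.
#' @param effect_size Correlation shift (delta r) applied to `effect_edges`.
#' @param noise_sd Marginal standard deviation of the generated signals.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec (subject i of either group uses seed `seed + i`, so with
#'   `effect_size = 0` the two groups are identical realizations).
#'
#' @return An object of class `gfc_cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_group_a = 142, n_group_b = 136, n_rois = 136,
                        n_volumes = 140, n_discard = 5, tr_seconds = 2,
                        band_hz = c(0.01, 0.1), base_covariance = "modular",
                        effect_edges = list(), effect_size = 0,
                        noise_sd = 1, seed = 1) {
  if (!is_count(n_group_a, 0) || !is_count(n_group_b, 0)) {
    abort("group sizes must be non-negative integers")
  }
  if (!is_count(n_rois, 4)) abort("n_rois must be an integer >= 4")
  if (!is_count(n_volumes, 1) || !is_count(n_discard, 0) ||
      n_volumes <= n_discard) {
    abort("n_volumes must exceed n_discard")
  }
  if (!(is.numeric(tr_seconds) && length(tr_seconds) == 1 && tr_seconds > 0)) {
    abort("tr_seconds must be a positive scalar")
  }
  nyquist <- 1 / (2 * tr_seconds)
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[1] >= band_hz[2] ||
      band_hz[2] >= nyquist) {
    abort(sprintf("band_hz must satisfy 0 < low < high < Nyquist = %g Hz",
                  nyquist))
  }
  if (!(is.numeric(noise_sd) && noise_sd > 0)) abort("noise_sd must be > 0")
  if (!is_count(seed, 0)) abort("seed must be a non-negative integer")

  base <- build_base_covariance(base_covariance, n_rois, seed)
  effect_edges <- lapply(effect_edges, function(e) {
    e <- as.integer(e)
    if (length(e) != 2 || any(e < 1) || any(e > n_rois) || e[1] == e[2]) {
      abort("each effect edge must be a pair of distinct ROI indices <= n_rois")
    }
    sort(e)
  })

  structure(
    list(n_group_a = n_group_a, n_group_b = n_group_b, n_rois = n_rois,
         n_volumes = n_volumes, n_discard = n_discard,
         tr_seconds = tr_seconds, band_hz = band_hz,
         base_covariance = base, effect_edges = effect_edges,
         effect_size = effect_size, noise_sd = noise_sd, seed = seed),
    class = "gfc_cohort_spec"
  )
}

#' @export
print.gfc_cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<gfc_cohort_spec> %d + %d subjects, M = %d ROIs, T = %d (of %d) at TR = %gs\n",
    x$n_group_a, x$n_group_b, x$n_rois, x$n_volumes - x$n_discard,
    x$n_volumes, x$tr_seconds))
  cat(sprintf("  band %g-%g Hz; %d effect edge(s), delta r = %g; seed %d\n",
              x$band_hz[1], x$band_hz[2], length(x$effect_edges),
              x$effect_size, x$seed))
  invisible(x)
}

build_base_covariance <- function(base, m, seed) {
  if (is.character(base) && length(base) == 1) {
    base <- switch(base,
      modular = modular_correlation(m),
      random = random_correlation(m, seed),
      abort(sprintf("unknown base_covariance template '%s'", base))
    )
  }
  check_symmetric(base, tol = 1e-8, what = "base_covariance")
  if (nrow(base) != m) abort("base_covariance dimension must equal n_rois")
  if (max(abs(diag(base) - 1)) > 1e-8) {
    abort("base_covariance must have a unit diagonal")
  }
  ev <- eigen(base, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("base_covariance must be positive semi-definite")
  unname((base + t(base)) / 2)
}

# four equal communities; 0.35 within, 0.05 between
modular_correlation <- function(m, n_modules = 4, within = 0.35,
                                between = 0.05) {
  module <- sort(rep(seq_len(n_modules), length.out = m))
  s <- matrix(between, m, m)
  for (k in seq_len(n_modules)) {
    idx <- which(module == k)
    s[idx, idx] <- within
  }
  diag(s) <- 1
  s
}

random_correlation <- function(m, seed) {
  with_seed(seed, {
    w <- matrix(rnorm(m * 2 * m), m, 2 * m)
    stats::cov2cor(tcrossprod(w))
  })
}

# shift planted edges, then repair to the nearest PSD correlation matrix by
# eigenvalue clipping + re-normalization; refuse if a target moves > 0.02
effect_covariance <- function(spec) {
  s <- spec$base_covariance
  if (length(spec$effect_edges) == 0 || spec$effect_size == 0) return(s)
  targets <- numeric(length(spec$effect_edges))
  for (k in seq_along(spec$effect_edges)) {
    e <- spec$effect_edges[[k]]
    r <- s[e[1], e[2]] + spec$effect_size
    if (abs(r) >= 1) {
      abort(sprintf(
        "effect_size pushes correlation of edge (%d, %d) to %.3f, outside (-1, 1)",
        e[1], e[2], r))
    }
    s[e[1], e[2]] <- s[e[2], e[1]] <- r
    targets[k] <- r
  }
  dec <- eigen(s, symmetric = TRUE)
  if (min(dec$values) < 1e-8) {
    lam <- pmax(dec$values, 1e-8)
    s <- dec$vectors %*% (lam * t(dec$vectors))
    s <- stats::cov2cor(s)
    s <- (s + t(s)) / 2
  }
  dev <- map_dbl(seq_along(spec$effect_edges), function(k) {
    e <- spec$effect_edges[[k]]
    abs(s[e[1], e[2]] - targets[k])
  })
  if (any(dev > 0.02)) {
    bad <- spec$effect_edges[dev > 0.02]
    abort(sprintf(
      "PSD repair moved planted edge(s) %s by more than 0.02 from the requested correlation",
      paste(map_chr(bad, function(e) sprintf("(%d, %d)", e[1], e[2])),
            collapse = ", ")))
  }
  s
}

# zero-phase Butterworth band-pass applied to each ROI series
bandpass_rows <- function(x, band_hz, tr_seconds, order = 4) {
  nyq <- 1 / (2 * tr_seconds)
  bf <- signal::butter(order, band_hz / nyq, type = "pass")
  t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
}

#' Generate a synthetic cohort of ROI time series
#'
#' Each subject's series is filtered Gaussian noise: a white multivariate
#' Gaussian draw with the group correlation matrix imposed by its Cholesky
#' factor, zero-phase band-pass filtered to `band_hz`, after which the first
#' `n_discard` samples are dropped. Because every ROI passes through the same
#' linear filter, the zero-lag correlation structure of the white input is
#' preserved in expectation, so the planted correlations remain the generating
#' truth of the filtered series.
#'
#' Group B's correlation matrix is the base matrix with `effect_edges` shifted
#' by `effect_size` and re-projected to the nearest positive semi-definite
#' correlation matrix (eigenvalue clipping at 1e-8, re-normalized to unit
#' diagonal); generation fails if any planted correlation then deviates from
#' its requested value by more than 0.02, naming the offending edges.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject: `subject_id`, `group` (factor
#'   with levels `"A"`, `"B"`), `data` (list of M x T matrices) and
#'   `tr_seconds`.
#' @examples
#' spec <- cohort_spec(n_group_a = 2, n_group_b = 2, n_rois = 6,
#'                     n_volumes = 60, n_discard = 5, seed = 7)
#' cohort <- generate_cohort(spec)
#' dim(cohort$data[[1]])  # 6 x 55
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "gfc_cohort_spec"))
  sigma_a <- spec$base_covariance
  sigma_b <- effect_covariance(spec)
  gen_group <- function(sigma, n, label) {
    if (n == 0) return(NULL)
    cl <- chol(sigma + diag(1e-10, spec$n_rois))
    rows <- map(seq_len(n), function(i) {
      x <- with_seed(spec$seed + i, {
        z <- matrix(rnorm(spec$n_rois * spec$n_volumes, sd = spec$noise_sd),
                    spec$n_rois, spec$n_volumes)
        crossprod(cl, z)
      })
      x <- bandpass_rows(x, spec$band_hz, spec$tr_seconds)
      x <- x[, (spec$n_discard + 1):spec$n_volumes, drop = FALSE]
      if (any(!is.finite(x))) {
        abort(sprintf("non-finite samples generated for subject %s%03d",
                      label, i))
      }
      if (any(apply(x, 1, stats::sd) <= 0)) {
        abort(sprintf("zero-variance ROI generated for subject %s%03d",
                      label, i))
      }
      unname(x)
    })
    tibble(subject_id = sprintf("%s%03d", label, seq_len(n)),
           group = label, data = rows, tr_seconds = spec$tr_seconds)
  }
  cohort <- bind_rows(gen_group(sigma_a, spec$n_group_a, "A"),
                      gen_group(sigma_b, spec$n_group_b, "B"))
  cohort$group <- factor(cohort$group, levels = c("A", "B"))
  cohort
}

#' Write / read a cohort as plain-text matrix files
#'
#' `write_cohort()` stores one tab-separated matrix file per subject (rows =
#' ROIs, columns = time points, no header, full double precision), a
#' two-column label table `labels.tsv` (`subject_id`, `group`) and a JSON
#' manifest listing the files and geometry. `read_cohort()` inverts it;
#' `read_cohort(write_cohort(x))` reproduces the data exactly.
#'
#' @param cohort A cohort tibble as returned by [generate_cohort()].
#' @param directory Target / source directory.
#' @return `write_cohort()` returns the manifest path invisibly;
#'   `read_cohort()` returns a cohort tibble.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- map_chr(cohort$subject_id, function(id) paste0(id, ".tsv"))
  walk(seq_len(nrow(cohort)), function(i) {
    m <- cohort$data[[i]]
    lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = "\t"))
    writeLines(lines, file.path(directory, files[i]))
  })
  readr::write_tsv(
    tibble(subject_id = cohort$subject_id,
           group = as.character(cohort$group)),
    file.path(directory, "labels.tsv"), col_names = FALSE)
  manifest <- list(
    files = as.list(setNames(files, cohort$subject_id)),
    n_rois = nrow(cohort$data[[1]]),
    n_timepoints = ncol(cohort$data[[1]]),
    tr_seconds = cohort$tr_seconds[1])
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"))
  labels <- readr::read_tsv(
    file.path(directory, "labels.tsv"),
    col_names = c("subject_id", "group"), col_types = "cc",
    progress = FALSE)
  bad <- setdiff(unique(labels$group), c("A", "B"))
  if (length(bad)) {
    abort(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")))
  }
  data <- map(labels$subject_id, function(id) {
    f <- manifest$files[[id]]
    if (is.null(f) || !file.exists(file.path(directory, f))) {
      abort(sprintf("manifest lists no readable file for subject %s (%s)",
                    id, f %||% "missing entry"))
    }
    m <- read_matrix_tsv(file.path(directory, f))
    if (nrow(m) != manifest$n_rois || ncol(m) != manifest$n_timepoints) {
      abort(sprintf("file for subject %s has shape %dx%d, manifest says %dx%d",
                    id, nrow(m), ncol(m), manifest$n_rois,
                    manifest$n_timepoints))
    }
    m
  })
  tibble(subject_id = labels$subject_id,
         group = factor(labels$group, levels = c("A", "B")),
         data = data,
         tr_seconds = as.numeric(manifest$tr_seconds))
}
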