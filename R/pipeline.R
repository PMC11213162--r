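# end-to-end orchestration: simulate -> fc -> gsp -> features -> classify ->
# report, with every intermediate persisted as plain text in the run
# directory so stages are idempotent and re-runnable in isolation.

write_matrix_tsv <- function(m, path) {
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = "\t")), path)
}

# scan() parses via strtod and round-trips %.17g output exactly
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  m <- do.call(rbind, lapply(lines, function(l) {
    scan(text = l, sep = "\t", quiet = TRUE)
  }))
  dimnames(m) <- NULL
  m
}

#' Pipeline run configuration
#'
#' Bundles every stage's parameters. The default synthetic cohort is small
#' (20 ROIs, 30 + 30 subjects) so a full run finishes in a few minutes;
#' study-scale geometry (136 ROIs, 142 + 136 subjects) is a matter of
#' passing the corresponding [cohort_spec()].
#'
#' @param cohort A [cohort_spec()] (synthetic source) or a directory path
#'   containing a cohort written by [write_cohort()].
#' @param rect_width,gauss_sigma,shift Sliding-window taper and step.
#' @param alpha,fdr Wilcoxon edge-significance level and optional BH
#'   adjustment for the sparse adjacency.
#' @param signed_laplacian Use signed SFC weights in the Laplacian instead of
#'   magnitudes.
#' @param selector,selector_config,svm,outer_folds,inner_folds Classification
#'   stage settings (see [nested_cv()]).
#' @param louvain_seed Seed for the Louvain restarts in the feature stage.
#' @param seed Master seed for the classification stage.
#' @return A list of class `gfc_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(n_group_a = 30,
                                                 n_group_b = 30,
                                                 n_rois = 20,
                                                 effect_edges = default_effect_edges(20),
                                                 effect_size = 0.4),
                            rect_width = 50, gauss_sigma = 3, shift = 1,
                            alpha = 0.05, fdr = FALSE,
                            signed_laplacian = FALSE,
                            selector = "none", selector_config = NULL,
                            svm = svm_config(), outer_folds = 10,
                            inner_folds = 5, louvain_seed = 42L, seed = 1) {
  structure(
    list(cohort = cohort, rect_width = rect_width, gauss_sigma = gauss_sigma,
         shift = shift, alpha = alpha, fdr = fdr,
         signed_laplacian = signed_laplacian, selector = selector,
         selector_config = selector_config, svm = svm,
         outer_folds = outer_folds, inner_folds = inner_folds,
         louvain_seed = louvain_seed, seed = seed),
    class = "gfc_pipeline_config")
}

#' Ten disjoint ROI pairs used as default planted effect edges
#'
#' @param m Number of ROIs (>= 20 for the full ten pairs).
#' @param n_edges Number of disjoint pairs.
#' @return List of index pairs `(1,2), (3,4), ...`.
#' @export
default_effect_edges <- function(m, n_edges = min(10, floor(m / 2))) {
  map(seq_len(n_edges), function(k) c(2 * k - 1, 2 * k))
}

require_stage <- function(path, stage) {
  if (!file.exists(path)) {
    abort(sprintf("missing output '%s': run stage '%s' first",
                  basename(path), stage))
  }
  path
}

stage_simulate <- function(config, dir) {
  cohort_dir <- file.path(dir, "cohort")
  if (inherits(config$cohort, "gfc_cohort_spec")) {
    cohort <- generate_cohort(config$cohort)
    write_cohort(cohort, cohort_dir)
  } else {
    cohort <- read_cohort(config$cohort)
    write_cohort(cohort, cohort_dir)
  }
  invisible(cohort_dir)
}

stage_fc <- function(config, dir) {
  cohort <- read_cohort(require_stage(file.path(dir, "cohort"), "simulate"))
  taper <- build_taper(config$rect_width, config$gauss_sigma)
  fcs <- cohort_fc(cohort, taper, shift = config$shift, band = "FFB")
  fc_dir <- file.path(dir, "fc")
  dir.create(fc_dir, showWarnings = FALSE)
  walk(seq_len(nrow(fcs)), function(i) {
    write_matrix_tsv(fcs$fc[[i]],
                     file.path(fc_dir, paste0(fcs$subject_id[i], "_ffb.tsv")))
  })
  invisible(fc_dir)
}

stage_gsp <- function(config, dir) {
  cohort <- read_cohort(require_stage(file.path(dir, "cohort"), "simulate"))
  fc_dir <- require_stage(file.path(dir, "fc"), "fc")
  ffb <- map(cohort$subject_id, function(id) {
    read_matrix_tsv(require_stage(file.path(fc_dir, paste0(id, "_ffb.tsv")),
                                  "fc"))
  })
  a_idx <- cohort$group == "A"
  sfc <- group_sparse_adjacency(ffb[a_idx], ffb[!a_idx],
                                alpha = config$alpha, fdr = config$fdr)
  write_matrix_tsv(sfc$mask * 1, file.path(dir, "edge_mask.tsv"))
  readr::write_tsv(sfc$tests, file.path(dir, "edge_tests.tsv"),
                   progress = FALSE)
  if (!any(sfc$mask)) {
    warn("no edge passed the rank-sum threshold; sparse adjacency is empty")
  }
  sparse <- vector("list", nrow(cohort))
  sparse[which(a_idx)] <- sfc$sparse_a
  sparse[which(!a_idx)] <- sfc$sparse_b
  taper <- build_taper(config$rect_width, config$gauss_sigma)
  bands <- band_split(nrow(ffb[[1]]))
  walk(seq_len(nrow(cohort)), function(i) {
    spec <- graph_spectrum(graph_laplacian(sparse[[i]],
                                           signed = config$signed_laplacian))
    for (b in c("lfb", "mfb", "hfb")) {
      xf <- band_filter(cohort$data[[i]], spec, b, bands)
      fc <- sliding_window_fc(xf, taper, shift = config$shift,
                              undefined = "zero")
      write_matrix_tsv(fc, file.path(fc_dir,
                                     paste0(cohort$subject_id[i], "_", b,
                                            ".tsv")))
    }
  })
  invisible(fc_dir)
}

stage_features <- function(config, dir) {
  cohort <- read_cohort(require_stage(file.path(dir, "cohort"), "simulate"))
  fc_dir <- require_stage(file.path(dir, "fc"), "fc")
  rows <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    purrr::map_dfr(band_labels, function(b) {
      f <- require_stage(
        file.path(fc_dir, paste0(cohort$subject_id[i], "_", b, ".tsv")),
        if (b == "ffb") "fc" else "gsp")
      tibble(subject_id = cohort$subject_id[i],
             group = as.character(cohort$group[i]), band = b,
             fc = list(read_matrix_tsv(f)))
    })
  })
  rows$group <- factor(rows$group, levels = c("A", "B"))
  ft <- feature_table(rows, louvain_seed = config$louvain_seed)
  readr::write_csv(ft, file.path(dir, "feature_table.csv"), progress = FALSE)
  readr::write_tsv(feature_dictionary(), file.path(dir, "feature_dictionary.tsv"),
                   progress = FALSE)
  invisible(file.path(dir, "feature_table.csv"))
}

stage_classify <- function(config, dir) {
  ft <- readr::read_csv(require_stage(file.path(dir, "feature_table.csv"),
                                      "features"),
                        col_types = readr::cols(subject_id = "c",
                                                group = "c",
                                                .default = "d"),
                        progress = FALSE)
  ft$group <- factor(ft$group, levels = c("A", "B"))
  cv <- nested_cv(ft, selector = config$selector,
                  selector_config = config$selector_config,
                  svm = config$svm, outer_folds = config$outer_folds,
                  inner_folds = config$inner_folds, seed = config$seed)
  jsonlite::write_json(
    list(selector = cv$selector,
         pooled = as.list(cv$pooled),
         aggregate = as.list(cv$aggregate),
         fold_mean = as.list(cv$fold_mean),
         auc = cv$auc,
         folds = select(cv$folds, -"selected"),
         selected = cv$folds$selected,
         seed = cv$seed),
    file.path(dir, "cv_report.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(cv$roc, file.path(dir, "roc.tsv"), progress = FALSE)
  saved <- cv
  invisible(saved)
}

stage_report <- function(config, dir) {
  ft <- readr::read_csv(require_stage(file.path(dir, "feature_table.csv"),
                                      "features"),
                        col_types = readr::cols(subject_id = "c",
                                                group = "c",
                                                .default = "d"),
                        progress = FALSE)
  ft$group <- factor(ft$group, levels = c("A", "B"))
  run_cv <- function(sub) {
    nested_cv(sub, selector = config$selector,
              selector_config = config$selector_config, svm = config$svm,
              outer_folds = config$outer_folds,
              inner_folds = config$inner_folds, seed = config$seed)
  }
  by_family <- report_tables(list(
    all = run_cv(ft),
    graph = run_cv(select_features(ft, "graph")),
    mst = run_cv(select_features(ft, "mst")),
    triad_tmh_links = run_cv(select_features(ft, "triad_tmh_links"))))
  by_band <- report_tables(setNames(
    map(band_labels, function(b) run_cv(select_features(ft, band = b))),
    band_labels))
  readr::write_csv(by_family, file.path(dir, "report_by_family.csv"),
                   progress = FALSE)
  readr::write_csv(by_band, file.path(dir, "report_by_band.csv"),
                   progress = FALSE)
  writeLines(c(format_report_table(by_family), "",
               format_report_table(by_band)),
             file.path(dir, "report_tables.txt"))
  invisible(list(by_family = by_family, by_band = by_band))
}

#' Compute the 100-feature table of a cohort in memory
#'
#' The in-memory core of the pipeline: full-band sliding-window FC per
#' subject, rank-sum sparse adjacency across groups, per-subject Laplacian
#' spectra, band filtering of the time series, per-band FC, and feature
#' extraction. Equivalent to the `fc` + `gsp` + `features` stages of
#' [run_pipeline()] without touching disk.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @param taper A [build_taper()].
#' @param shift Window shift in TRs.
#' @param alpha,fdr Rank-sum threshold and optional BH adjustment.
#' @param signed_laplacian Use signed sparse weights in the Laplacian.
#' @param louvain_seed Seed for Louvain restarts.
#' @return A list: `features` (the feature table), `mask` (significant-edge
#'   matrix), `edge_tests` (per-edge rank-sum table).
#' @export
analyze_cohort <- function(cohort, taper = build_taper(), shift = 1,
                           alpha = 0.05, fdr = FALSE,
                           signed_laplacian = FALSE, louvain_seed = 42L) {
  ffb <- cohort_fc(cohort, taper, shift = shift, band = "FFB")
  a_idx <- cohort$group == "A"
  sfc <- group_sparse_adjacency(ffb$fc[a_idx], ffb$fc[!a_idx],
                                alpha = alpha, fdr = fdr)
  sparse <- vector("list", nrow(cohort))
  sparse[which(a_idx)] <- sfc$sparse_a
  sparse[which(!a_idx)] <- sfc$sparse_b
  bands <- band_split(nrow(ffb$fc[[1]]))
  band_rows <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    spec <- graph_spectrum(graph_laplacian(sparse[[i]],
                                           signed = signed_laplacian))
    purrr::map_dfr(c("lfb", "mfb", "hfb"), function(b) {
      xf <- band_filter(cohort$data[[i]], spec, b, bands)
      tibble(subject_id = cohort$subject_id[i],
             group = as.character(cohort$group[i]), band = b,
             fc = list(sliding_window_fc(xf, taper, shift = shift,
                                         undefined = "zero")))
    })
  })
  fc_tbl <- bind_rows(
    mutate(ffb, group = as.character(.data$group), band = "ffb"),
    band_rows)
  fc_tbl$group <- factor(fc_tbl$group, levels = c("A", "B"))
  list(features = feature_table(fc_tbl, louvain_seed = louvain_seed),
       mask = sfc$mask, edge_tests = sfc$tests)
}

pipeline_stages <- c("simulate", "fc", "gsp", "features", "classify",
                     "report")

#' Run the graph-frequency-band connectivity pipeline end to end
#'
#' Executes (a subset of) the stages `simulate` (generate or import the
#' cohort), `fc` (full-band sliding-window FC), `gsp` (rank-sum sparse
#' adjacency, Laplacian spectra, band filtering, per-band FC), `features`
#' (100-feature table), `classify` (nested CV) and `report` (family-wise and
#' band-wise summary tables). Each stage reads its inputs from the run
#' directory, so stages are idempotent and individually re-runnable; a
#' missing upstream output aborts naming the stage that must run first.
#' A `manifest.json` with MD5 checksums of every output is written at the
#' end; re-running with the same config and seed reproduces identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if needed).
#' @param stages Character vector of stages to execute, in pipeline order.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the run directory and the classify/report
#'   results that were produced in this call.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = pipeline_stages, quiet = FALSE) {
  stopifnot(inherits(config, "gfc_pipeline_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(dir = out_dir)
  for (st in pipeline_stages[pipeline_stages %in% stages]) {
    t0 <- Sys.time()
    out <- switch(st,
      simulate = stage_simulate(config, out_dir),
      fc = stage_fc(config, out_dir),
      gsp = stage_gsp(config, out_dir),
      features = stage_features(config, out_dir),
      classify = stage_classify(config, out_dir),
      report = stage_report(config, out_dir))
    if (st %in% c("classify", "report")) results[[st]] <- out
    if (!quiet) {
      inform(sprintf("stage %-9s done in %.1fs", st,
                     as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json" |
                   dirname(files) != out_dir]
  manifest <- list(
    files = as.list(setNames(unname(tools::md5sum(files)),
                             sub(paste0("^", out_dir, "/?"), "", files))),
    stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Heatmap of an FC matrix
#'
#' @param fc Symmetric FC matrix.
#' @param title Plot title.
#' @return A ggplot.
#' @export
plot_fc_matrix <- function(fc, title = "Functional connectivity") {
  df <- tidyr::expand_grid(roi_i = seq_len(nrow(fc)),
                           roi_j = seq_len(ncol(fc)))
  df$value <- fc[cbind(df$roi_i, df$roi_j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi_j, y = .data$roi_i,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ROI", y = "ROI", fill = "r", title = title) +
    ggplot2::theme_minimal()
}
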