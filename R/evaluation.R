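#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `acc = (TP + TN) / (TP + TN + FP + FN)`, `sen = TP / (TP + FN)`,
#' `spec = TN / (TN + FP)`. Sensitivity (resp. specificity) is NA when its
#' denominator is zero. The positive class is the progressive group, so
#' sensitivity is the progressive-detection rate.
#'
#' @param tp,fp,tn,fn Non-negative integer counts, total > 0.
#' @return A one-row tibble `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  if (sum(counts) == 0) abort("confusion counts are all zero")
  tibble(
    accuracy = (tp + tn) / sum(counts),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique decision values as thresholds (higher score = more
#' positive); tied scores step the curve simultaneously. The AUC is the
#' trapezoidal area under the (FPR, TPR) polyline.
#'
#' @param scores Numeric decision values.
#' @param labels Two-level factor (or coercible); `positive` names the
#'   positive class, defaulting to the last level.
#' @param positive Positive class label.
#' @return List with `roc` (tibble `threshold`, `fpr`, `tpr`, monotone in
#'   FPR) and `auc`.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  y <- factor(labels)
  if (nlevels(y) != 2) abort("ROC needs exactly two classes present")
  positive <- positive %||% levels(y)[nlevels(y)]
  is_pos <- y == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) abort("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- is_pos[ord]
  keep <- c(diff(s) != 0, TRUE)  # last index of each tied block
  tp <- cumsum(pos)[keep]
  fp <- cumsum(!pos)[keep]
  roc <- tibble(threshold = c(Inf, s[keep]),
                fpr = c(0, fp / n_neg),
                tpr = c(0, tp / n_pos))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Nested cross-validated SVM-RBF evaluation with per-fold feature selection
#'
#' Stratified `outer_folds`-fold cross-validation. Within each outer
#' training fold: features are standardized on the training data, the
#' selector (binary PSO, SA, or none) is run with fitness equal to
#' inner-cross-validated SVM accuracy on that training data only, an
#' RBF-kernel SVM is trained on the selected features, and the held-out fold
#' is predicted. The outer test fold never influences selection or training.
#'
#' Headline metrics are computed from the pooled confusion counts; the
#' mean-of-folds variants are also reported. The ROC curve pools the
#' decision values of all outer test folds, oriented so larger values favor
#' the positive (progressive) class.
#'
#' @param features Feature table: tibble with `group` (two-level factor,
#'   second level = positive/progressive class) and numeric feature columns;
#'   `subject_id` optional.
#' @param labels Optional label vector overriding `features$group`.
#' @param selector `"none"`, `"pso"` or `"sa"`.
#' @param selector_config A [pso_config()] / [sa_config()] matching
#'   `selector`.
#' @param svm A [svm_config()].
#' @param outer_folds,inner_folds Outer / inner CV fold counts.
#' @param seed Integer seed (outer folds, per-fold selector seeds).
#' @return An object of class `gfc_cv`: list with `folds` (per-fold tibble
#'   incl. confusion counts, metrics and selected features), `pooled`
#'   (confusion totals), `aggregate` (pooled metrics), `fold_mean`
#'   (mean-of-fold metrics), `roc`, `auc`, `positive_class`, `selector`.
#' @export
nested_cv <- function(features, labels = NULL, selector = c("none", "pso", "sa"),
                      selector_config = NULL, svm = svm_config(),
                      outer_folds = 10, inner_folds = 5, seed = 1) {
  selector <- match.arg(selector)
  x <- feature_matrix(features)
  y <- feature_labels(features, labels)
  if (min(table(y)) < outer_folds) {
    abort("each class needs at least `outer_folds` subjects")
  }
  positive <- levels(y)[2]
  fold <- stratified_folds(y, outer_folds, seed)
  nm <- colnames(x)

  fold_rows <- map(seq_len(outer_folds), function(fi) {
    tr <- fold != fi
    parts <- if (svm$standardize) {
      standardize_train_test(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    } else {
      list(train = x[tr, , drop = FALSE], test = x[!tr, , drop = FALSE])
    }
    xtr <- parts$train
    ytr <- y[tr]
    fold_seed <- seed * 1000L + fi
    sel <- switch(selector,
      none = NULL,
      pso = {
        cfg <- selector_config %||% pso_config()
        cfg$seed <- fold_seed
        pso_select(xtr, ytr, config = cfg, inner_folds = inner_folds,
                   svm = svm)
      },
      sa = {
        cfg <- selector_config %||% sa_config()
        cfg$seed <- fold_seed
        sa_select(xtr, ytr, config = cfg, inner_folds = inner_folds,
                  svm = svm)
      })
    mask <- if (is.null(sel)) rep(TRUE, ncol(x)) else sel$mask
    fit <- fit_svm(xtr[, mask, drop = FALSE], ytr, svm)
    pred <- predict(fit, parts$test[, mask, drop = FALSE],
                    decision.values = TRUE)
    dv <- as.numeric(attr(pred, "decision.values"))
    # e1071 orients the decision value toward the class named first in the
    # "A/B" colname; flip so larger always favors the positive class
    dv_name <- colnames(attr(pred, "decision.values"))[1]
    if (strsplit(dv_name, "/")[[1]][1] != positive) dv <- -dv
    yte <- y[!tr]
    tp <- sum(pred == positive & yte == positive)
    fp <- sum(pred == positive & yte != positive)
    tn <- sum(pred != positive & yte != positive)
    fn <- sum(pred != positive & yte == positive)
    mets <- confusion_metrics(tp, fp, tn, fn)
    tibble(fold = fi, n = sum(!tr), tp = tp, fp = fp, tn = tn, fn = fn,
           accuracy = mets$accuracy, sensitivity = mets$sensitivity,
           specificity = mets$specificity,
           selected = list(nm[mask]),
           decision_values = list(dv), truth = list(as.character(yte)))
  })
  folds <- bind_rows(fold_rows)
  pooled <- c(tp = sum(folds$tp), fp = sum(folds$fp),
              tn = sum(folds$tn), fn = sum(folds$fn))
  aggregate <- confusion_metrics(pooled["tp"], pooled["fp"],
                                 pooled["tn"], pooled["fn"])
  fold_mean <- summarise(folds,
                         accuracy = mean(.data$accuracy),
                         sensitivity = mean(.data$sensitivity, na.rm = TRUE),
                         specificity = mean(.data$specificity, na.rm = TRUE))
  rc <- roc_curve(unlist(folds$decision_values), unlist(folds$truth),
                  positive = positive)
  structure(
    list(folds = select(folds, -"decision_values", -"truth"),
         pooled = pooled, aggregate = aggregate, fold_mean = fold_mean,
         roc = rc$roc, auc = rc$auc, positive_class = positive,
         selector = selector, outer_folds = outer_folds,
         n_features = ncol(x), seed = seed),
    class = "gfc_cv")
}

#' @export
print.gfc_cv <- function(x, ...) {
  cat(sprintf(
    "<gfc_cv> %d-fold nested CV (selector: %s)\n  pooled acc %.3f | sen %.3f | spec %.3f | auc %.3f\n",
    x$outer_folds, x$selector, x$aggregate$accuracy,
    x$aggregate$sensitivity, x$aggregate$specificity, x$auc))
  invisible(x)
}

#' @export
tidy.gfc_cv <- function(x, ...) {
  select(x$folds, "fold", "n", "tp", "fp", "tn", "fn",
         "accuracy", "sensitivity", "specificity")
}

#' @export
glance.gfc_cv <- function(x, ...) {
  tibble(accuracy = x$aggregate$accuracy,
         sensitivity = x$aggregate$sensitivity,
         specificity = x$aggregate$specificity,
         auc = x$auc,
         mean_fold_accuracy = x$fold_mean$accuracy,
         n = sum(x$folds$n),
         selector = x$selector,
         mean_selected = mean(purrr::map_int(x$folds$selected, length)))
}

#' Plot the pooled ROC curve of a nested CV run
#'
#' @param object A `gfc_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gfc_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("Pooled ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Summarize CV runs the way the two reporting approaches do
#'
#' Collates a set of tagged [nested_cv()] reports into one table with one
#' row per (subset, selector): accuracy / sensitivity / specificity, the
#' number of extracted and selected features, and the union of selected
#' feature names across folds.
#'
#' @param reports Named list of `gfc_cv` objects; names are the subset tags
#'   (e.g. `"graph"`, `"mst"`, or band names). Duplicate tag + selector
#'   combinations are an error.
#' @return A tibble with columns `subset`, `selector`, `accuracy`,
#'   `sensitivity`, `specificity`, `n_extracted`, `n_selected`,
#'   `selected_features`.
#' @export
report_tables <- function(reports) {
  if (length(reports) == 0) abort("no reports supplied")
  if (is.null(names(reports)) || any(names(reports) == "")) {
    abort("reports must be a named list (subset tags)")
  }
  rows <- imap(reports, function(r, tag) {
    stopifnot(inherits(r, "gfc_cv"))
    sel_union <- sort(unique(unlist(r$folds$selected)))
    tibble(subset = tag, selector = r$selector,
           accuracy = r$aggregate$accuracy,
           sensitivity = r$aggregate$sensitivity,
           specificity = r$aggregate$specificity,
           n_extracted = r$n_features,
           n_selected = round(mean(purrr::map_int(r$folds$selected, length))),
           selected_features = paste(sel_union, collapse = ", "))
  })
  out <- bind_rows(rows)
  if (anyDuplicated(out[c("subset", "selector")])) {
    abort("duplicate subset/selector tags")
  }
  out
}

#' Format a report table as aligned text
#'
#' @param table A tibble from [report_tables()].
#' @return A character vector of fixed-width lines (printable with `cat`).
#' @export
format_report_table <- function(table) {
  hdr <- sprintf("%-18s %-8s %6s %6s %6s %10s %10s  %s",
                 "Subset", "Select", "Acc", "Sen", "Spec",
                 "Extracted", "Selected", "Selected features")
  rows <- pmap(table, function(subset, selector, accuracy, sensitivity,
                               specificity, n_extracted, n_selected,
                               selected_features, ...) {
    sprintf("%-18s %-8s %5.1f%% %5.1f%% %5.1f%% %10s %10d  %s",
            subset, selector, 100 * accuracy, 100 * sensitivity,
            100 * specificity,
            ifelse(is.na(n_extracted), "-", as.character(n_extracted)),
            n_selected, selected_features)
  })
  c(hdr, unlist(rows))
}
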