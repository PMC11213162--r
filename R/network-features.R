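# Feature families computed from one signed FC matrix.
#
# Conventions shared by all families:
#  * path-based metrics use the positive-weight subgraph with edge length 1/w
#    (negative edges carry no path information);
#  * the MST uses the correlation-to-distance map d = 1 - w on positive
#    weights and tree metrics are computed on the unweighted tree topology;
#  * metrics whose value is undefined on the given matrix are returned as NA
#    and reported via a warning; cohort-level assembly imputes them.

positive_graph <- function(fc) {
  w <- fc
  w[w < 0] <- 0
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Global graph metrics of a signed FC matrix
#'
#' Nine whole-network summaries: global efficiency (GE, mean inverse shortest
#' path length), mean eccentricity (ME), radius and diameter (min / max
#' eccentricity), assortativity coefficient (AC, degree-degree correlation
#' over edges), mean clustering coefficient (MCC, geometric-mean weighted
#' triangle formula), mean eigenvector centrality (MEC, mean of the
#' unit-norm principal eigenvector of `|FC|`), mean strength (MS, mean signed
#' row sum) and Louvain modularity (on positive weights, resolution 1, best
#' of `n_restarts` seeded restarts).
#'
#' Shortest paths use the positive subgraph with length `1/w`. On a
#' disconnected positive subgraph the eccentricity-based metrics and GE's
#' unreachable pairs follow the usual conventions (unreachable pairs
#' contribute zero efficiency; eccentricities become infinite and are
#' returned as NA with a warning). A degree-regular graph has no degree
#' variance, so AC is returned as 0 with a warning.
#'
#' @param fc Symmetric M x M signed FC matrix, zero diagonal.
#' @param louvain_seed,n_restarts Seed and restart count for Louvain.
#' @return Named numeric vector:
#'   `ge, me, radius, diameter, ac, mcc, mec, ms, modularity`.
#' @export
graph_global_metrics <- function(fc, louvain_seed = 42L, n_restarts = 10L) {
  check_fc(fc)
  m <- nrow(fc)
  g <- positive_graph(fc)
  out <- c(ge = NA_real_, me = NA_real_, radius = NA_real_,
           diameter = NA_real_, ac = NA_real_, mcc = NA_real_,
           mec = NA_real_, ms = NA_real_, modularity = NA_real_)

  if (igraph::ecount(g) > 0) {
    d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    inv <- 1 / d
    diag(inv) <- 0
    out["ge"] <- sum(inv) / (m * (m - 1))
    ecc <- apply(d, 1, max)
    if (all(is.finite(ecc))) {
      out["me"] <- mean(ecc)
      out["radius"] <- min(ecc)
      out["diameter"] <- max(ecc)
    } else {
      warn("positive subgraph is disconnected; eccentricity metrics undefined")
    }
    ac <- suppressWarnings(igraph::assortativity_degree(g))
    if (is.finite(ac)) {
      out["ac"] <- ac
    } else {
      warn("assortativity undefined (regular degree sequence); flagged 0")
      out["ac"] <- 0
    }
    out["mcc"] <- mean_clustering_onnela(fc)
  } else {
    warn("no positive edges; path, clustering and assortativity metrics undefined")
  }

  ev <- eigen(abs(fc), symmetric = TRUE)
  pv <- ev$vectors[, which.max(ev$values)]
  pv <- abs(pv) / sqrt(sum(pv^2))
  out["mec"] <- mean(pv)
  out["ms"] <- mean(rowSums(fc))
  out["modularity"] <- louvain_modularity(g, louvain_seed, n_restarts)
  out
}

# Onnela geometric-mean weighted clustering coefficient on positive weights,
# averaged over nodes (nodes with degree < 2 contribute 0)
mean_clustering_onnela <- function(fc) {
  w <- fc
  w[w < 0] <- 0
  mx <- max(w)
  if (mx <= 0) return(NA_real_)
  wh <- (w / mx)^(1 / 3)
  num <- diag(wh %*% wh %*% wh)
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(ci)
}

louvain_modularity <- function(g, seed, n_restarts) {
  if (igraph::ecount(g) == 0) return(NA_real_)
  with_seed(seed, {
    best <- -Inf
    for (i in seq_len(n_restarts)) {
      cl <- igraph::cluster_louvain(g, resolution = 1)
      q <- igraph::modularity(g, igraph::membership(cl),
                              weights = igraph::E(g)$weight)
      if (q > best) best <- q
    }
    best
  })
}

#' Minimum spanning tree metrics of an FC matrix
#'
#' The MST is built on the positive-weight subgraph with the
#' correlation-to-distance map `d = 1 - w` (equivalent to the single-linkage
#' dendrogram backbone). Metrics are computed on the unweighted tree
#' topology: radius and diameter (hop eccentricities), maximum degree, leaf
#' fraction (degree-1 nodes / M), maximum betweenness centrality normalized
#' by `(M-1)(M-2)/2`, tree hierarchy `LF / (2 BC_max)` and kappa
#' `sum(k^2) / sum(k)`, the breadth of the degree distribution.
#'
#' @param fc Symmetric signed FC matrix, zero diagonal; its positive subgraph
#'   must be connected and M >= 3.
#' @param weighted_tree If `TRUE`, radius/diameter/betweenness use the tree's
#'   `1 - w` distances instead of hop counts.
#' @return Named numeric vector:
#'   `radius, diameter, deg_max, leaf_fraction, bc_max, tree_hierarchy, kappa`.
#' @export
mst_metrics <- function(fc, weighted_tree = FALSE) {
  check_fc(fc)
  m <- nrow(fc)
  if (m < 3) abort("MST metrics need at least 3 ROIs")
  g <- positive_graph(fc)
  if (igraph::ecount(g) == 0 || igraph::components(g)$no > 1) {
    abort("positive subgraph is disconnected; MST undefined")
  }
  igraph::E(g)$dist <- 1 - igraph::E(g)$weight
  tree <- igraph::mst(g, weights = igraph::E(g)$dist)
  wts <- if (weighted_tree) igraph::E(tree)$dist else NA
  d <- igraph::distances(tree, weights = wts)
  ecc <- apply(d, 1, max)
  deg <- igraph::degree(tree)
  bc <- igraph::betweenness(tree, weights = wts) / ((m - 1) * (m - 2) / 2)
  bc_max <- max(bc)
  lf <- mean(deg == 1)
  c(radius = min(ecc), diameter = max(ecc), deg_max = max(deg),
    leaf_fraction = lf, bc_max = bc_max,
    tree_hierarchy = lf / (2 * bc_max),
    kappa = sum(deg^2) / sum(deg))
}

#' Triadic balance census and network energy
#'
#' Every ROI triple whose three edges are all nonzero is classified by its
#' number of positive edges: weakly unbalanced T0 (- - -), weakly balanced
#' T1 (+ - -), strongly unbalanced T2 (+ + -) and strongly balanced
#' T3 (+ + +). The network energy is the negative mean triple product of the
#' qualifying triads' weights:
#' `Un = -sum(w_xy * w_xz * w_yz) / Delta`, with `Delta` the number of
#' qualifying triads. Balanced triads (even number of negative edges ... T1,
#' T3) contribute negative energy, pushing Un down; a network dominated by
#' balanced strong triads therefore has low (negative) energy.
#'
#' @param fc Symmetric signed FC matrix, zero diagonal.
#' @return Named numeric vector `t0, t1, t2, t3, energy`; all NA (with a
#'   warning) if no triple has three nonzero edges.
#' @export
triad_metrics <- function(fc) {
  check_fc(fc)
  p <- (fc > 0) * 1
  n <- (fc < 0) * 1
  tr3 <- function(a, b, c) sum(diag(a %*% b %*% c))
  t3 <- tr3(p, p, p) / 6
  t0 <- tr3(n, n, n) / 6
  t2 <- tr3(p, p, n) / 2
  t1 <- tr3(p, n, n) / 2
  delta <- t0 + t1 + t2 + t3
  if (delta == 0) {
    warn("no triple has three nonzero edges; triad metrics undefined")
    return(c(t0 = NA_real_, t1 = NA_real_, t2 = NA_real_, t3 = NA_real_,
             energy = NA_real_))
  }
  energy <- -sum(diag(fc %*% fc %*% fc)) / 6 / delta
  c(t0 = t0, t1 = t1, t2 = t2, t3 = t3, energy = energy)
}

#' Tendency to make hub (TMH), positive and negative
#'
#' The positive TMH is `sum(D_p^2) / sum(D_p)` where `D_p[i]` is ROI i's
#' positive strength (sum of its positive weights); the negative TMH is the
#' same functional of the magnitudes of the negative weights (so both are
#' non-negative). Equal-strength networks have TMH equal to the common
#' strength; heavier-tailed strength distributions push TMH up, indicating a
#' propensity to form hubs.
#'
#' @param fc Symmetric signed FC matrix, zero diagonal.
#' @return Named numeric vector `positive, negative`; a side with no links is
#'   NA with a warning.
#' @export
tmh_metrics <- function(fc) {
  check_fc(fc)
  dp <- rowSums(fc * (fc > 0))
  dn <- rowSums(-fc * (fc < 0))
  one <- function(d, side) {
    if (sum(d) <= 0) {
      warn(sprintf("no %s links; TMH %s undefined", side, side))
      return(NA_real_)
    }
    sum(d^2) / sum(d)
  }
  c(positive = one(dp, "positive"), negative = one(dn, "negative"))
}

#' Counts of positive and negative links
#'
#' @param fc Symmetric signed FC matrix, zero diagonal.
#' @return Named numeric vector `positive, negative`: counts of strictly
#'   positive / negative upper-triangle entries.
#' @export
link_counts <- function(fc) {
  check_fc(fc)
  ut <- fc[upper.tri(fc)]
  c(positive = sum(ut > 0), negative = sum(ut < 0))
}

band_labels <- c("ffb", "lfb", "mfb", "hfb")

metric_families <- list(
  graph = c("ge", "me", "radius", "diameter", "ac", "mcc", "mec", "ms",
            "modularity"),
  mst = c("radius", "diameter", "deg_max", "leaf_fraction", "bc_max",
          "tree_hierarchy", "kappa"),
  triad = c("t0", "t1", "t2", "t3", "energy"),
  tmh = c("positive", "negative"),
  links = c("positive", "negative")
)

#' Feature data dictionary
#'
#' @return A tibble with one row per feature (100 rows): `feature`, `band`,
#'   `family`, `metric`, in the canonical extraction order (bands FFB, LFB,
#'   MFB, HFB; families graph, mst, triad, tmh, links).
#' @export
feature_dictionary <- function() {
  rows <- purrr::map_dfr(band_labels, function(b) {
    purrr::map_dfr(names(metric_families), function(fam) {
      tibble(band = b, family = fam, metric = metric_families[[fam]])
    })
  })
  mutate(rows,
         feature = paste(.data$band, .data$family, .data$metric, sep = "."),
         .before = 1)
}

#' Extract the 25-metric feature block from one band's FC matrix
#'
#' @param fc Symmetric signed FC matrix, zero diagonal.
#' @param band Band label (`"ffb"`, `"lfb"`, `"mfb"`, `"hfb"`).
#' @inheritParams graph_global_metrics
#' @return Named numeric vector of 25 features `<band>.<family>.<metric>`.
#' @export
band_features <- function(fc, band, louvain_seed = 42L) {
  band <- tolower(band)
  if (!band %in% band_labels) abort(sprintf("unknown band '%s'", band))
  mst <- tryCatch(mst_metrics(fc), error = function(e) {
    warn(paste("MST metrics undefined:", conditionMessage(e)))
    setNames(rep(NA_real_, 7), metric_families$mst)
  })
  vals <- c(graph_global_metrics(fc, louvain_seed = louvain_seed),
            mst, triad_metrics(fc), tmh_metrics(fc), link_counts(fc))
  setNames(vals, filter(feature_dictionary(), band == !!band)$feature)
}

#' Assemble one subject's 100-feature vector
#'
#' Concatenates the five metric families for the full band and the three
#' graph-frequency bands, in the canonical dictionary order.
#'
#' @param fc_ffb,fc_lfb,fc_mfb,fc_hfb The subject's four same-sized FC
#'   matrices.
#' @inheritParams graph_global_metrics
#' @return Named numeric vector of exactly 100 features.
#' @export
extract_features <- function(fc_ffb, fc_lfb, fc_mfb, fc_hfb,
                             louvain_seed = 42L) {
  mats <- list(ffb = fc_ffb, lfb = fc_lfb, mfb = fc_mfb, hfb = fc_hfb)
  dims <- map(mats, dim)
  if (length(unique(map_chr(dims, paste, collapse = "x"))) != 1) {
    abort("the four FC matrices must have identical dimensions")
  }
  unlist(imap(mats, function(fc, b) band_features(fc, b,
                                                  louvain_seed = louvain_seed)),
         use.names = FALSE) |>
    setNames(feature_dictionary()$feature)
}

#' Build the cohort feature table
#'
#' Takes a per-subject, per-band FC tibble (rows `subject_id`, `group`,
#' `band`, `fc`; four rows per subject) and returns the subjects-by-features
#' table. Metrics that are undefined for a subject are imputed with the
#' cohort median of that feature; the number of imputed cells is reported.
#'
#' @param fc_tbl Tibble with columns `subject_id`, `group`, `band`
#'   (`"FFB"/"LFB"/"MFB"/"HFB"`, any case) and `fc` (list of matrices).
#' @inheritParams graph_global_metrics
#' @return A tibble: `subject_id`, `group`, then 100 feature columns.
#' @export
feature_table <- function(fc_tbl, louvain_seed = 42L) {
  fc_tbl <- mutate(fc_tbl, band = tolower(.data$band))
  wide <- tidyr::pivot_wider(fc_tbl, id_cols = c("subject_id", "group"),
                             names_from = "band", values_from = "fc")
  missing_bands <- setdiff(band_labels, names(wide))
  if (length(missing_bands)) {
    abort(sprintf("missing band(s): %s", paste(missing_bands, collapse = ", ")))
  }
  feats <- map(seq_len(nrow(wide)), function(i) {
    extract_features(wide$ffb[[i]], wide$lfb[[i]], wide$mfb[[i]],
                     wide$hfb[[i]], louvain_seed = louvain_seed)
  })
  fm <- do.call(rbind, feats)
  n_imputed <- sum(is.na(fm))
  if (n_imputed > 0) {
    all_na <- colSums(!is.na(fm)) == 0
    if (any(all_na)) {
      warn(sprintf(
        "feature(s) undefined for every subject, set to 0: %s",
        paste(colnames(fm)[all_na], collapse = ", ")))
      fm[, all_na] <- 0
    }
    med <- apply(fm, 2, median, na.rm = TRUE)
    for (j in which(colSums(is.na(fm)) > 0)) {
      fm[is.na(fm[, j]), j] <- med[j]
    }
    inform(sprintf("imputed %d undefined feature value(s) with cohort medians",
                   n_imputed))
  }
  bind_cols(tibble(subject_id = wide$subject_id, group = wide$group),
            as_tibble(fm))
}

#' Select feature columns by family and/or band
#'
#' Pools features the way the two reporting approaches do: by family across
#' all bands (`graph` = 36, `mst` = 28, `triad_tmh_links` = 36, `all` = 100)
#' or by band across all families (25 each).
#'
#' @param features A feature table (see [feature_table()]).
#' @param family One of `"all"`, `"graph"`, `"mst"`, `"triad_tmh_links"`, or
#'   a vector of family names from the dictionary.
#' @param band Optional band restriction (`"ffb"`, `"lfb"`, `"mfb"`, `"hfb"`).
#' @return The feature table restricted to the matching feature columns (id
#'   columns kept).
#' @export
select_features <- function(features, family = "all", band = NULL) {
  dict <- feature_dictionary()
  fams <- switch(family[1],
    all = unique(dict$family),
    triad_tmh_links = c("triad", "tmh", "links"),
    family
  )
  keep <- dict$family %in% fams
  if (!is.null(band)) keep <- keep & dict$band %in% tolower(band)
  cols <- dict$feature[keep]
  if (length(cols) == 0) abort("no features match the requested subset")
  select(features, all_of(c(intersect(c("subject_id", "group"),
                                      names(features)), cols)))
}
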