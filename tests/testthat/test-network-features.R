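k4 <- matrix(1, 4, 4) - diag(4)
star5 <- {
  s <- matrix(0, 5, 5)
  s[1, 2:5] <- 1
  s + t(s)
}

test_that("global graph metrics have their closed forms on K4 and the star", {
  g <- suppressWarnings(graph_global_metrics(k4))
  expect_equal(g[["ge"]], 1)
  expect_equal(g[["me"]], 1)
  expect_equal(g[["radius"]], 1)
  expect_equal(g[["diameter"]], 1)
  expect_equal(g[["mcc"]], 1)
  expect_equal(g[["ms"]], 3)
  expect_equal(g[["mec"]], 0.5)
  expect_equal(g[["modularity"]], 0)
  expect_equal(g[["ac"]], 0)  # regular graph: flagged 0

  s <- suppressWarnings(graph_global_metrics(star5))
  expect_equal(s[["radius"]], 1)
  expect_equal(s[["diameter"]], 2)
  expect_equal(s[["me"]], 1.8)
  expect_equal(s[["ms"]], 8 / 5)
  expect_equal(s[["mcc"]], 0)
})

test_that("path-based metrics match the Floyd-Warshall oracle with 1/w lengths", {
  for (seed in c(11, 12, 13)) {
    fc <- random_signed_fc(8, seed, neg_frac = 0.2)
    g <- suppressWarnings(graph_global_metrics(fc))
    len <- 1 / fc
    len[fc <= 0] <- 0  # negative edges carry no path
    d <- bf_shortest_paths(len)
    inv <- 1 / d
    diag(inv) <- 0
    ecc <- apply(d, 1, max)
    expect_equal(g[["ge"]], sum(inv) / (8 * 7), tolerance = 1e-10)
    expect_equal(g[["me"]], mean(ecc), tolerance = 1e-10)
    expect_equal(g[["radius"]], min(ecc), tolerance = 1e-10)
    expect_equal(g[["diameter"]], max(ecc), tolerance = 1e-10)
  }
})

test_that("all-non-positive matrices flag their path metrics undefined", {
  neg <- -k4 * 0.5
  expect_warning(g <- graph_global_metrics(neg), "no positive")
  expect_true(is.na(g[["ge"]]))
  expect_true(is.na(g[["radius"]]))
  expect_equal(g[["ms"]], -1.5)
})

test_that("MST metrics have their closed forms and match the Kruskal oracle", {
  m <- mst_metrics(star5)
  expect_equal(m[["deg_max"]], 4)
  expect_equal(m[["leaf_fraction"]], 0.8)
  expect_equal(m[["bc_max"]], 1)
  expect_equal(m[["tree_hierarchy"]], 0.4)
  expect_equal(m[["kappa"]], 2.5)
  expect_equal(m[["radius"]], 1)
  expect_equal(m[["diameter"]], 2)

  # 4-node path (already a tree): degrees 1,2,2,1
  pth <- matrix(0, 4, 4)
  pth[1, 2] <- pth[2, 3] <- pth[3, 4] <- 0.5
  pth <- pth + t(pth)
  mp <- mst_metrics(pth)
  expect_equal(mp[["kappa"]], 10 / 6)
  expect_equal(mp[["leaf_fraction"]], 0.5)

  # random positive matrices: edge set equals Kruskal on d = 1 - w
  for (seed in c(21, 22, 23)) {
    fc <- random_signed_fc(10, seed, neg_frac = 0)
    tree <- igraph::as_edgelist(
      igraph::mst(igraph::graph_from_adjacency_matrix(
        fc * (fc > 0), mode = "undirected", weighted = TRUE, diag = FALSE),
        weights = 1 - igraph::E(igraph::graph_from_adjacency_matrix(
          fc * (fc > 0), mode = "undirected", weighted = TRUE,
          diag = FALSE))$weight))
    dist <- 1 - fc
    dist[fc <= 0] <- Inf
    diag(dist) <- Inf
    oracle <- bf_kruskal_mst(dist)
    tree <- t(apply(tree, 1, sort))
    tree <- tree[order(tree[, 1], tree[, 2]), ]
    expect_equal(unname(tree), unname(oracle))
    # and the metrics are computed on that tree's topology
    mm <- mst_metrics(fc)
    degs <- tabulate(c(oracle), nbins = 10)
    expect_equal(mm[["deg_max"]], max(degs))
    expect_equal(mm[["kappa"]], sum(degs^2) / sum(degs), tolerance = 1e-12)
  }

  disc <- diag(0, 4)
  disc[1, 2] <- disc[2, 1] <- 0.5
  expect_error(mst_metrics(disc), "disconnected")
})

test_that("kappa is at least the mean tree degree, with equality only for regular trees", {
  for (seed in 31:35) {
    fc <- random_signed_fc(9, seed, neg_frac = 0)
    mm <- mst_metrics(fc)
    mean_deg <- 2 * (9 - 1) / 9
    expect_gte(mm[["kappa"]], mean_deg - 1e-12)
  }
})

test_that("triad census and energy match the exhaustive enumeration oracle", {
  k3 <- matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3)
  t3 <- triad_metrics(k3)
  expect_equal(unname(t3[c("t0", "t1", "t2", "t3")]), c(0, 0, 0, 1))
  expect_equal(t3[["energy"]], -0.125)

  k3u <- matrix(c(0, 1, 1, 1, 0, -1, 1, -1, 0), 3)
  t2 <- triad_metrics(k3u)
  expect_equal(t2[["t2"]], 1)
  expect_equal(t2[["energy"]], 1)

  for (seed in c(41, 42)) {
    fc <- random_signed_fc(10, seed, neg_frac = 0.4)
    got <- triad_metrics(fc)
    oracle <- bf_triads(fc)
    expect_equal(unname(got), unname(oracle), tolerance = 1e-10)
    expect_equal(sum(got[c("t0", "t1", "t2", "t3")]), choose(10, 3))
  }

  # sparse matrix: only triples with three nonzero edges qualify
  sp <- matrix(0, 6, 6)
  sp[1, 2] <- sp[2, 3] <- sp[1, 3] <- 0.5
  sp[4, 5] <- -0.3
  sp <- sp + t(sp)
  ts <- triad_metrics(sp)
  expect_equal(sum(ts[c("t0", "t1", "t2", "t3")]), 1)

  expect_warning(td <- triad_metrics(diag(0, 5)), "undefined")
  expect_true(all(is.na(td)))
})

test_that("TMH matches its loop oracle and its closed forms", {
  expect_equal(suppressWarnings(tmh_metrics(star5))[["positive"]], 20 / 8)
  # uniform K5 with weight c: all strengths equal 4c -> TMH = 4c
  k5 <- (matrix(1, 5, 5) - diag(5)) * 0.3
  expect_equal(suppressWarnings(tmh_metrics(k5))[["positive"]], 4 * 0.3)

  for (seed in c(51, 52)) {
    fc <- random_signed_fc(12, seed, neg_frac = 0.35)
    expect_equal(tmh_metrics(fc), bf_tmh(fc), tolerance = 1e-12)
  }
})

test_that("link counts are exact and antisymmetric under negation", {
  expect_equal(unname(link_counts(k4)), c(6, 0))
  fc <- random_signed_fc(9, 61, neg_frac = 0.3)
  lc <- link_counts(fc)
  lcn <- link_counts(-fc)
  expect_equal(lc[["positive"]], lcn[["negative"]])
  expect_equal(lc[["negative"]], lcn[["positive"]])
  expect_equal(sum(lc), sum(fc[upper.tri(fc)] != 0))
})

test_that("metric families scale as documented under w -> c w", {
  fc <- random_signed_fc(8, 71, neg_frac = 0.3)
  c0 <- 2.5
  g1 <- suppressWarnings(graph_global_metrics(fc))
  g2 <- suppressWarnings(graph_global_metrics(fc * c0))
  expect_equal(g2[["ms"]], c0 * g1[["ms"]], tolerance = 1e-10)
  t1 <- tmh_metrics(fc)
  t2 <- tmh_metrics(fc * c0)
  expect_equal(unname(t2), unname(c0 * t1), tolerance = 1e-10)
  u1 <- triad_metrics(fc)
  u2 <- triad_metrics(fc * c0)
  expect_equal(u2[["energy"]], c0^3 * u1[["energy"]], tolerance = 1e-10)
  expect_equal(u2[c("t0", "t1", "t2", "t3")], u1[c("t0", "t1", "t2", "t3")])
})

test_that("the assembled feature vector is complete, ordered and permutation invariant", {
  dict <- feature_dictionary()
  expect_equal(nrow(dict), 100)
  expect_equal(unname(table(dict$band)[c("ffb", "lfb", "mfb", "hfb")]),
               rep(25L, 4), ignore_attr = TRUE)
  expect_equal(as.vector(table(dict$family)[c("graph", "mst", "triad",
                                              "tmh", "links")]),
               c(9L, 7L, 5L, 2L, 2L) * 4L)

  mats <- lapply(c(81, 82, 83, 84), random_signed_fc, m = 10,
                 neg_frac = 0.25)
  fv <- suppressWarnings(extract_features(mats[[1]], mats[[2]], mats[[3]],
                                          mats[[4]]))
  expect_length(fv, 100)
  expect_identical(names(fv), dict$feature)
  fv2 <- suppressWarnings(extract_features(mats[[1]], mats[[2]], mats[[3]],
                                           mats[[4]]))
  expect_identical(fv, fv2)  # determinism

  set.seed(99)
  perm <- sample(10)
  pmats <- lapply(mats, function(m) m[perm, perm])
  fvp <- suppressWarnings(extract_features(pmats[[1]], pmats[[2]],
                                           pmats[[3]], pmats[[4]]))
  expect_equal(fvp, fv, tolerance = 1e-9)
})

test_that("feature table assembly imputes undefined cells with cohort medians", {
  mats <- lapply(1:6, function(s) random_signed_fc(8, 200 + s,
                                                   neg_frac = 0.2))
  allneg <- -abs(random_signed_fc(8, 299))  # path metrics undefined
  tbl <- dplyr::bind_rows(
    purrr::map_dfr(1:2, function(i) {
      tibble::tibble(subject_id = paste0("S", i), group = c("A", "B")[i],
                     band = c("ffb", "lfb", "mfb", "hfb"),
                     fc = list(mats[[i]], mats[[i + 1]], mats[[i + 2]],
                               mats[[i + 3]]))
    }),
    tibble::tibble(subject_id = "S3", group = "A",
                   band = c("ffb", "lfb", "mfb", "hfb"),
                   fc = list(mats[[1]], allneg, mats[[2]], mats[[3]])))
  tbl$group <- factor(tbl$group, levels = c("A", "B"))
  expect_message(
    ft <- suppressWarnings(feature_table(tbl)),
    "imputed")
  expect_equal(ncol(ft), 102)
  expect_false(anyNA(ft))
  # the undefined lfb global-efficiency cell took the median of the others
  defined <- suppressWarnings(
    c(band_features(mats[[2]], "lfb")[["lfb.graph.ge"]],
      band_features(mats[[3]], "lfb")[["lfb.graph.ge"]]))
  expect_equal(ft$lfb.graph.ge[ft$subject_id == "S3"], median(defined))
})

test_that("family and band subsetting reproduce the pooled feature counts", {
  dict <- feature_dictionary()
  ft <- tibble::as_tibble(setNames(as.data.frame(t(rnorm(100))),
                                   dict$feature))
  expect_equal(ncol(select_features(ft, "all")), 100)
  expect_equal(ncol(select_features(ft, "graph")), 36)
  expect_equal(ncol(select_features(ft, "mst")), 28)
  expect_equal(ncol(select_features(ft, "triad_tmh_links")), 36)
  for (b in c("ffb", "lfb", "mfb", "hfb")) {
    expect_equal(ncol(select_features(ft, band = b)), 25)
  }
  expect_error(select_features(ft, "nope"), "no features")
})
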