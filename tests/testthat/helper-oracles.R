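# Independent brute-force oracles used across the suite. Each is a direct,
# unoptimized transcription of the defining formula, deliberately sharing no
# code with the package implementation.

# weighted Pearson correlation of two vectors, weights sum to 1
bf_weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x)
  my <- sum(w * y)
  sxy <- sum(w * (x - mx) * (y - my))
  sx <- sum(w * (x - mx)^2)
  sy <- sum(w * (y - my)^2)
  sxy / sqrt(sx * sy)
}

# explicit loop over windows + median aggregation
bf_sliding_fc <- function(x, w, shift = 1) {
  m <- nrow(x)
  W <- length(w)
  starts <- seq(1, ncol(x) - W + 1, by = shift)
  out <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      rs <- sapply(starts, function(s) {
        bf_weighted_cor(x[i, s:(s + W - 1)], x[j, s:(s + W - 1)], w)
      })
      out[i, j] <- out[j, i] <- median(rs)
    }
  }
  out
}

# all-pairs shortest paths by Floyd-Warshall on an explicit length matrix
bf_shortest_paths <- function(len) {
  m <- nrow(len)
  d <- len
  d[d == 0] <- Inf
  diag(d) <- 0
  for (k in seq_len(m)) {
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Kruskal MST on a symmetric distance matrix; returns sorted edge matrix
bf_kruskal_mst <- function(dist) {
  m <- nrow(dist)
  edges <- which(upper.tri(dist), arr.ind = TRUE)
  edges <- edges[is.finite(dist[edges]), , drop = FALSE]
  ord <- order(dist[edges])
  edges <- edges[ord, , drop = FALSE]
  parent <- seq_len(m)
  find <- function(v) {
    while (parent[v] != v) v <- parent[v]
    v
  }
  chosen <- matrix(integer(0), 0, 2)
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1])
    b <- find(edges[e, 2])
    if (a != b) {
      parent[a] <- b
      chosen <- rbind(chosen, sort(edges[e, ]))
    }
  }
  chosen[order(chosen[, 1], chosen[, 2]), , drop = FALSE]
}

# exhaustive triple loop: census by positive-edge count + energy
bf_triads <- function(fc) {
  m <- nrow(fc)
  counts <- c(t0 = 0, t1 = 0, t2 = 0, t3 = 0)
  ssum <- 0
  delta <- 0
  for (x in 1:(m - 2)) {
    for (y in (x + 1):(m - 1)) {
      for (z in (y + 1):m) {
        wxy <- fc[x, y]; wxz <- fc[x, z]; wyz <- fc[y, z]
        if (wxy != 0 && wxz != 0 && wyz != 0) {
          npos <- sum(c(wxy, wxz, wyz) > 0)
          counts[npos + 1] <- counts[npos + 1] + 1
          ssum <- ssum + wxy * wxz * wyz
          delta <- delta + 1
        }
      }
    }
  }
  c(counts, energy = if (delta > 0) -ssum / delta else NA_real_)
}

# two-pass loop for positive/negative hub-tendency
bf_tmh <- function(fc) {
  m <- nrow(fc)
  dp <- dn <- numeric(m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j != i) {
        if (fc[i, j] > 0) dp[i] <- dp[i] + fc[i, j]
        if (fc[i, j] < 0) dn[i] <- dn[i] - fc[i, j]
      }
    }
  }
  c(positive = if (sum(dp) > 0) sum(dp^2) / sum(dp) else NA_real_,
    negative = if (sum(dn) > 0) sum(dn^2) / sum(dn) else NA_real_)
}

# two-sided rank-sum p, normal approximation with tie correction and
# continuity correction, written from the textbook formula
bf_rank_sum_p <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nt <- table(r)
  bign <- n1 + n2
  sig2 <- n1 * n2 / 12 * ((bign + 1) - sum(nt^3 - nt) / (bign * (bign - 1)))
  if (sig2 == 0) return(1)
  z <- (abs(u - mu) - 0.5) / sqrt(sig2)
  2 * stats::pnorm(-max(z, 0))
}

# random signed FC matrix with connected positive subgraph
random_signed_fc <- function(m, seed, neg_frac = 0.25) {
  set.seed(seed)
  repeat {
    w <- matrix(0, m, m)
    vals <- runif(m * (m - 1) / 2, 0.05, 0.9)
    flip <- runif(length(vals)) < neg_frac
    vals[flip] <- -vals[flip]
    w[upper.tri(w)] <- vals
    w <- w + t(w)
    pos <- w > 0
    g <- igraph::graph_from_adjacency_matrix(pos, mode = "undirected")
    if (igraph::components(g)$no == 1) return(w)
  }
}

# small two-class feature table with `informative` shifted columns
toy_feature_table <- function(n_per_class = 30, n_features = 8,
                              informative = 1, d = 2, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), each = n_per_class))
  x <- matrix(rnorm(2 * n_per_class * n_features), 2 * n_per_class)
  for (j in seq_len(informative)) x[y == "B", j] <- x[y == "B", j] + d
  colnames(x) <- paste0("f", seq_len(n_features))
  dplyr::bind_cols(tibble::tibble(group = y), tibble::as_tibble(x))
}
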