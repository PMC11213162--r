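#' Configuration objects for the wrapper feature selectors and the SVM
#'
#' `pso_config()` parameterizes binary particle swarm optimization: swarm of
#' 20 particles, cognitive and social coefficients 1.5, inertia 0.72,
#' velocities clipped to `± v_max` and mapped through a sigmoid to per-bit
#' Bernoulli position updates. `sa_config()` parameterizes simulated
#' annealing with initial temperature 10, Boltzmann acceptance
#' `P = exp(-theta / T)` (theta = best-so-far fitness minus the neighbor's)
#' and geometric cooling. `svm_config()` parameterizes the RBF-kernel SVM
#' used both inside the fitness function and for final classification;
#' `gamma = NULL` applies the variance-scaled rule
#' `1 / (n_features * var(X))`.
#'
#' @param swarm_size,cognitive,social,inertia,iterations,v_max Binary PSO
#'   hyperparameters.
#' @param seed Integer seed making a selection run reproducible.
#' @return A config object (`gfc_pso_config` / `gfc_sa_config` /
#'   `gfc_svm_config`).
#' @export
pso_config <- function(swarm_size = 20, cognitive = 1.5, social = 1.5,
                       inertia = 0.72, iterations = 50, v_max = 4,
                       seed = 1) {
  if (!is_count(swarm_size, 2)) abort("swarm_size must be an integer >= 2")
  if (!is_count(iterations, 1)) abort("iterations must be an integer >= 1")
  structure(list(swarm_size = swarm_size, cognitive = cognitive,
                 social = social, inertia = inertia,
                 iterations = iterations, v_max = v_max, seed = seed),
            class = "gfc_pso_config")
}

#' @rdname pso_config
#' @param t_initial,cooling_ratio,iters_per_temp,t_min Simulated annealing
#'   hyperparameters: initial temperature, geometric cooling factor, flips
#'   evaluated per temperature level, and the temperature floor that ends the
#'   run.
#' @export
sa_config <- function(t_initial = 10, cooling_ratio = 0.95,
                      iters_per_temp = 20, t_min = 1e-3, seed = 1) {
  if (!(cooling_ratio > 0 && cooling_ratio < 1)) {
    abort("cooling_ratio must be in (0, 1)")
  }
  if (!(t_initial > t_min && t_min > 0)) {
    abort("need t_initial > t_min > 0")
  }
  if (!is_count(iters_per_temp, 1)) {
    abort("iters_per_temp must be an integer >= 1")
  }
  structure(list(t_initial = t_initial, cooling_ratio = cooling_ratio,
                 iters_per_temp = iters_per_temp, t_min = t_min,
                 seed = seed),
            class = "gfc_sa_config")
}

#' @rdname pso_config
#' @param cost SVM soft-margin cost C.
#' @param gamma RBF kernel width; `NULL` for the variance-scaled rule.
#' @param standardize Center/scale features on the training data.
#' @export
svm_config <- function(cost = 1, gamma = NULL, standardize = TRUE, seed = 1) {
  if (!(cost > 0)) abort("cost must be > 0")
  if (!is.null(gamma) && !(gamma > 0)) abort("explicit gamma must be > 0")
  structure(list(cost = cost, gamma = gamma, standardize = standardize,
                 seed = seed),
            class = "gfc_svm_config")
}

# feature-table accessors: id columns out, numeric matrix + labels
feature_matrix <- function(features) {
  cols <- setdiff(names(features), c("subject_id", "group"))
  x <- as.matrix(features[cols])
  storage.mode(x) <- "double"
  x
}

feature_labels <- function(features, labels = NULL) {
  y <- labels %||% features$group
  if (is.null(y)) abort("no labels: supply `labels` or a `group` column")
  y <- factor(y)
  if (nlevels(y) != 2) abort("exactly two classes are required")
  droplevels(y)
}

# center/scale by training statistics; zero-sd columns are left centered
standardize_train_test <- function(xtr, xte = NULL) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  scale_m <- function(x) sweep(sweep(x, 2, mu), 2, sdv, "/")
  list(train = scale_m(xtr), test = if (!is.null(xte)) scale_m(xte))
}

resolve_gamma <- function(x, cfg) {
  cfg$gamma %||% {
    v <- stats::var(as.vector(x))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(x) * v)
  }
}

fit_svm <- function(x, y, cfg) {
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = cfg$cost, gamma = resolve_gamma(x, cfg), scale = FALSE)
}

# stratified fold assignment, deterministic given seed
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Wrapper fitness: inner-cross-validated SVM accuracy of a feature mask
#'
#' Mean accuracy of an RBF-kernel SVM over stratified `inner_folds`, trained
#' on the masked features, standardized per fold on the training split only.
#' An empty mask scores 0 (penalty). Deterministic given `seed`.
#'
#' @param mask Logical vector over the feature columns.
#' @param features Feature table (tibble with `group` and feature columns) or
#'   numeric matrix.
#' @param labels Two-level factor; defaults to `features$group`.
#' @param inner_folds Number of inner CV folds.
#' @param svm Config from [svm_config()].
#' @param seed Integer seed for the fold assignment.
#' @return Mean inner-CV accuracy in \[0, 1\].
#' @export
selection_fitness <- function(mask, features, labels = NULL,
                              inner_folds = 5, svm = svm_config(),
                              seed = 1) {
  x <- if (is.matrix(features)) features else feature_matrix(features)
  y <- if (is.matrix(features)) feature_labels(NULL, labels)
       else feature_labels(features, labels)
  mask <- as.logical(mask)
  if (length(mask) != ncol(x)) {
    abort("mask length must equal the number of feature columns")
  }
  if (!any(mask)) return(0)
  if (min(table(y)) < inner_folds) {
    abort("each class needs at least `inner_folds` subjects")
  }
  xs <- x[, mask, drop = FALSE]
  fold <- stratified_folds(y, inner_folds, seed)
  acc <- map_dbl(seq_len(inner_folds), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) abort("single-class inner training fold")
    parts <- if (svm$standardize) {
      standardize_train_test(xs[tr, , drop = FALSE], xs[!tr, , drop = FALSE])
    } else {
      list(train = xs[tr, , drop = FALSE], test = xs[!tr, , drop = FALSE])
    }
    fit <- fit_svm(parts$train, y[tr], svm)
    mean(predict(fit, parts$test) == y[!tr])
  })
  mean(acc)
}

# memoized fitness over masks (packed to a key); one cache per selection run
make_cached_fitness <- function(fitness_fn) {
  cache <- new.env(parent = emptyenv())
  function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- fitness_fn(mask)
    cache[[key]] <- val
    val
  }
}

new_selection_result <- function(mask, feature_names, best_fitness, trace,
                                 optimizer, config) {
  structure(
    list(mask = setNames(mask, feature_names),
         selected = feature_names[mask],
         best_fitness = best_fitness,
         fitness_trace = trace,
         n_selected = sum(mask),
         optimizer = optimizer,
         config = config),
    class = "gfc_selection")
}

#' @export
print.gfc_selection <- function(x, ...) {
  cat(sprintf("<gfc_selection> %s: %d / %d features, fitness %.4f\n",
              toupper(x$optimizer), x$n_selected, length(x$mask),
              x$best_fitness))
  invisible(x)
}

#' Binary particle swarm feature selection
#'
#' Velocities follow the canonical PSO update with inertia, cognitive and
#' social terms against the personal and global best positions, are clipped
#' to `± v_max`, and are mapped through a sigmoid to per-bit Bernoulli
#' position resampling (binary PSO). The best-so-far mask and its fitness
#' are returned together with the per-iteration best-so-far trace, which is
#' non-decreasing by construction. An all-zero candidate mask is repaired to
#' the best singleton.
#'
#' @param features Feature table or numeric matrix.
#' @param labels Two-level factor; defaults to `features$group`.
#' @param config A [pso_config()].
#' @param fitness Function `mask -> fitness`; defaults to
#'   [selection_fitness()] with `inner_folds` and `svm`.
#' @param inner_folds,svm Passed to the default fitness.
#' @return A `gfc_selection` object.
#' @export
pso_select <- function(features, labels = NULL, config = pso_config(),
                       fitness = NULL, inner_folds = 5, svm = svm_config()) {
  x <- if (is.matrix(features)) features else feature_matrix(features)
  nm <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  fit_fn <- fitness %||% function(mask) {
    selection_fitness(mask, features, labels, inner_folds = inner_folds,
                      svm = svm, seed = config$seed)
  }
  f <- make_cached_fitness(fit_fn)
  d <- ncol(x)
  with_seed(config$seed, {
    pos <- matrix(runif(config$swarm_size * d) < 0.5, config$swarm_size, d)
    for (i in seq_len(config$swarm_size)) {
      if (!any(pos[i, ])) pos[i, sample.int(d, 1)] <- TRUE
    }
    vel <- matrix(0, config$swarm_size, d)
    pfit <- apply(pos, 1, f)
    pbest <- pos
    gbest_i <- which.max(pfit)
    gbest <- pos[gbest_i, ]
    gfit <- pfit[gbest_i]
    trace <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      r1 <- matrix(runif(config$swarm_size * d), config$swarm_size, d)
      r2 <- matrix(runif(config$swarm_size * d), config$swarm_size, d)
      vel <- config$inertia * vel +
        config$cognitive * r1 * (pbest - pos) +
        config$social * r2 * (matrix(gbest, config$swarm_size, d,
                                     byrow = TRUE) - pos)
      vel <- pmin(pmax(vel, -config$v_max), config$v_max)
      prob <- 1 / (1 + exp(-vel))
      pos <- matrix(runif(config$swarm_size * d), config$swarm_size, d) < prob
      for (i in seq_len(config$swarm_size)) {
        if (!any(pos[i, ])) pos[i, sample.int(d, 1)] <- TRUE
      }
      fits <- apply(pos, 1, f)
      improved <- fits > pfit
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pfit[improved] <- fits[improved]
      if (max(pfit) > gfit) {
        gbest_i <- which.max(pfit)
        gbest <- pbest[gbest_i, ]
        gfit <- pfit[gbest_i]
      }
      trace[it] <- gfit
    }
    if (!any(gbest)) {
      singles <- map_dbl(seq_len(d), function(j) {
        mk <- rep(FALSE, d); mk[j] <- TRUE; f(mk)
      })
      gbest <- rep(FALSE, d)
      gbest[which.max(singles)] <- TRUE
      gfit <- max(singles)
    }
    new_selection_result(as.logical(gbest), nm, gfit, trace, "pso", config)
  })
}

# Boltzmann acceptance for a worse neighbor: theta measured against the
# best-so-far fitness
sa_accept_prob <- function(f_best, f_neighbor, temp) {
  theta <- f_best - f_neighbor
  if (theta <= 0) return(1)
  exp(-theta / temp)
}

#' Simulated annealing feature selection
#'
#' Starts from a random mask; each step flips one uniformly chosen bit.
#' Improvements over the current mask are always accepted; worse neighbors
#' are accepted with Boltzmann probability `exp(-theta / T)`, where `theta`
#' is the fitness gap to the best solution found so far. The temperature
#' cools geometrically (`T <- cooling_ratio * T` every `iters_per_temp`
#' steps) from `t_initial` until `t_min`. The best-ever mask is returned.
#'
#' @inheritParams pso_select
#' @param config A [sa_config()].
#' @return A `gfc_selection` object (trace = best-so-far per evaluation).
#' @export
sa_select <- function(features, labels = NULL, config = sa_config(),
                      fitness = NULL, inner_folds = 5, svm = svm_config()) {
  x <- if (is.matrix(features)) features else feature_matrix(features)
  nm <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  fit_fn <- fitness %||% function(mask) {
    selection_fitness(mask, features, labels, inner_folds = inner_folds,
                      svm = svm, seed = config$seed)
  }
  f <- make_cached_fitness(fit_fn)
  d <- ncol(x)
  with_seed(config$seed, {
    cur <- runif(d) < 0.5
    if (!any(cur)) cur[sample.int(d, 1)] <- TRUE
    f_cur <- f(cur)
    best <- cur
    f_best <- f_cur
    temp <- config$t_initial
    trace <- numeric(0)
    while (temp >= config$t_min) {
      for (s in seq_len(config$iters_per_temp)) {
        nb <- cur
        j <- sample.int(d, 1)
        nb[j] <- !nb[j]
        if (!any(nb)) nb[sample.int(d, 1)] <- TRUE
        f_nb <- f(nb)
        if (f_nb > f_best) {
          best <- nb
          f_best <- f_nb
        }
        if (f_nb >= f_cur ||
            runif(1) < sa_accept_prob(f_best, f_nb, temp)) {
          cur <- nb
          f_cur <- f_nb
        }
        trace <- c(trace, f_best)
      }
      temp <- temp * config$cooling_ratio
    }
    new_selection_result(as.logical(best), nm, f_best, trace, "sa", config)
  })
}

#' @export
tidy.gfc_selection <- function(x, ...) {
  tibble(feature = names(x$mask), selected = unname(x$mask))
}

#' @export
glance.gfc_selection <- function(x, ...) {
  tibble(optimizer = x$optimizer, n_selected = x$n_selected,
         n_features = length(x$mask), best_fitness = x$best_fitness,
         n_evaluated = length(x$fitness_trace))
}

#' Plot a selection run's best-so-far fitness trace
#'
#' @param object A `gfc_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gfc_selection <- function(object, ...) {
  df <- tibble(step = seq_along(object$fitness_trace),
               fitness = object$fitness_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "evaluation", y = "best-so-far fitness",
                  title = sprintf("%s feature selection",
                                  toupper(object$optimizer))) +
    ggplot2::theme_minimal()
}
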