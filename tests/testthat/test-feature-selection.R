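test_that("fitness is inner-CV accuracy with the documented edge cases", {
  # one feature that perfectly separates the classes
  y <- factor(rep(c("A", "B"), each = 20))
  sep <- dplyr::bind_cols(
    tibble::tibble(group = y),
    tibble::as_tibble(matrix(rnorm(40 * 3), 40,
                             dimnames = list(NULL, c("f1", "f2", "f3")))))
  sep$f1 <- ifelse(y == "B", 10, -10) + rnorm(40, sd = 0.1)
  expect_equal(selection_fitness(c(TRUE, FALSE, FALSE), sep, seed = 2), 1)

  # empty mask is penalized to zero
  expect_equal(selection_fitness(c(FALSE, FALSE, FALSE), sep, seed = 2), 0)

  # permuted labels on a null table hover at chance
  null_tbl <- toy_feature_table(100, 10, informative = 0, seed = 10)
  set.seed(3)
  null_tbl$group <- sample(null_tbl$group)
  f <- selection_fitness(rep(TRUE, 10), null_tbl, seed = 4)
  expect_gt(f, 0.4)
  expect_lt(f, 0.6)

  # duplicating an unselected column cannot change the fitness
  base <- toy_feature_table(20, 4, seed = 5)
  f1 <- selection_fitness(c(TRUE, TRUE, FALSE, FALSE), base, seed = 6)
  dup <- dplyr::mutate(base, f5 = .data$f3)
  f2 <- selection_fitness(c(TRUE, TRUE, FALSE, FALSE, FALSE), dup, seed = 6)
  expect_identical(f1, f2)

  expect_error(selection_fitness(rep(TRUE, 3), sep, inner_folds = 50),
               "at least")
})

test_that("PSO finds at least the best singleton and is reproducible", {
  tbl <- toy_feature_table(20, 8, informative = 1, d = 2.5, seed = 7)
  fit_seed <- 11
  fitness <- function(mask) selection_fitness(mask, tbl, seed = fit_seed)

  # exhaustive search over all 255 non-empty masks
  masks <- expand.grid(rep(list(c(FALSE, TRUE)), 8))
  masks <- masks[rowSums(masks) > 0, ]
  all_fits <- apply(masks, 1, fitness)
  best_exhaustive <- max(all_fits)
  singles <- sapply(1:8, function(j) fitness(seq_len(8) == j))

  sel <- pso_select(tbl, config = pso_config(iterations = 12, seed = 1),
                    fitness = fitness)
  expect_gte(sel$best_fitness, max(singles))
  expect_lte(sel$best_fitness, best_exhaustive + 1e-12)
  # recorded fitness agrees with recomputation on the returned mask
  expect_equal(sel$best_fitness, fitness(sel$mask), tolerance = 1e-12)
  # best-so-far trace is non-decreasing
  expect_true(all(diff(sel$fitness_trace) >= 0))

  sel2 <- pso_select(tbl, config = pso_config(iterations = 12, seed = 1),
                     fitness = fitness)
  expect_identical(sel[c("mask", "best_fitness", "fitness_trace")],
                   sel2[c("mask", "best_fitness", "fitness_trace")])

  # SA reaches within 0.02 of the exhaustive optimum for some seed in 1..5
  sa_best <- max(sapply(1:5, function(s) {
    sa_select(tbl, config = sa_config(t_initial = 1, cooling_ratio = 0.8,
                                      iters_per_temp = 10, t_min = 0.05,
                                      seed = s),
              fitness = fitness)$best_fitness
  }))
  expect_gte(sa_best, best_exhaustive - 0.02)
})

test_that("SA acceptance follows the Boltzmann rule and freezes at low temperature", {
  # P(theta = T) = 1/e exactly, and empirically over binary draws
  expect_equal(gfcband:::sa_accept_prob(0.8, 0.8 - 0.2, 0.2), exp(-1))
  set.seed(13)
  acc <- mean(runif(1e4) < gfcband:::sa_accept_prob(0.8, 0.6, 0.2))
  expect_lt(abs(acc - exp(-1)), 3 * sqrt(exp(-1) * (1 - exp(-1)) / 1e4) + 1e-3)
  # improvements are always accepted
  expect_equal(gfcband:::sa_accept_prob(0.5, 0.7, 0.2), 1)
  # at T -> 0 any worse neighbor is rejected almost surely
  expect_lt(gfcband:::sa_accept_prob(0.8, 0.79, 1e-6), 1e-300)

  # hill-climbing limit: the accepted trajectory never worsens, so the
  # current fitness always equals the best-so-far at the end
  tbl <- toy_feature_table(15, 6, informative = 1, d = 3, seed = 8)
  fitness <- function(mask) selection_fitness(mask, tbl, seed = 21)
  sel <- sa_select(tbl, config = sa_config(t_initial = 1e-6,
                                           cooling_ratio = 0.5,
                                           iters_per_temp = 30,
                                           t_min = 1e-7, seed = 3),
                   fitness = fitness)
  expect_equal(sel$best_fitness, fitness(sel$mask), tolerance = 1e-12)
  expect_true(all(diff(sel$fitness_trace) >= 0))
})

test_that("selection results are tidy-able and mask bookkeeping is consistent", {
  tbl <- toy_feature_table(15, 5, seed = 9)
  sel <- pso_select(tbl, config = pso_config(iterations = 3, seed = 2))
  expect_s3_class(sel, "gfc_selection")
  expect_equal(sel$n_selected, sum(sel$mask))
  expect_gte(sel$n_selected, 1)
  expect_identical(sel$selected, names(sel$mask)[sel$mask])
  td <- tidy(sel)
  expect_equal(nrow(td), 5)
  expect_equal(sum(td$selected), sel$n_selected)
  gl <- glance(sel)
  expect_equal(gl$optimizer, "pso")
  expect_equal(gl$best_fitness, sel$best_fitness)
  p <- autoplot(sel)
  expect_s3_class(p, "ggplot")
})

test_that("both optimizers recover planted informative features", {
  # 5 informative among 30 at d = 1.5: the union over a few seeded runs
  # must contain at least 4 of the 5 planted columns
  tbl <- toy_feature_table(50, 30, informative = 5, d = 1.5, seed = 17)
  planted <- paste0("f", 1:5)
  hits <- function(selector) {
    picked <- unlist(lapply(1:4, function(s) {
      if (selector == "pso") {
        pso_select(tbl, config = pso_config(iterations = 8, seed = s),
                   inner_folds = 3)$selected
      } else {
        sa_select(tbl, config = sa_config(t_initial = 1,
                                          cooling_ratio = 0.7,
                                          iters_per_temp = 15,
                                          t_min = 0.05, seed = s),
                  inner_folds = 3)$selected
      }
    }))
    length(intersect(planted, picked))
  }
  expect_gte(hits("pso"), 4)
  expect_gte(hits("sa"), 4)
})
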