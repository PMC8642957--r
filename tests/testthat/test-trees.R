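test_that("normalized Shannon gain matches hand-computed values", {
  # perfect balanced split: H_c = H_s = I = 1
  expect_equal(split_score(c(1, 1), c(-1, -1)), 1)
  # uninformative split
  expect_equal(split_score(c(1, -1), c(1, -1)), 0)
  # 3:1 parent split into [1,1] | [1,0]
  hc <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  i <- hc - 0.5 * 1
  expect_equal(split_score(c(1, 1), c(1, -1)), 2 * i / (hc + 1))
  expect_equal(split_score(c(1, 1), c(1, -1)), 0.3437, tolerance = 1e-4)
  expect_error(split_score(c(1, 1), integer(0)), "empty side")
})

test_that("split score stays in [0,1] and weighting equals replication", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    y <- sample(c(-1L, 1L), n, replace = TRUE)
    k <- sample(seq_len(n - 1), 1)
    s <- split_score(y[1:k], y[(k + 1):n])
    expect_gte(s, 0); expect_lte(s, 1)
    # doubling every sample (or doubling all weights) changes nothing
    s2 <- split_score(rep(y[1:k], 2), rep(y[(k + 1):n], 2))
    expect_equal(s, s2)
  }
})

test_that("exhaustive decision-tree split matches the stump oracle", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    x <- matrix(sample(0:5, 2 * n, replace = TRUE) + rnorm(2 * n, 0, 0.01),
                n, 2)
    y <- sample(c(-1L, 1L), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    best <- lpiboost:::.best_exhaustive_split(x, seq_len(n), y,
                                              rep(1, n), "gain")
    oracle <- oracle_best_stump_gain(x, y)
    if (is.null(best)) {
      expect_equal(oracle, 0)
    } else {
      expect_equal(best$gain, oracle, tolerance = 1e-10)
    }
  }
})

test_that("decision tree reproduces the info-gain extremes", {
  # a feature that splits the classes perfectly is used (gain 1)
  x <- cbind(c(1, 2, 3, 4), c(1, 2, 1, 2))
  y <- c(1L, 1L, -1L, -1L)
  tr <- grow_decision_tree(x, y, params = tree_params(n_min = 2))
  expect_false(tr$leaf)
  expect_equal(tr$feature, 1)
  expect_equal(tr$gain, 1)
  expect_equal(predict_tree(tr, x), c(1, 1, 0, 0))
  # only an evenly-mixing feature available: no positive gain, leaf
  x2 <- cbind(c(1, 2, 1, 2))
  tr2 <- grow_decision_tree(x2, y, params = tree_params(n_min = 2))
  expect_true(tr2$leaf)
})

test_that("random split selection respects its contracts", {
  x <- matrix(c(0, 1), 2, 1)
  y <- c(-1L, 1L)
  got <- lpiboost:::with_seed(5, pick_random_split(x, y, c(1, 1), K = 1))
  expect_equal(got$feature, 1)
  expect_gt(got$cut, 0); expect_lt(got$cut, 1)
  expect_equal(got$score, 1) # any interior cut separates perfectly
  # K larger than the number of non-constant features: all are used
  x3 <- cbind(c(0, 0, 1, 1), c(5, 5, 5, 5))
  g3 <- lpiboost:::with_seed(5, pick_random_split(x3, c(-1L, -1L, 1L, 1L),
                                                  rep(1, 4), K = 10))
  expect_equal(g3$feature, 1)
  # all-constant: no candidate
  expect_null(lpiboost:::with_seed(5,
    pick_random_split(matrix(1, 3, 2), c(1L, 1L, -1L), rep(1, 3), K = 2)))
  # determinism under a fixed seed
  a <- lpiboost:::with_seed(7, pick_random_split(x3, c(-1L, -1L, 1L, 1L),
                                                 rep(1, 4), K = 1))
  b <- lpiboost:::with_seed(7, pick_random_split(x3, c(-1L, -1L, 1L, 1L),
                                                 rep(1, 4), K = 1))
  expect_identical(a, b)
})

test_that("extra trees grow, stop and reproduce deterministically", {
  # pure node: single leaf
  x <- matrix(rnorm(10), 5, 2)
  t0 <- grow_extra_tree(x, rep(1L, 5))
  expect_true(t0$leaf)
  # two separable points reach training accuracy 1 at depth 1
  x2 <- matrix(c(0, 1, 0, 1), 2, 2)
  y2 <- c(-1L, 1L)
  t2 <- lpiboost:::with_seed(3,
    grow_extra_tree(x2, y2, params = tree_params(n_min = 2)))
  expect_false(t2$leaf)
  expect_equal(ifelse(predict_tree(t2, x2) > 0.5, 1L, -1L), y2)
  # bit-reproducible under the same seed
  set.seed(99)
  x3 <- matrix(rnorm(60), 20, 3)
  y3 <- ifelse(x3[, 1] + rnorm(20, 0, 0.3) > 0, 1L, -1L)
  ta <- lpiboost:::with_seed(11, grow_extra_tree(x3, y3))
  tb <- lpiboost:::with_seed(11, grow_extra_tree(x3, y3))
  expect_identical(ta, tb)
  # separable data with unrestricted depth: accuracy 1 whatever the seed
  ysep <- ifelse(x3[, 2] > 0, 1L, -1L)
  for (s in 1:5) {
    tr <- lpiboost:::with_seed(s, grow_extra_tree(
      x3, ysep, params = tree_params(n_min = 2, max_depth = 30)))
    expect_equal(ifelse(predict_tree(tr, x3) > 0.5, 1L, -1L), ysep)
  }
})

test_that("decision-tree structure is invariant to sample duplication", {
  set.seed(13)
  x <- matrix(rnorm(40), 20, 2)
  y <- ifelse(x[, 1] - x[, 2] > 0, 1L, -1L)
  strip_n <- function(node) {
    node$n <- NULL
    if (!isTRUE(node$leaf)) {
      node$left <- strip_n(node$left)
      node$right <- strip_n(node$right)
    }
    node
  }
  t1 <- grow_decision_tree(x, y)
  t2 <- grow_decision_tree(rbind(x, x), c(y, y), rep(0.5 / 20, 40))
  expect_equal(strip_n(t1), strip_n(t2))
})

test_that("forest voting follows the documented tie rules", {
  leaf_tree <- function(p) structure(list(leaf = TRUE, prop = p,
                                          vote = if (p > 0.5) 1L else -1L,
                                          n = 1L), class = "lpi_tree")
  mk_forest <- function(props) structure(
    list(trees = lapply(props, leaf_tree), params = tree_params(), seed = 1),
    class = "lpi_forest")
  x1 <- matrix(0, 1, 2)
  # unanimous vote
  f <- mk_forest(c(0.9, 0.8, 0.7))
  pr <- predict_forest(f, x1)
  expect_equal(pr$label, 1L)
  expect_gte(pr$score, 0.5)
  # single-tree forest is the tree
  f1 <- mk_forest(0.2)
  expect_equal(predict_forest(f1, x1)$label, -1L)
  expect_equal(predict_forest(f1, x1)$score, 0.2)
  # 1-1 vote tie resolved by the mean score (0.65 -> +1)
  f2 <- mk_forest(c(0.9, 0.4))
  pr2 <- predict_forest(f2, x1)
  expect_equal(pr2$score, 0.65)
  expect_equal(pr2$label, 1L)
  # tie with mean exactly 0.5 falls to -1
  f3 <- mk_forest(c(0.9, 0.1))
  expect_equal(predict_forest(f3, x1)$label, -1L)
  # seeded forests are reproducible
  set.seed(1)
  x <- matrix(rnorm(40), 20, 2)
  y <- ifelse(x[, 1] > 0, 1L, -1L)
  fa <- grow_extra_forest(x, y, params = tree_params(n_trees = 3), seed = 5)
  fb <- grow_extra_forest(x, y, params = tree_params(n_trees = 3), seed = 5)
  expect_identical(fa, fb)
})
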