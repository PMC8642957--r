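# small separable training set shared by the fitting tests
make_blobs <- function(n = 60, seed = 1, gap = 1) {
  # strictly separable along the first coordinate
  set.seed(seed)
  y <- rep(c(-1L, 1L), each = n / 2)
  x <- cbind(runif(n) + (gap + 1) * (y == 1), rnorm(n))
  list(x = x, y = y)
}

test_that("boosting algebra matches hand-computed values", {
  expect_equal(weighted_error(c(1, 1, -1, -1), c(1, 1, -1, -1),
                              rep(0.25, 4)), 0)
  expect_equal(weighted_error(c(-1, -1, 1, 1), c(1, 1, -1, -1),
                              rep(0.25, 4)), 1)
  expect_equal(weighted_error(c(1, 1, -1, 1), c(1, 1, -1, -1),
                              rep(0.25, 4)), 0.25)

  expect_equal(learner_weight(0.25), 0.5 * log(3))
  expect_error(learner_weight(0.5), "not a weak learner")
  expect_true(is.finite(learner_weight(0)))
  expect_equal(learner_weight(1e-12), learner_weight(0)) # clipped floor
  # alpha -> 0 as error -> 0.5 from below
  expect_lt(learner_weight(0.4999), 5e-4)

  # uniform weights, alpha = 0.5 ln 3, one of four misclassified:
  # the wrong sample moves to 1/2, the rest to 1/6 each
  w <- update_weights(rep(0.25, 4), 0.5 * log(3),
                      c(-1, 1, 1, 1), c(1, 1, 1, 1))
  expect_equal(w, c(0.5, 1 / 6, 1 / 6, 1 / 6))
  # all correct: renormalization restores the original weights
  w2 <- update_weights(c(0.1, 0.2, 0.3, 0.4), 1, c(1, 1, -1, -1),
                       c(1, 1, -1, -1))
  expect_equal(w2, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(update_weights(rep(0.25, 4), 0, c(1, -1, 1, -1),
                              c(1, 1, 1, 1)), rep(0.25, 4))
  # printed-sign mode moves the weight the other way
  wp <- update_weights(rep(0.25, 4), 0.5 * log(3),
                       c(-1, 1, 1, 1), c(1, 1, 1, 1), mode = "as_printed")
  expect_lt(wp[1], 0.25)
})

test_that("weight updates keep a normalized distribution and up-weight errors", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    w <- runif(n); w <- w / sum(w)
    y <- sample(c(-1, 1), n, replace = TRUE)
    p <- sample(c(-1, 1), n, replace = TRUE)
    err <- weighted_error(p, y, w)
    if (err <= 0 || err >= 0.5) next
    a <- learner_weight(err)
    w2 <- update_weights(w, a, p, y)
    expect_equal(sum(w2), 1, tolerance = 1e-9)
    expect_true(all(w2 >= 0))
    wrong <- p != y
    expect_true(all(w2[wrong] > w[wrong]))
  }
})

test_that("fitting a separable problem reaches training accuracy 1 quickly", {
  b <- make_blobs(seed = 2)
  fit <- fit_ensemble(b$x, b$y,
                      tparams = tree_params(n_min = 2, max_depth = 15,
                                            n_trees = 5),
                      bparams = boost_params(max_iter = 4, patience = 2,
                                             candidates = 3, seed = 3))
  expect_s3_class(fit, "lpi_ensemble")
  expect_equal(predict(fit, b$x), b$y)
  # families alternate deterministically with iteration parity
  fams <- vapply(fit$learners, `[[`, character(1), "family")
  expect_identical(fams,
                   ifelse(seq_along(fams) %% 2 == 1, "extra_tree",
                          "decision_tree"))
  # every accepted learner is a weak learner with positive weight
  expect_true(all(vapply(fit$learners, `[[`, numeric(1), "alpha") > 0))
  expect_true(all(vapply(fit$learners, `[[`, numeric(1), "error") < 0.5))
  # best validation AUC is the max of the history
  expect_equal(fit$best_auc, max(fit$history))
})

test_that("patience zero keeps exactly one learner", {
  b <- make_blobs(seed = 4)
  fit <- fit_ensemble(b$x, b$y,
                      tparams = tree_params(n_min = 2, n_trees = 3),
                      bparams = boost_params(patience = 0, seed = 1))
  expect_length(fit$learners, 1)
  expect_identical(fit$learners[[1]]$family, "extra_tree")
})

test_that("a single-learner ensemble reduces to that learner", {
  b <- make_blobs(seed = 5)
  fit <- fit_ensemble(b$x, b$y,
                      tparams = tree_params(n_min = 2, n_trees = 3),
                      bparams = boost_params(patience = 0, seed = 2))
  f1 <- fit$learners[[1]]$model
  expect_equal(predict(fit, b$x), predict_forest(f1, b$x)$label)
  expect_equal(decision_score(fit, b$x),
               as.numeric(predict_forest(f1, b$x)$label))
})

test_that("decision scores combine learners by their weights", {
  leaf_tree <- function(p) structure(list(leaf = TRUE, prop = p,
                                          vote = if (p > 0.5) 1L else -1L,
                                          n = 1L), class = "lpi_tree")
  model <- structure(list(
    learners = list(
      list(model = leaf_tree(1), family = "decision_tree", alpha = 1,
           error = 0.1),
      list(model = leaf_tree(0), family = "decision_tree", alpha = 0.5,
           error = 0.2)),
    history = c(0.5, 0.5), best_t = 2L, best_auc = 0.5, d = 2L,
    tparams = tree_params(), bparams = boost_params()),
    class = "lpi_ensemble")
  x <- matrix(0, 3, 2)
  expect_equal(decision_score(model, x), rep((1 - 0.5) / 1.5, 3))
  expect_equal(predict(model, x), rep(1L, 3))
  expect_error(decision_score(model, matrix(0, 3, 5)), "dimension")
})

test_that("degenerate fits fail loudly", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_ensemble(x, rep(1L, 10)), "both classes")
  b <- make_blobs(seed = 6)
  expect_error(fit_ensemble(b$x, b$y, x_val = b$x[1:3, ],
                            y_val = rep(1L, 3)),
               "validation")
})

test_that("the planted-signal pipeline separates signal from permuted nulls", {
  aucs <- c(); null_aucs <- c()
  for (seed in 1:2) {
    d <- simulate_lpi(small_spec(seed))
    lf <- rna_features(d$rna, small_cfg())
    pf <- protein_features(d$protein, small_cfg())
    rl <- predict(fit_pca(lf, 15), lf)
    rp <- predict(fit_pca(pf, 11), pf)
    pairs <- make_pairs(rl, rp, d$matrix, neg_sampling(1, seed = seed))
    n <- length(pairs$label)
    te <- lpiboost:::with_seed(seed, sort(sample(n, round(0.2 * n))))
    tp <- tree_params(n_trees = 5)
    bp <- boost_params(max_iter = 10, patience = 4, candidates = 3,
                       seed = seed)
    fit <- fit_ensemble(pairs$x[-te, ], pairs$label[-te], tp, bp)
    aucs <- c(aucs, roc_auc(pairs$label[te],
                            decision_score(fit, pairs$x[te, ])))
    yperm <- lpiboost:::with_seed(seed + 100, sample(pairs$label))
    fitn <- fit_ensemble(pairs$x[-te, ], yperm[-te], tp, bp)
    null_aucs <- c(null_aucs, roc_auc(yperm[te],
                                      decision_score(fitn, pairs$x[te, ])))
  }
  expect_gt(mean(aucs), 0.75)
  expect_gt(mean(aucs) - mean(null_aucs), 0.15)
})
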