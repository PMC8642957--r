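# Weak-learner trees.
#
# Two families:
#   * extremely randomized trees: at each node, K randomly chosen
#     non-constant features each receive one cut-point drawn uniformly in
#     (min, max); the candidate with the highest normalized Shannon
#     information gain Score = 2 I / (H_c + H_s) wins.  Grown on the full
#     (weighted) sample, no bootstrap.  Several such trees vote as a small
#     forest.
#   * classic decision trees: exhaustive scan of all features and all
#     midpoints between sorted adjacent distinct values, scored by
#     information gain (default) or gain ratio.
# All entropy/gain computations use weighted class proportions so boosting
# reweighting shapes tree growth.  Cut-point semantics: values strictly
# smaller than the cut go left.

#' Tree growth parameters
#'
#' @param K number of candidate features examined per extra-tree node;
#'   default `floor(sqrt(p))` where `p` is the pair-vector length (so 14
#'   for the conventional d = 100 pipeline).  `NULL` defers the choice to
#'   fit time.
#' @param n_min minimum number of samples a node needs to be split.
#' @param max_depth depth cap (root = depth 0).
#' @param n_trees trees per extra-tree voting forest.
#' @param criterion decision-tree split criterion: `"gain"` (information
#'   gain) or `"gainratio"`.
#' @return list of class `tree_params`.
#' @export
tree_params <- function(K = NULL, n_min = 5, max_depth = 5, n_trees = 10,
                        criterion = c("gain", "gainratio")) {
  criterion <- match.arg(criterion)
  if (!is.null(K) && K < 1) stopf("K must be >= 1")
  if (n_min < 2) stopf("n_min must be >= 2")
  if (max_depth < 1) stopf("max_depth must be >= 1")
  if (n_trees < 1) stopf("n_trees must be >= 1")
  structure(list(K = K, n_min = as.integer(n_min),
                 max_depth = as.integer(max_depth),
                 n_trees = as.integer(n_trees), criterion = criterion),
            class = "tree_params")
}

# weighted positive proportion
.wprop <- function(y, w) {
  s <- sum(w)
  if (s <= 0) return(0.5)
  sum(w[y == 1L]) / s
}

# scalar binary entropy without the vectorized pmin/pmax overhead
.h2 <- function(p) {
  if (p <= 0 || p >= 1) return(0)
  -(p * log2(p) + (1 - p) * log2(1 - p))
}

# normalized Shannon gain from side aggregates (wl1 = positive weight on
# the left, wl = total weight on the left, etc.)
.score_from_sums <- function(wl1, wl, wr1, wr) {
  wt <- wl + wr
  hc <- .h2((wl1 + wr1) / wt)
  hs <- .h2(wl / wt)
  i <- hc - (wl * .h2(wl1 / wl) + wr * .h2(wr1 / wr)) / wt
  den <- hc + hs
  if (den <= 0) return(0)
  min(max(2 * i / den, 0), 1)
}

#' Normalized Shannon information gain of a candidate split
#'
#' `Score = 2 I / (H_c + H_s)` where `H_c` is the class entropy of the
#' parent, `H_s` the entropy of the left/right size split, and `I` the
#' information gain.  All three use (optionally weighted) proportions with
#' `0 log 0 := 0`; a pure parent (`H_c + H_s = 0` cannot occur for a valid
#' two-sided split, but `H_c = 0`) yields score 0.
#'
#' @param y_left,y_right labels (+1/-1) routed to each side; both must be
#'   non-empty and their union is the parent.
#' @param w_left,w_right optional non-negative sample weights.
#' @return score in `[0, 1]`.
#' @export
split_score <- function(y_left, y_right, w_left = NULL, w_right = NULL) {
  if (!length(y_left) || !length(y_right)) {
    stopf("invalid split candidate: empty side")
  }
  w_left <- w_left %||% rep(1, length(y_left))
  w_right <- w_right %||% rep(1, length(y_right))
  .score_from_sums(sum(w_left[y_left == 1L]), sum(w_left),
                   sum(w_right[y_right == 1L]), sum(w_right))
}

#' Random cut-point selection for one extra-tree node
#'
#' Draws one uniform cut-point in the open `(min, max)` interval of each of
#' up to `K` randomly chosen non-constant features and returns the
#' candidate with the highest [split_score()].  Uses the current RNG
#' stream.
#'
#' @param x sample matrix (node rows only).
#' @param y labels (+1/-1).
#' @param w sample weights.
#' @param K number of features to examine (clamped to the number of
#'   non-constant features).
#' @return list `(feature, cut, score)` or `NULL` when every feature is
#'   constant on the node.
#' @export
pick_random_split <- function(x, y, w, K) {
  .pick_random_split_idx(x, seq_len(nrow(x)), y, w, K)
}

# internal worker: operates on a row-index subset of x without copying the
# submatrix; features are scanned in a uniform random order and the first
# K non-constant ones examined (equivalent to a uniform K-subset of the
# non-constant features)
.pick_random_split_idx <- function(x, idx, y, w, K) {
  p <- ncol(x)
  ord <- if (p == 1L) 1L else sample.int(p)
  wsum <- sum(w); w1sum <- sum(w[y == 1L])
  best <- NULL
  examined <- 0L
  for (j in ord) {
    xs <- x[idx, j]
    mn <- min(xs); mx <- max(xs)
    if (mn >= mx) next
    examined <- examined + 1L
    cut <- runif(1, mn, mx)
    left <- xs < cut
    if (!any(left) || all(left)) {
      if (examined >= K) break else next # measure-zero boundary draw
    }
    wl <- sum(w[left]); wl1 <- sum(w[left & y == 1L])
    sc <- .score_from_sums(wl1, wl, w1sum - wl1, wsum - wl)
    if (is.null(best) || sc > best$score) {
      best <- list(feature = j, cut = cut, score = sc)
    }
    if (examined >= K) break
  }
  best
}

.leaf <- function(y, w) {
  p <- .wprop(y, w)
  list(leaf = TRUE, prop = p, vote = if (p > 0.5) 1L else -1L,
       n = length(y))
}

#' Grow one extremely randomized tree
#'
#' Recursion stops when a node has fewer than `n_min` samples, is pure,
#' reaches `max_depth`, or has no non-constant feature.  Leaves store the
#' weighted positive-class proportion.  Uses the current RNG stream; wrap
#' in a seeded context for reproducibility.
#'
#' @param x samples x features matrix.
#' @param y labels (+1/-1).
#' @param w non-negative weights, sum > 0.
#' @param params a [tree_params()].
#' @return nested-list tree (`TreeNode`).
#' @export
grow_extra_tree <- function(x, y, w = rep(1, length(y)), params = tree_params()) {
  stopifnot(nrow(x) == length(y), length(y) == length(w), sum(w) > 0,
            all(w >= 0))
  K <- params$K %||% max(1L, floor(sqrt(ncol(x))))
  grow <- function(idx, depth) {
    yy <- y[idx]; ww <- w[idx]
    if (length(idx) < params$n_min || depth >= params$max_depth ||
        all(yy == yy[1])) {
      return(.leaf(yy, ww))
    }
    cand <- .pick_random_split_idx(x, idx, yy, ww, K)
    if (is.null(cand)) return(.leaf(yy, ww))
    left <- x[idx, cand$feature] < cand$cut
    list(leaf = FALSE, feature = cand$feature, cut = cand$cut,
         score = cand$score,
         left = grow(idx[left], depth + 1L),
         right = grow(idx[!left], depth + 1L))
  }
  structure(grow(seq_along(y), 0L), class = "lpi_tree")
}

# exhaustive best split of one node by info gain / gain ratio; vectorized
# over the sorted order of each feature; works on a row-index subset
.best_exhaustive_split <- function(x, idx, y, w, criterion) {
  wt <- sum(w)
  w1 <- w * (y == 1L)
  h_parent <- entropy2(sum(w1) / wt)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    xs <- x[idx, j]
    o <- order(xs)
    xo <- xs[o]
    n <- length(xo)
    if (xo[1] == xo[n]) next
    cw <- cumsum(w[o])[-n]
    cw1 <- cumsum(w1[o])[-n]
    valid <- which(xo[-n] < xo[-1]) # split between distinct adjacent values
    if (!length(valid)) next
    wl <- cw[valid]; wl1 <- cw1[valid]
    wr <- wt - wl; wr1 <- sum(w1) - wl1
    gain <- h_parent - (wl * entropy2(wl1 / wl) + wr * entropy2(wr1 / wr)) / wt
    crit <- if (criterion == "gainratio") {
      hs <- entropy2(wl / wt)
      ifelse(hs > 0, gain / hs, 0)
    } else gain
    i_best <- which.max(crit)
    if (is.null(best) || crit[i_best] > best$crit + 1e-12) {
      k <- valid[i_best]
      best <- list(feature = j, cut = (xo[k] + xo[k + 1]) / 2,
                   crit = crit[i_best], gain = gain[i_best])
    }
  }
  best
}

#' Grow a classic decision tree by exhaustive split search
#'
#' At each node the best (feature, cut-point) pair over all midpoints
#' between sorted adjacent distinct values is chosen by weighted
#' information gain (or gain ratio).  Stopping rules as in
#' [grow_extra_tree()]; a node also becomes a leaf when no split has
#' positive gain.
#'
#' @inheritParams grow_extra_tree
#' @return nested-list tree.
#' @export
grow_decision_tree <- function(x, y, w = rep(1, length(y)),
                               params = tree_params()) {
  stopifnot(nrow(x) == length(y), length(y) == length(w), sum(w) > 0,
            all(w >= 0))
  grow <- function(idx, depth) {
    yy <- y[idx]; ww <- w[idx]
    if (length(idx) < params$n_min || depth >= params$max_depth ||
        all(yy == yy[1])) {
      return(.leaf(yy, ww))
    }
    cand <- .best_exhaustive_split(x, idx, yy, ww, params$criterion)
    if (is.null(cand) || cand$gain <= 1e-12) return(.leaf(yy, ww))
    left <- x[idx, cand$feature] < cand$cut
    list(leaf = FALSE, feature = cand$feature, cut = cand$cut,
         gain = cand$gain,
         left = grow(idx[left], depth + 1L),
         right = grow(idx[!left], depth + 1L))
  }
  structure(grow(seq_along(y), 0L), class = "lpi_tree")
}

#' Leaf positive-class proportion for each row
#'
#' @param tree a tree from [grow_extra_tree()] or [grow_decision_tree()].
#' @param x matrix of rows to route.
#' @return numeric vector of weighted positive proportions in `[0, 1]`.
#' @export
predict_tree <- function(tree, x) {
  out <- numeric(nrow(x))
  route <- function(node, idx) {
    if (!length(idx)) return(invisible(NULL))
    if (isTRUE(node$leaf)) {
      out[idx] <<- node$prop
      return(invisible(NULL))
    }
    left <- x[idx, node$feature] < node$cut
    route(node$left, idx[left])
    route(node$right, idx[!left])
  }
  route(tree, seq_len(nrow(x)))
  out
}

#' Grow a voting forest of extra trees
#'
#' @inheritParams grow_extra_tree
#' @param seed integer seed; tree `i` is grown under a seed derived from
#'   `(seed, i)` so forests are bit-reproducible.
#' @return list of class `lpi_forest`.
#' @export
grow_extra_forest <- function(x, y, w = rep(1, length(y)),
                              params = tree_params(), seed = 1) {
  trees <- lapply(seq_len(params$n_trees), function(i) {
    with_seed(derive_seed(seed, i), grow_extra_tree(x, y, w, params))
  })
  structure(list(trees = trees, params = params, seed = seed),
            class = "lpi_forest")
}

#' Forest prediction by voting
#'
#' Label is the majority vote over trees (a tree votes +1 when its leaf
#' positive proportion exceeds 0.5); the score is the mean leaf positive
#' proportion.  Vote ties resolve by the mean score, then to -1.
#'
#' @param forest an `lpi_forest`.
#' @param x rows to classify.
#' @return list with `label` (+1/-1) and `score` (in `[0, 1]`).
#' @export
predict_forest <- function(forest, x) {
  props <- vapply(forest$trees, predict_tree, numeric(nrow(x)), x = x)
  if (nrow(x) == 1L) props <- matrix(props, nrow = 1)
  score <- rowMeans(props)
  votes <- rowSums(ifelse(props > 0.5, 1, -1))
  label <- ifelse(votes > 0, 1L, ifelse(votes < 0, -1L,
                                        ifelse(score > 0.5, 1L, -1L)))
  list(label = as.integer(label), score = score)
}

# unified weak-learner prediction: label in {-1, +1}
.learner_predict <- function(model, x) {
  if (inherits(model, "lpi_forest")) {
    predict_forest(model, x)$label
  } else {
    p <- predict_tree(model, x)
    as.integer(ifelse(p > 0.5, 1L, -1L))
  }
}
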