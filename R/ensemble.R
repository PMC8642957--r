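# The alternating boosting loop.
#
# Odd iterations select the best (lowest weighted error) of several
# candidate extra-tree voting forests; even iterations grow the
# (deterministic) exhaustive-search decision tree.  Learners with weighted
# error >= 0.5 are rejected; accepted learners get weight
# alpha = 0.5 * ln((1 - err) / err) and the sample weights are updated
# multiplicatively.  After every iteration the running ensemble is scored
# (AUC) on a validation split; the model returned is the prefix of the
# learner sequence that achieved the best validation AUC, and fitting
# stops once the AUC has not improved for `patience` iterations.

#' Boosting parameters
#'
#' @param max_iter hard cap on boosting iterations.
#' @param patience stop after this many consecutive iterations without
#'   validation-AUC improvement (`M`); `patience = 0` keeps exactly the
#'   first learner.
#' @param candidates candidate extra-tree forests grown per odd iteration
#'   (the decision-tree family is deterministic given the weights, so even
#'   iterations always grow exactly one tree).
#' @param val_fraction fraction of the training pairs carved out
#'   (stratified) as the validation set when none is supplied.
#' @param weight_update `"standard"` multiplies by `exp(-alpha * p * y)`
#'   (misclassified samples are up-weighted); `"as_printed"` uses the
#'   opposite sign convention for comparison.
#' @param init_weights `"uniform"` (1/n) or `"balanced"`
#'   (proportional to 1 / (2 n_class), emphasizing the minority class).
#' @param retry_cap redraws of the candidate set when every candidate has
#'   error >= 0.5.
#' @param seed master seed for candidate growth and the validation split.
#' @return list of class `boost_params`.
#' @export
boost_params <- function(max_iter = 100, patience = 10, candidates = 5,
                         val_fraction = 0.2,
                         weight_update = c("standard", "as_printed"),
                         init_weights = c("uniform", "balanced"),
                         retry_cap = 3, seed = 1) {
  weight_update <- match.arg(weight_update)
  init_weights <- match.arg(init_weights)
  if (max_iter < 1 || patience < 0 || candidates < 1 || retry_cap < 0)
    stopf("invalid boosting parameters")
  if (val_fraction <= 0 || val_fraction >= 1) stopf("val_fraction in (0,1)")
  structure(list(max_iter = as.integer(max_iter),
                 patience = as.integer(patience),
                 candidates = as.integer(candidates),
                 val_fraction = val_fraction,
                 weight_update = weight_update,
                 init_weights = init_weights,
                 retry_cap = as.integer(retry_cap),
                 seed = as.integer(seed)),
            class = "boost_params")
}

#' Weighted misclassification error
#'
#' @param predictions,labels vectors in {+1, -1}.
#' @param w non-negative sample weights (normalized internally).
#' @return `sum(w * [predictions != labels]) / sum(w)`.
#' @export
weighted_error <- function(predictions, labels, w) {
  stopifnot(length(predictions) == length(labels),
            length(labels) == length(w))
  sum(w * (predictions != labels)) / sum(w)
}

#' Boosting weight of a weak learner
#'
#' `alpha = 0.5 * ln((1 - err) / err)`; the error is clipped below at
#' 1e-10 so a perfect learner gets a large finite weight.  Learners with
#' error >= 0.5 are not weak learners and must be rejected upstream; this
#' function refuses them.
#'
#' @param error weighted error in `[0, 0.5)`.
#' @return positive weight.
#' @export
learner_weight <- function(error) {
  if (error >= 0.5) stopf("not a weak learner: weighted error %.4f >= 0.5",
                          error)
  error <- max(error, 1e-10)
  0.5 * log((1 - error) / error)
}

#' Multiplicative sample-weight update
#'
#' @param w current weights (sum 1).
#' @param alpha learner weight.
#' @param predictions,labels vectors in {+1, -1}.
#' @param mode `"standard"` (`exp(-alpha p y)`) or `"as_printed"`
#'   (`exp(+alpha p y)`).
#' @return updated weights, renormalized to sum 1.
#' @export
update_weights <- function(w, alpha, predictions, labels,
                           mode = c("standard", "as_printed")) {
  mode <- match.arg(mode)
  s <- if (mode == "standard") -1 else 1
  w2 <- w * exp(s * alpha * predictions * labels)
  z <- sum(w2)
  if (!is.finite(z) || z <= 0) stopf("degenerate weight update")
  w2 / z
}

# stratified index split: returns validation indices
.stratified_val <- function(labels, fraction, seed) {
  with_seed(seed, {
    idx <- unlist(lapply(c(-1L, 1L), function(cl) {
      pool <- which(labels == cl)
      n <- max(1L, round(fraction * length(pool)))
      sample(pool, min(n, length(pool)))
    }))
    sort(idx)
  })
}

#' Fit the alternating extra-tree / decision-tree boosting ensemble
#'
#' @param x training matrix (pairs x 2d features) or an `lpi_pairs`
#'   object (then `y` is taken from it).
#' @param y labels in {+1, -1}.
#' @param tparams a [tree_params()].
#' @param bparams a [boost_params()].
#' @param x_val,y_val optional explicit validation set; when omitted a
#'   stratified `val_fraction` split of the training pairs is carved out.
#' @return object of class `lpi_ensemble`: `learners` (list of
#'   `model`/`family`/`alpha`/`error`, trimmed to the best-AUC prefix),
#'   `history` (validation AUC per iteration), `best_t`, `d` (feature
#'   count), and the parameter objects.
#' @export
fit_ensemble <- function(x, y = NULL, tparams = tree_params(),
                         bparams = boost_params(),
                         x_val = NULL, y_val = NULL) {
  if (inherits(x, "lpi_pairs")) {
    y <- x$label
    x <- x$x
  }
  stopifnot(is.matrix(x), length(y) == nrow(x))
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stopf("labels must be +1/-1")
  if (length(unique(y)) < 2) stopf("training data must contain both classes")

  if (is.null(x_val)) {
    vi <- .stratified_val(y, bparams$val_fraction,
                          derive_seed(bparams$seed, 999))
    x_val <- x[vi, , drop = FALSE]; y_val <- y[vi]
    x <- x[-vi, , drop = FALSE]; y <- y[-vi]
  }
  if (length(unique(y_val)) < 2) {
    stopf("validation set must contain both classes (AUC undefined)")
  }
  n <- length(y)
  w <- if (bparams$init_weights == "uniform") rep(1 / n, n) else {
    wi <- 1 / (2 * ifelse(y == 1L, sum(y == 1L), sum(y == -1L)))
    wi / sum(wi)
  }

  learners <- list()
  history <- numeric(0)
  val_score <- numeric(length(y_val)) # running sum of alpha * f_t on val
  best_auc <- -Inf; best_t <- 0L
  t <- 0L
  while (t < bparams$max_iter && (t - best_t) < bparams$patience + (t == 0L)) {
    t <- t + 1L
    family <- if (t %% 2L == 1L) "extra_tree" else "decision_tree"
    picked <- NULL
    n_cand <- if (family == "extra_tree") bparams$candidates else 1L
    for (attempt in 0:bparams$retry_cap) {
      for (c_i in seq_len(n_cand)) {
        model <- if (family == "extra_tree") {
          grow_extra_forest(x, y, w, tparams,
                            seed = derive_seed(bparams$seed, t, attempt, c_i))
        } else {
          grow_decision_tree(x, y, w, tparams)
        }
        pred <- .learner_predict(model, x)
        err <- weighted_error(pred, y, w)
        if (is.null(picked) || err < picked$error) {
          picked <- list(model = model, family = family, error = err,
                         pred = pred)
        }
      }
      if (picked$error < 0.5) break
      if (family == "decision_tree") break # deterministic: retries identical
      picked <- NULL
    }
    if (is.null(picked) || picked$error >= 0.5) {
      if (t == 1L) {
        stopf("no weak learner with error < 0.5 found at iteration 1")
      }
      t <- t - 1L
      break
    }
    alpha <- learner_weight(picked$error)
    w <- update_weights(w, alpha, picked$pred, y, bparams$weight_update)
    learners[[t]] <- list(model = picked$model, family = family,
                          alpha = alpha, error = picked$error)
    val_score <- val_score + alpha * .learner_predict(picked$model, x_val)
    auc <- roc_auc(y_val, val_score)
    history[t] <- auc
    if (auc > best_auc + 1e-12) {
      best_auc <- auc
      best_t <- t
    }
  }
  if (!length(learners)) stopf("boosting produced no learners")
  if (best_t == 0L) best_t <- 1L
  structure(list(learners = learners[seq_len(best_t)],
                 history = history, best_t = best_t,
                 best_auc = best_auc, d = ncol(x),
                 tparams = tparams, bparams = bparams),
            class = "lpi_ensemble")
}

#' Normalized ensemble decision score
#'
#' `sum(alpha_t f_t(x)) / sum(alpha_t)`, in `[-1, 1]`; used for ranking,
#' ROC and PR curves.
#'
#' @param model an `lpi_ensemble`.
#' @param x matrix of pair vectors (or `lpi_pairs`).
#' @return numeric scores.
#' @export
decision_score <- function(model, x) {
  if (inherits(x, "lpi_pairs")) x <- x$x
  stopifnot(is.matrix(x))
  if (ncol(x) != model$d) {
    stopf("feature dimension %d does not match training dimension %d",
          ncol(x), model$d)
  }
  alphas <- vapply(model$learners, `[[`, numeric(1), "alpha")
  s <- numeric(nrow(x))
  for (i in seq_along(model$learners)) {
    s <- s + alphas[i] * .learner_predict(model$learners[[i]]$model, x)
  }
  s / sum(alphas)
}

#' Predict interaction labels
#'
#' Sign of the weighted learner sum, with 0 mapped to -1.
#'
#' @param object an `lpi_ensemble`.
#' @param x matrix of pair vectors (or `lpi_pairs`).
#' @param ... unused.
#' @return integer labels in {+1, -1}.
#' @export
predict.lpi_ensemble <- function(object, x, ...) {
  s <- decision_score(object, x)
  as.integer(ifelse(s > 0, 1L, -1L))
}

#' @export
print.lpi_ensemble <- function(x, ...) {
  fams <- vapply(x$learners, `[[`, character(1), "family")
  cat(sprintf("<lpi_ensemble> %d weak learners (%d extra-tree forests, %d decision trees), best val AUC %.4f\n",
              length(x$learners), sum(fams == "extra_tree"),
              sum(fams == "decision_tree"), x$best_auc))
  invisible(x)
}
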