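# Metrics and the cross-validation harness.

#' Confusion counts
#'
#' @param labels,predictions vectors in {+1, -1} (or 0/1, coerced).
#' @return list of class `confusion` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(labels, predictions) {
  if (!length(labels)) stopf("empty input")
  stopifnot(length(labels) == length(predictions))
  to_pm <- function(v) ifelse(as.numeric(v) > 0, 1L, -1L)
  y <- to_pm(labels); p <- to_pm(predictions)
  structure(list(TP = sum(y == 1L & p == 1L), TN = sum(y == -1L & p == -1L),
                 FP = sum(y == -1L & p == 1L), FN = sum(y == 1L & p == -1L)),
            class = "confusion")
}

#' Precision, recall, accuracy and F1 from confusion counts
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, algebraically the harmonic mean of
#' precision and recall when both are defined.  Ratios with a zero
#' denominator are reported as 0 and flagged in the `degenerate`
#' attribute.
#'
#' @param cc a `confusion` (or anything with TP/TN/FP/FN fields).
#' @return named list `precision`, `recall`, `accuracy`, `f1`.
#' @export
classification_metrics <- function(cc) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  p <- safe_div(cc$TP, cc$TP + cc$FP)
  r <- safe_div(cc$TP, cc$TP + cc$FN)
  a <- safe_div(cc$TP + cc$TN, cc$TP + cc$TN + cc$FP + cc$FN)
  f <- safe_div(2 * cc$TP, 2 * cc$TP + cc$FP + cc$FN)
  flags <- c(precision = is.na(p), recall = is.na(r), accuracy = is.na(a),
             f1 = is.na(f))
  out <- list(precision = p %|NA|% 0, recall = r %|NA|% 0,
              accuracy = a %|NA|% 0, f1 = f %|NA|% 0)
  attr(out, "degenerate") <- names(flags)[flags]
  out
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The tie-corrected rank statistic: the probability that a random
#' positive scores above a random negative, with half credit for ties.
#'
#' @param labels vector with both classes present (+1/-1 or 1/0).
#' @param scores numeric scores, higher = more likely positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  y <- as.numeric(labels) > 0
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stopf("AUC undefined: single-class labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation: thresholds sweep the distinct score values in
#' decreasing order and the area is `sum((R_i - R_{i-1}) * P_i)`.
#'
#' @inheritParams roc_auc
#' @return AUPR in `(0, 1]`.
#' @export
pr_auc <- function(labels, scores) {
  pts <- pr_points(labels, scores)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

#' ROC / PR curve points
#'
#' One point per distinct score threshold (decreasing).
#'
#' @inheritParams roc_auc
#' @return data frames: `roc_points` with `fpr`, `tpr`, `threshold`;
#'   `pr_points` with `recall`, `precision`, `threshold`.
#' @export
roc_points <- function(labels, scores) {
  y <- as.numeric(labels) > 0
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stopf("ROC undefined: single-class labels")
  o <- order(-scores)
  ys <- y[o]; ss <- scores[o]
  last <- !duplicated(ss, fromLast = TRUE) # last index of each tie block
  tp <- cumsum(ys)[last]; fp <- cumsum(!ys)[last]
  data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1),
             threshold = c(Inf, ss[last]))
}

#' @rdname roc_points
#' @export
pr_points <- function(labels, scores) {
  y <- as.numeric(labels) > 0
  n1 <- sum(y)
  if (n1 == 0 || n1 == length(y)) stopf("PR undefined: single-class labels")
  o <- order(-scores)
  ys <- y[o]; ss <- scores[o]
  last <- !duplicated(ss, fromLast = TRUE)
  tp <- cumsum(ys)[last]
  npred <- seq_along(ys)[last]
  data.frame(recall = tp / n1, precision = tp / npred,
             threshold = ss[last])
}

#' Cross-validation scheme
#'
#' Three cold-start flavors: `cv_l` partitions lncRNAs (all pairs of a
#' held-out lncRNA go to test, simulating prediction for a new lncRNA),
#' `cv_p` partitions proteins, `cv_lp` partitions the sampled pair
#' vectors.
#'
#' @param mode `"cv_l"`, `"cv_p"` or `"cv_lp"`.
#' @param n_folds number of folds (default 5).
#' @param repeats experiment repeats to average over (the conventional
#'   full profile is 20; tests use a scaled-down 3).
#' @param seed master seed.
#' @return list of class `cv_scheme`.
#' @export
cv_scheme <- function(mode = c("cv_lp", "cv_l", "cv_p"), n_folds = 5,
                      repeats = 20, seed = 1) {
  mode <- match.arg(mode)
  if (n_folds < 2 || repeats < 1) stopf("invalid scheme")
  structure(list(mode = mode, n_folds = as.integer(n_folds),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "cv_scheme")
}

# balanced random partition of n units into k folds
.partition <- function(n, k, seed) {
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Fold assignments for a cross-validation scheme
#'
#' Deterministic under the scheme seed.  Folds whose test side would be
#' single-class are resampled with a derived seed (up to 10 retries).
#'
#' @param scheme a [cv_scheme()].
#' @param m an `lpi_matrix`.
#' @param pair_labels for `cv_lp`: the label vector of the sampled pair
#'   set to partition.
#' @param rep_index repeat number, folded into the seed derivation.
#' @return integer fold id per unit (lncRNA, protein, or pair).
#' @export
make_folds <- function(scheme, m, pair_labels = NULL, rep_index = 1) {
  n <- switch(scheme$mode,
              cv_l = length(m$lnc_ids),
              cv_p = length(m$prot_ids),
              cv_lp = length(pair_labels))
  if (scheme$mode == "cv_lp" && is.null(pair_labels)) {
    stopf("cv_lp needs the sampled pair labels")
  }
  if (n < scheme$n_folds) stopf("not enough units for %d folds", scheme$n_folds)
  # entity folds are assigned in sorted-id order, so the partition is a
  # function of the id set (not of input record order) for a given seed
  ord <- switch(scheme$mode,
                cv_l = order(m$lnc_ids),
                cv_p = order(m$prot_ids),
                cv_lp = seq_len(n))
  for (try in 1:10) {
    folds <- integer(n)
    folds[ord] <- .partition(n, scheme$n_folds,
                             derive_seed(scheme$seed, rep_index, try))
    ok <- all(vapply(seq_len(scheme$n_folds), function(f) {
      test_lab <- switch(scheme$mode,
        cv_l = as.vector(m$y[folds == f, , drop = FALSE]),
        cv_p = as.vector(m$y[, folds == f, drop = FALSE]),
        cv_lp = pair_labels[folds == f])
      length(unique(test_lab)) == 2
    }, logical(1)))
    if (ok) return(folds)
  }
  stopf("could not build folds with two-class test sets after 10 tries")
}

# one train/test evaluation given raw feature tables and an index split;
# PCA is fit on training entities only
.eval_split <- function(lnc_feat, prot_feat, m, train_lnc, train_prot,
                        train_cells, test_cells, d, r, tparams, bparams,
                        seed, store_curves = FALSE) {
  pca_l <- fit_pca(lnc_feat[train_lnc, , drop = FALSE], d)
  pca_p <- fit_pca(prot_feat[train_prot, , drop = FALSE], d)
  red_l <- predict(pca_l, lnc_feat)
  red_p <- predict(pca_p, prot_feat)
  train_pairs <- make_pairs(red_l, red_p, m,
                            sampling = neg_sampling(r, derive_seed(seed, 7)),
                            cells = train_cells)
  test_pairs <- make_pairs(red_l, red_p, m, sampling = neg_sampling("all"),
                           cells = test_cells)
  bp <- bparams
  bp$seed <- derive_seed(seed, 11)
  fit <- fit_ensemble(train_pairs, tparams = tparams, bparams = bp)
  scores <- decision_score(fit, test_pairs)
  pred <- as.integer(ifelse(scores > 0, 1L, -1L))
  cm <- classification_metrics(confusion_counts(test_pairs$label, pred))
  res <- data.frame(precision = cm$precision, recall = cm$recall,
                    accuracy = cm$accuracy, f1 = cm$f1,
                    auc = roc_auc(test_pairs$label, scores),
                    aupr = pr_auc(test_pairs$label, scores))
  curves <- if (store_curves) {
    list(roc = roc_points(test_pairs$label, scores),
         pr = pr_points(test_pairs$label, scores))
  } else NULL
  list(metrics = res, curves = curves, model = fit,
       n_test = length(test_pairs$label))
}

.all_cells <- function(rows, cols) {
  as.matrix(expand.grid(row = rows, col = cols))
}

#' Run a full cross-validated experiment
#'
#' For every repeat and fold: sample training negatives, fit PCA on
#' training entities only, fit the boosting ensemble (with its internal
#' stratified validation split), score the test side, and collect the six
#' metrics.  Under `cv_l` / `cv_p` the test side contains *all* pairs
#' involving the held-out entities (a new entity must be ranked against
#' every candidate partner); under `cv_lp` the sampled pair set is
#' partitioned directly.
#'
#' @param lnc_seqs,prot_seqs sequence collections
#'   (named character vectors, as from [read_lpi_fasta()]).
#' @param m an `lpi_matrix`.
#' @param scheme a [cv_scheme()].
#' @param cfg a [feature_config()].
#' @param d PCA dimension per entity kind (pair vectors have 2d).
#' @param r training negative:positive sampling ratio.
#' @param tparams,bparams tree and boosting parameters.
#' @param store_curves keep ROC/PR points of every fold.
#' @return object of class `lpi_report`: `folds` (one metric row per
#'   repeat x fold), `summary` (mean and sd of each metric), `curves`
#'   (optional), `scheme`.
#' @export
run_experiment <- function(lnc_seqs, prot_seqs, m, scheme = cv_scheme(),
                           cfg = feature_config(), d = 100, r = 1,
                           tparams = tree_params(),
                           bparams = boost_params(),
                           store_curves = FALSE) {
  # canonical (sorted-id) entity order: reports depend only on the id ->
  # sequence mapping, not on the order of the input records
  ol <- order(m$lnc_ids); op <- order(m$prot_ids)
  m <- structure(list(lnc_ids = m$lnc_ids[ol], prot_ids = m$prot_ids[op],
                      y = m$y[ol, op, drop = FALSE]), class = "lpi_matrix")
  lnc_feat <- rna_features(lnc_seqs, cfg)
  prot_feat <- protein_features(prot_seqs, cfg)
  lnc_feat <- lnc_feat[m$lnc_ids, , drop = FALSE]
  prot_feat <- prot_feat[m$prot_ids, , drop = FALSE]
  rows <- list(); curves <- list()
  for (rep_i in seq_len(scheme$repeats)) {
    if (scheme$mode == "cv_lp") {
      # sample the pair set once per repeat, then partition it
      samp_seed <- derive_seed(scheme$seed, rep_i, 5)
      cells <- .all_cells(seq_along(m$lnc_ids), seq_along(m$prot_ids))
      lab <- m$y[cells]
      pos <- which(lab == 1L)
      neg_pool <- which(lab == 0L)
      n_neg <- if (identical(r, "all")) length(neg_pool) else
        min(round(as.numeric(r) * length(pos)), length(neg_pool))
      neg <- with_seed(samp_seed, sort(sample(neg_pool, n_neg)))
      sel <- c(pos, neg)
      sel_cells <- cells[sel, , drop = FALSE]
      sel_lab <- ifelse(lab[sel] == 1L, 1L, -1L)
      folds <- make_folds(scheme, m, pair_labels = sel_lab,
                          rep_index = rep_i)
    } else {
      folds <- make_folds(scheme, m, rep_index = rep_i)
    }
    for (f in seq_len(scheme$n_folds)) {
      seed_f <- derive_seed(scheme$seed, rep_i, f)
      if (scheme$mode == "cv_l") {
        test_l <- which(folds == f); train_l <- which(folds != f)
        ev <- .eval_split(lnc_feat, prot_feat, m,
                          train_lnc = train_l,
                          train_prot = seq_along(m$prot_ids),
                          train_cells = .all_cells(train_l,
                                                   seq_along(m$prot_ids)),
                          test_cells = .all_cells(test_l,
                                                  seq_along(m$prot_ids)),
                          d, r, tparams, bparams, seed_f, store_curves)
      } else if (scheme$mode == "cv_p") {
        test_p <- which(folds == f); train_p <- which(folds != f)
        ev <- .eval_split(lnc_feat, prot_feat, m,
                          train_lnc = seq_along(m$lnc_ids),
                          train_prot = train_p,
                          train_cells = .all_cells(seq_along(m$lnc_ids),
                                                   train_p),
                          test_cells = .all_cells(seq_along(m$lnc_ids),
                                                  test_p),
                          d, r, tparams, bparams, seed_f, store_curves)
      } else {
        tr <- folds != f
        ev <- .eval_cvlp(lnc_feat, prot_feat, m,
                         sel_cells[tr, , drop = FALSE], sel_lab[tr],
                         sel_cells[!tr, , drop = FALSE], sel_lab[!tr],
                         d, tparams, bparams, seed_f, store_curves)
      }
      rows[[length(rows) + 1L]] <- cbind(data.frame(repeat_ = rep_i,
                                                    fold = f),
                                         ev$metrics)
      if (store_curves) curves[[sprintf("r%df%d", rep_i, f)]] <- ev$curves
    }
  }
  folds_df <- do.call(rbind, rows)
  met <- c("precision", "recall", "accuracy", "f1", "auc", "aupr")
  summ <- data.frame(metric = met,
                     mean = vapply(met, function(k) mean(folds_df[[k]]),
                                   numeric(1)),
                     sd = vapply(met, function(k) sd(folds_df[[k]]),
                                 numeric(1)))
  rownames(summ) <- NULL
  structure(list(folds = folds_df, summary = summ,
                 curves = if (store_curves) curves else NULL,
                 scheme = scheme),
            class = "lpi_report")
}

# cv_lp split: the sampled pair set is already labeled; PCA on all
# entities (none are held out under a pair split)
.eval_cvlp <- function(lnc_feat, prot_feat, m, train_cells, train_lab,
                       test_cells, test_lab, d, tparams, bparams, seed,
                       store_curves = FALSE) {
  pca_l <- fit_pca(lnc_feat, d)
  pca_p <- fit_pca(prot_feat, d)
  red_l <- predict(pca_l, lnc_feat)
  red_p <- predict(pca_p, prot_feat)
  pv <- function(cells) {
    x <- cbind(red_l[cells[, 1], , drop = FALSE],
               red_p[cells[, 2], , drop = FALSE])
    rownames(x) <- NULL
    x
  }
  bp <- bparams
  bp$seed <- derive_seed(seed, 11)
  fit <- fit_ensemble(pv(train_cells), train_lab, tparams = tparams,
                      bparams = bp)
  xt <- pv(test_cells)
  scores <- decision_score(fit, xt)
  pred <- as.integer(ifelse(scores > 0, 1L, -1L))
  cm <- classification_metrics(confusion_counts(test_lab, pred))
  res <- data.frame(precision = cm$precision, recall = cm$recall,
                    accuracy = cm$accuracy, f1 = cm$f1,
                    auc = roc_auc(test_lab, scores),
                    aupr = pr_auc(test_lab, scores))
  curves <- if (store_curves) {
    list(roc = roc_points(test_lab, scores),
         pr = pr_points(test_lab, scores))
  } else NULL
  list(metrics = res, curves = curves, model = fit, n_test = length(test_lab))
}

#' @export
print.lpi_report <- function(x, ...) {
  cat(sprintf("<lpi_report> %s, %d repeat(s) x %d fold(s)\n",
              x$scheme$mode, x$scheme$repeats, x$scheme$n_folds))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
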