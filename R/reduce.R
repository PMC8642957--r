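#' Fit a PCA model on a feature table
#'
#' Centered (and by default standardized) principal component analysis.
#' Columns with zero variance are dropped before the fit; when the
#' requested dimension `d` exceeds the numerical rank of the data the
#' surplus components are zero-padded and the model is flagged
#' (`padded = TRUE`), so downstream pair vectors always have exactly `d`
#' coordinates per entity.
#'
#' For wide tables (many more features than entities) the decomposition is
#' computed from the eigendecomposition of the `n x n` Gram matrix, which
#' is algebraically identical to the SVD route used by [stats::prcomp()]
#' (a unit test checks the agreement).
#'
#' @param table numeric matrix, entities x features (as from
#'   [rna_features()] / [protein_features()]).
#' @param d target dimension (the conventional pipeline default is 100).
#' @param standardize scale columns to unit variance before the fit.
#' @return an object of class `lpi_pca` with elements `mean`, `scale`,
#'   `keep` (retained column names), `rotation` (features x d, orthonormal
#'   up to the data rank), `explained_variance` (non-increasing), `d`,
#'   `rank`, `padded`.
#' @export
fit_pca <- function(table, d, standardize = TRUE) {
  if (!is.matrix(table) || nrow(table) < 2) stopf("need >= 2 rows to fit PCA")
  if (d < 1) stopf("d must be >= 1")
  d <- as.integer(d)
  cn <- colnames(table)
  if (is.null(cn)) stopf("feature table must have column names")
  v <- apply(table, 2, stats::var)
  keep <- v > 0
  if (!any(keep)) stopf("constant feature table: zero variance everywhere")
  x <- table[, keep, drop = FALSE]
  mu <- colMeans(x)
  sc <- if (standardize) sqrt(v[keep]) else rep(1, ncol(x))
  xc <- sweep(sweep(x, 2, mu, "-"), 2, sc, "/")
  n <- nrow(xc); p <- ncol(xc)
  if (p > n) {
    # Gram-matrix route: eigen of xc xc^T, components = xc^T u / sigma
    g <- tcrossprod(xc)
    e <- eigen(g, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    tol <- max(ev) * 1e-12
    r <- sum(ev > tol)
    sv <- sqrt(ev[seq_len(r)])
    u <- e$vectors[, seq_len(r), drop = FALSE]
    rot <- crossprod(xc, u) / rep(sv, each = p)
  } else {
    s <- svd(xc)
    tol <- max(s$d) * 1e-10
    r <- sum(s$d > tol)
    sv <- s$d[seq_len(r)]
    rot <- s$v[, seq_len(r), drop = FALSE]
  }
  r_use <- min(r, d)
  rotation <- matrix(0, p, d,
                     dimnames = list(colnames(x), paste0("PC", seq_len(d))))
  rotation[, seq_len(r_use)] <- rot[, seq_len(r_use)]
  expl <- numeric(d)
  expl[seq_len(r_use)] <- (sv[seq_len(r_use)]^2) / (n - 1)
  structure(list(mean = mu, scale = sc, keep = colnames(x),
                 feature_names = cn, rotation = rotation,
                 explained_variance = expl, d = d, rank = r,
                 padded = d > r, standardize = standardize),
            class = "lpi_pca")
}

#' Project a feature table onto a fitted PCA model
#'
#' @param object an `lpi_pca` model.
#' @param table feature matrix whose columns match the fitted table (same
#'   names; order may differ, rows are re-aligned by name).
#' @param ... unused.
#' @return entities x d score matrix.  The training mean maps to the zero
#'   vector.
#' @export
predict.lpi_pca <- function(object, table, ...) {
  if (is.null(colnames(table)) || !all(object$keep %in% colnames(table))) {
    stopf("feature names of the table do not match the fitted PCA model")
  }
  x <- table[, object$keep, drop = FALSE]
  xc <- sweep(sweep(x, 2, object$mean, "-"), 2, object$scale, "/")
  sc <- xc %*% object$rotation
  rownames(sc) <- rownames(table)
  sc
}

#' Reconstruct feature-space coordinates from PCA scores
#'
#' Inverse of [predict.lpi_pca()] on the component subspace (exact when the
#' scores span the full data rank).
#'
#' @param model an `lpi_pca`.
#' @param scores entities x d score matrix.
#' @return matrix in the retained-feature space.
#' @export
inverse_pca <- function(model, scores) {
  x <- scores %*% t(model$rotation)
  sweep(sweep(x, 2, model$scale, "*"), 2, model$mean, "+")
}

#' Negative-sampling specification
#'
#' @param r ratio of sampled negatives to known positives, or `"all"` to
#'   keep every unlabeled pair as a negative.
#' @param seed integer seed for the (uniform, without-replacement) draw.
#' @return a list of class `neg_sampling`.
#' @export
neg_sampling <- function(r = 1, seed = 1) {
  if (!identical(r, "all")) {
    r <- as.numeric(r)
    if (!is.finite(r) || r <= 0) stopf("r must be positive or \"all\"")
  }
  structure(list(r = r, seed = as.integer(seed)), class = "neg_sampling")
}

#' Build labeled pair vectors from reduced entity features
#'
#' Every known interaction becomes a positive (+1) pair whose vector is the
#' concatenation of the lncRNA's and the protein's d-dimensional PCA scores
#' (2d coordinates).  Negatives (-1) are drawn uniformly without
#' replacement from the unlabeled cells at `r` times the number of
#' positives; `r = "all"` keeps every unlabeled cell.
#'
#' @param lnc_reduced,prot_reduced score matrices with entity ids as row
#'   names (as from [predict.lpi_pca()]).
#' @param m an `lpi_matrix`; every id must be present in the score tables.
#' @param sampling a [neg_sampling()].
#' @param cells optional integer matrix of (row, col) indices restricting
#'   the candidate cells (used by the cross-validation harness).
#' @return a list of class `lpi_pairs` with `lnc_id`, `prot_id`, `x`
#'   (pairs x 2d matrix) and `label` in {+1, -1}.
#' @export
make_pairs <- function(lnc_reduced, prot_reduced, m,
                       sampling = neg_sampling(), cells = NULL) {
  stopifnot(inherits(m, "lpi_matrix"))
  if (!all(m$lnc_ids %in% rownames(lnc_reduced)) ||
      !all(m$prot_ids %in% rownames(prot_reduced))) {
    stopf("interaction matrix ids missing from reduced tables")
  }
  if (is.null(cells)) {
    cells <- as.matrix(expand.grid(row = seq_along(m$lnc_ids),
                                   col = seq_along(m$prot_ids)))
  }
  lab <- m$y[cells]
  pos <- cells[lab == 1L, , drop = FALSE]
  neg <- cells[lab == 0L, , drop = FALSE]
  n_pos <- nrow(pos)
  if (identical(sampling$r, "all")) {
    take <- seq_len(nrow(neg))
  } else {
    want <- round(sampling$r * n_pos)
    if (want > nrow(neg)) {
      warnf("requested %d negatives but only %d unlabeled cells; using all",
            want, nrow(neg))
      want <- nrow(neg)
    }
    old <- .Random.seed_save()
    set.seed(sampling$seed)
    take <- sort(sample.int(nrow(neg), want))
    .Random.seed_restore(old)
  }
  neg <- neg[take, , drop = FALSE]
  all_cells <- rbind(pos, neg)
  labels <- c(rep(1L, nrow(pos)), rep(-1L, nrow(neg)))
  x <- cbind(lnc_reduced[match(m$lnc_ids[all_cells[, 1]],
                               rownames(lnc_reduced)), , drop = FALSE],
             prot_reduced[match(m$prot_ids[all_cells[, 2]],
                                rownames(prot_reduced)), , drop = FALSE])
  colnames(x) <- c(paste0("lnc.", colnames(lnc_reduced)),
                   paste0("prot.", colnames(prot_reduced)))
  rownames(x) <- NULL
  structure(list(lnc_id = m$lnc_ids[all_cells[, 1]],
                 prot_id = m$prot_ids[all_cells[, 2]],
                 x = x, label = labels),
            class = "lpi_pairs")
}

#' @export
print.lpi_pairs <- function(x, ...) {
  cat(sprintf("<lpi_pairs> %d pairs (%d positive, %d negative), %d features\n",
              length(x$label), sum(x$label == 1), sum(x$label == -1),
              ncol(x$x)))
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}
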