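# Shared fixtures: everything is generated in code at test time.

write_fasta_fixture <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

write_pairs_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

# small descriptor configuration that keeps unit tests fast
small_cfg <- function() {
  feature_config(k_gap = 2, k_tuple = 2,
                 rna = c("zCurve", "gcContent", "atgcRatio",
                         "cumulativeSkew", "kTuple", "monoMonoKGap"),
                 protein = c("AAC", "CTD", "conjointTriad"),
                 lag = 4, lambda = 4)
}

# a light planted-signal dataset + parameters for quick end-to-end fits
small_spec <- function(seed = 1) {
  synthetic_spec(n_lnc = 40, n_prot = 12, lnc_len = c(60, 80),
                 prot_len = c(40, 60), seed = seed)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# unweighted information gain of the best axis-aligned stump, by full
# enumeration — the independent oracle for the tree split search
oracle_best_stump_gain <- function(x, y) {
  H <- function(lab) {
    if (!length(lab)) return(0)
    p <- mean(lab == 1)
    if (p <= 0 || p >= 1) 0 else -(p * log2(p) + (1 - p) * log2(1 - p))
  }
  best <- 0
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    cuts <- (v[-1] + v[-length(v)]) / 2
    for (ct in cuts) {
      l <- x[, j] < ct
      g <- H(y) - (mean(l) * H(y[l]) + mean(!l) * H(y[!l]))
      best <- max(best, g)
    }
  }
  best
}

# pair-ordering AUC oracle: fraction of correctly ordered (pos, neg)
# score pairs with half credit for ties
oracle_auc <- function(labels, scores) {
  pos <- scores[as.numeric(labels) > 0]
  neg <- scores[as.numeric(labels) <= 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Full-default pipeline on planted synthetic data: one 80/20 pair holdout,
# returning the held-out AUC.  `permute` breaks the sequence-label link by
# shuffling labels (null model).  Mirrors the study conditions: default
# generator spec, descriptor set, d = 100, balanced negative sampling,
# default tree and boosting parameters.
planted_holdout_auc <- function(seed, permute = FALSE) {
  d <- simulate_lpi(synthetic_spec(seed = seed))
  lf <- rna_features(d$rna)
  pf <- protein_features(d$protein)
  rl <- predict(fit_pca(lf, 100), lf)
  rp <- predict(fit_pca(pf, 100), pf)
  pairs <- make_pairs(rl, rp, d$matrix,
                      neg_sampling(1, seed = derive_seed(seed, 2)))
  y <- pairs$label
  if (permute) y <- lpiboost:::with_seed(derive_seed(seed, 4), sample(y))
  n <- length(y)
  te <- lpiboost:::with_seed(derive_seed(seed, 3),
                             sort(sample(n, round(0.2 * n))))
  fit <- fit_ensemble(pairs$x[-te, ], y[-te], tree_params(),
                      boost_params(seed = derive_seed(seed, 5)))
  roc_auc(y[te], decision_score(fit, pairs$x[te, ]))
}

# brute-force gapped-pattern counter (x-mer, gap, y-mer), for RNA oracle
oracle_gap_counts <- function(seq, a, g, b) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  win <- a + g + b
  bases <- c("A", "C", "G", "T")
  xs <- apply(expand.grid(rep(list(bases), a))[, a:1, drop = FALSE], 1,
              paste, collapse = "")
  ys <- apply(expand.grid(rep(list(bases), b))[, b:1, drop = FALSE], 1,
              paste, collapse = "")
  counts <- matrix(0, length(xs), length(ys), dimnames = list(xs, ys))
  n_win <- max(L - win + 1, 0)
  if (n_win > 0) {
    for (i in seq_len(n_win)) {
      xm <- paste(ch[i:(i + a - 1)], collapse = "")
      ym <- paste(ch[(i + a + g):(i + win - 1)], collapse = "")
      counts[xm, ym] <- counts[xm, ym] + 1
    }
  }
  list(counts = counts, n_windows = n_win)
}
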