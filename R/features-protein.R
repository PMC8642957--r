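# Protein sequence descriptors.
#
# Conventions (fixed by this package):
#   * AAC / dipeptide / conjoint triad: normalized counts over unambiguous
#     residues / windows (ambiguity codes B, Z, X, U, O are masked);
#   * CTD: for each of the 7 standard 3-class physicochemical partitions
#     (constants.R), composition = class frequencies; transition = fraction
#     of adjacent residue pairs crossing each unordered class pair;
#     distribution = relative position (fraction of counted residues, in
#     (0, 1]) of the first / 25% / 50% / 75% / last residue of each class;
#   * conjoint triad: 343 normalized triple counts over the 7 groups
#     {AGV, ILFP, YMTS, HNQW, RK, DE, C};
#   * QSO: tau_l = sum over i of d2(R_i, R_{i+l}) where d2 is the mean
#     squared difference of the three standardized property scales
#     (hydrophobicity, hydrophilicity, side-chain mass); features are
#     f_u / (sum f + w * sum tau) for the 20 residues and
#     w * tau_l / (same) for l = 1..L;
#   * PAAC: theta_l = average of d2 over pairs at lag l; features are
#     f_u / (sum f + w * sum theta) and w * theta_l / (same), l = 1..lambda,
#     with f the residue frequencies;
#   * Moreau-Broto: AC(scale, l) = mean over pairs of z_i * z_{i+l} for each
#     standardized scale, l = 1..L.
# Lags infeasible for a short sequence are zero-filled with a warning.

.aa_codes <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  match(ch, AA_ORDER) - 1L
}

.protein_row <- function(seq, cfg) {
  num <- .aa_codes(toupper(seq))
  L <- length(num)
  ok <- !is.na(num)
  nv <- sum(ok)
  counts <- tabulate(num[ok] + 1L, 20L)
  freq <- if (nv > 0) counts / nv else numeric(20)
  warns <- character(0)
  # standardized property values per position (3 x L), NA where masked
  z <- AA_SCALES_Z[, num + 1L, drop = FALSE]

  # mean squared scale difference for all residue pairs at lag l
  pair_d2 <- function(l) {
    if (L - l < 1L) return(numeric(0))
    i <- seq_len(L - l)
    d <- z[, i, drop = FALSE] - z[, i + l, drop = FALSE]
    colMeans(d * d) # NA where either residue is masked
  }

  out <- numeric(0)
  for (d in cfg$protein) {
    v <- switch(d,
      AAC = freq,
      dipeptide = {
        r <- .norm_counts(.kmer_codes(num, 2L, base = 20L), 400L)
        if (r$empty) warns <- c(warns, "no valid dipeptide window")
        r$v
      },
      CTD = unlist(lapply(CTD_LOOKUP, function(lk) {
        grp <- lk[num + 1L]
        gok <- !is.na(grp)
        ngv <- sum(gok)
        comp <- if (ngv > 0) tabulate(grp[gok], 3L) / ngv else numeric(3)
        # transitions over adjacent unmasked pairs
        tr <- numeric(3)
        if (L >= 2) {
          a <- grp[-L]; b <- grp[-1]
          keep <- !is.na(a) & !is.na(b)
          a <- a[keep]; b <- b[keep]
          if (length(a)) {
            lo <- pmin(a, b); hi <- pmax(a, b)
            tr <- c(sum(lo == 1 & hi == 2), sum(lo == 1 & hi == 3),
                    sum(lo == 2 & hi == 3)) / length(a)
          }
        }
        dist <- unlist(lapply(1:3, function(g) {
          pos <- which(grp[gok] == g) # index among counted residues
          if (!length(pos)) return(numeric(5))
          qs <- pos[pmax(1L, ceiling(c(1e-9, 0.25, 0.5, 0.75, 1) * length(pos)))]
          qs / ngv
        }))
        c(comp, tr, dist)
      })),
      conjointTriad = {
        grp <- CONJOINT_LOOKUP[num + 1L] - 1L
        r <- .norm_counts(.kmer_codes(grp, 3L, base = 7L), 343L)
        if (r$empty) warns <- c(warns, "no valid triad window")
        r$v
      },
      QSO = {
        tau <- vapply(seq_len(cfg$lag), function(l) {
          d2 <- pair_d2(l)
          d2 <- d2[!is.na(d2)]
          if (!length(d2)) {
            warns <<- c(warns, sprintf("qso lag %d infeasible", l))
            return(0)
          }
          sum(d2)
        }, numeric(1))
        denom <- sum(counts) + cfg$weight * sum(tau)
        if (denom == 0) denom <- 1
        c(counts / denom, cfg$weight * tau / denom)
      },
      PAAC = {
        theta <- vapply(seq_len(cfg$lambda), function(l) {
          d2 <- pair_d2(l)
          d2 <- d2[!is.na(d2)]
          if (!length(d2)) {
            warns <<- c(warns, sprintf("paac tier %d infeasible", l))
            return(0)
          }
          mean(d2)
        }, numeric(1))
        denom <- sum(freq) + cfg$weight * sum(theta)
        if (denom == 0) denom <- 1
        c(freq / denom, cfg$weight * theta / denom)
      },
      autocorrelation = unlist(lapply(1:3, function(s) {
        vapply(seq_len(cfg$lag), function(l) {
          if (L - l < 1L) {
            warns <<- c(warns, sprintf("autocorrelation lag %d infeasible", l))
            return(0)
          }
          i <- seq_len(L - l)
          prod <- z[s, i] * z[s, i + l]
          prod <- prod[!is.na(prod)]
          if (!length(prod)) {
            warns <<- c(warns, sprintf("autocorrelation lag %d fully masked", l))
            return(0)
          }
          mean(prod)
        }, numeric(1))
      })))
    out <- c(out, v)
  }
  list(values = out, warnings = warns)
}

#' Protein descriptor table
#'
#' Computes the enabled amino-acid descriptors for each sequence and
#' returns an entities-by-features matrix.  See [feature_config()] for the
#' families and `feature_names(cfg, "protein")` for the column order.
#'
#' @inheritParams rna_features
#' @param seqs named character vector of protein sequences.
#' @return numeric matrix (ids x named features).
#' @export
protein_features <- function(seqs, cfg = feature_config()) {
  .feature_table(seqs, cfg, .protein_row, protein_feature_names(cfg))
}
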