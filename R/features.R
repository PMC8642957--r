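# Descriptor configuration and feature naming.
#
# The descriptor families mirror the classical RNA / protein sequence
# descriptor sets popularized by feature-extraction toolkits: gapped and
# ungapped k-mer composition plus zCurve / GC statistics for nucleotide
# sequences, and AAC / dipeptide / CTD / conjoint triad / QSO / PAAC /
# Moreau-Broto autocorrelation for proteins.  All formulas are fixed here
# (see the descriptor functions); no attempt is made to be byte-compatible
# with any external tool's output ordering or naming.

RNA_DESCRIPTORS <- c("zCurve", "gcContent", "atgcRatio", "cumulativeSkew",
                     "kTuple",
                     "monoMonoKGap", "monoDiKGap", "diMonoKGap", "diDiKGap",
                     "monoTriKGap", "triMonoKGap", "diTriKGap", "triDiKGap")
PROTEIN_DESCRIPTORS <- c("AAC", "dipeptide", "CTD", "conjointTriad",
                         "QSO", "PAAC", "autocorrelation")

# x-mer / y-mer sizes of each gapped family
GAP_FAMILIES <- list(
  monoMonoKGap = c(1L, 1L), monoDiKGap = c(1L, 2L), diMonoKGap = c(2L, 1L),
  diDiKGap = c(2L, 2L), monoTriKGap = c(1L, 3L), triMonoKGap = c(3L, 1L),
  diTriKGap = c(2L, 3L), triDiKGap = c(3L, 2L))

#' Descriptor configuration
#'
#' @param k_gap maximum gap length for the gapped k-mer families (each
#'   family contributes one block per gap `g = 1..k_gap`).
#' @param k_tuple maximum k for plain k-mer composition (1-3).
#' @param rna,protein character vectors of enabled descriptor families.
#' @param lag maximum lag `L` for quasi-sequence-order coupling terms and
#'   Moreau-Broto autocorrelation.
#' @param lambda number of pseudo amino-acid composition correlation tiers.
#' @param weight weight `w` of the sequence-order terms in QSO and PAAC.
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(k_gap = 5, k_tuple = 3,
                           rna = RNA_DESCRIPTORS,
                           protein = PROTEIN_DESCRIPTORS,
                           lag = 10, lambda = 10, weight = 0.1) {
  k_gap <- as.integer(k_gap); k_tuple <- as.integer(k_tuple)
  if (k_gap < 1) stopf("k_gap must be >= 1")
  if (!k_tuple %in% 1:3) stopf("k_tuple must be 1, 2 or 3")
  bad_r <- setdiff(rna, RNA_DESCRIPTORS)
  bad_p <- setdiff(protein, PROTEIN_DESCRIPTORS)
  if (length(bad_r)) stopf("unknown rna descriptor(s): %s",
                           paste(bad_r, collapse = ", "))
  if (length(bad_p)) stopf("unknown protein descriptor(s): %s",
                           paste(bad_p, collapse = ", "))
  if (!length(rna) || !length(protein)) {
    stopf("at least one descriptor must be enabled per kind")
  }
  if (lag < 1 || lambda < 1 || weight < 0) stopf("invalid lag/lambda/weight")
  structure(list(k_gap = k_gap, k_tuple = k_tuple,
                 rna = RNA_DESCRIPTORS[RNA_DESCRIPTORS %in% rna],
                 protein = PROTEIN_DESCRIPTORS[PROTEIN_DESCRIPTORS %in% protein],
                 lag = as.integer(lag), lambda = as.integer(lambda),
                 weight = weight),
            class = "feature_config")
}

# all k-mer strings over the DNA alphabet in code order (A<C<G<T,
# first letter most significant) — identical to lexicographic order
mer_strings <- function(k, alphabet = DNA_BASES) {
  n <- length(alphabet)
  out <- rep("", n^k)
  for (code in seq_len(n^k) - 1L) {
    c0 <- code
    s <- character(k)
    for (j in k:1) {
      s[j] <- alphabet[c0 %% n + 1L]
      c0 <- c0 %/% n
    }
    out[code + 1L] <- paste(s, collapse = "")
  }
  out
}

#' Deterministic feature names for a configuration
#'
#' @param cfg a [feature_config()].
#' @param kind `"rna"` or `"protein"`.
#' @return character vector matching the column order of the corresponding
#'   feature table.
#' @export
feature_names <- function(cfg, kind = c("rna", "protein")) {
  kind <- match.arg(kind)
  if (kind == "rna") rna_feature_names(cfg) else protein_feature_names(cfg)
}

rna_feature_names <- function(cfg) {
  nm <- character(0)
  for (d in cfg$rna) {
    nm <- c(nm, switch(d,
      zCurve = paste0("rna.zCurve.", c("x", "y", "z")),
      gcContent = "rna.gcContent",
      atgcRatio = "rna.atgcRatio",
      cumulativeSkew = paste0("rna.skew.", c("gc", "at")),
      kTuple = unlist(lapply(seq_len(cfg$k_tuple), function(k)
        paste0("rna.kmer.k", k, ".", mer_strings(k)))),
      { # gapped family
        ab <- GAP_FAMILIES[[d]]
        xs <- mer_strings(ab[1]); ys <- mer_strings(ab[2])
        unlist(lapply(seq_len(cfg$k_gap), function(g)
          paste0("rna.", d, ".g", g, ".",
                 rep(xs, each = length(ys)), "_", ys)))
      }))
  }
  nm
}

protein_feature_names <- function(cfg) {
  nm <- character(0)
  tri <- expand.grid(g3 = 1:7, g2 = 1:7, g1 = 1:7)[, 3:1]
  for (d in cfg$protein) {
    nm <- c(nm, switch(d,
      AAC = paste0("prot.aac.", AA_ORDER),
      dipeptide = paste0("prot.dipep.", mer_strings(2, AA_ORDER)),
      CTD = unlist(lapply(names(CTD_GROUPS), function(p) {
        gn <- names(CTD_GROUPS[[p]])
        c(paste0("prot.ctd.", p, ".comp.", gn),
          paste0("prot.ctd.", p, ".trans.",
                 c(paste0(gn[1], "_", gn[2]), paste0(gn[1], "_", gn[3]),
                   paste0(gn[2], "_", gn[3]))),
          unlist(lapply(gn, function(g)
            paste0("prot.ctd.", p, ".dist.", g, ".p",
                   c(0, 25, 50, 75, 100)))))
      })),
      conjointTriad = paste0("prot.triad.", tri$g1, "_", tri$g2, "_", tri$g3),
      QSO = c(paste0("prot.qso.", AA_ORDER),
              paste0("prot.qso.tau", seq_len(cfg$lag))),
      PAAC = c(paste0("prot.paac.", AA_ORDER),
               paste0("prot.paac.lambda", seq_len(cfg$lambda))),
      autocorrelation = unlist(lapply(rownames(AA_SCALES), function(s)
        paste0("prot.mb.", s, ".lag", seq_len(cfg$lag))))))
  }
  nm
}

# Shared driver: apply a per-sequence row function, collect warnings once.
.feature_table <- function(seqs, cfg, row_fun, names) {
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) stopf("sequences must have unique ids")
  warn_pool <- character(0)
  rows <- lapply(seq_along(seqs), function(i) {
    r <- row_fun(seqs[[i]], cfg)
    if (length(r$warnings)) {
      warn_pool <<- c(warn_pool, paste0(ids[i], ": ", r$warnings))
    }
    r$values
  })
  if (length(warn_pool)) {
    warnf("degenerate descriptor blocks zero-filled:\n  %s",
          paste(unique(warn_pool), collapse = "\n  "))
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(ids, names)
  if (any(!is.finite(m))) stopf("internal error: non-finite feature value")
  m
}
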