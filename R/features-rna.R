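# Nucleotide sequence descriptors.
#
# Conventions (fixed by this package):
#   * composition counts ignore positions with ambiguity codes ("mask"
#     policy); every normalized composition block divides by the number of
#     fully unambiguous windows, so it sums to 1 for clean sequences;
#   * zCurve = ((fA+fG)-(fC+fT), (fA+fC)-(fG+fT), (fA+fT)-(fG+fC)) over
#     base frequencies;
#   * gcContent = (G+C)/len over counted bases;
#   * atgcRatio = (A+T)/(G+C), defined as (A+T)/1 (with a warning) when
#     G+C = 0 to avoid infinities;
#   * cumulativeSkew = ((G-C)/(G+C), (A-T)/(A+T)), 0 when a denominator is 0;
#   * each gapped family counts (x-mer, gap g, y-mer) patterns for
#     g = 1..k_gap, normalized per gap by its number of windows.

# integer codes 0..3 for A,C,G,T; NA for ambiguity codes
.dna_codes <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  match(ch, DNA_BASES) - 1L
}

# codes of all k-mers (first letter most significant); NA if any base is NA
.kmer_codes <- function(num, k, base = 4L) {
  L <- length(num)
  if (L < k) return(integer(0))
  code <- num[seq_len(L - k + 1L)]
  if (k >= 2) {
    for (j in 2:k) code <- code * base + num[j:(L - k + j)]
  }
  code
}

.norm_counts <- function(codes, nbins) {
  ok <- !is.na(codes)
  n <- sum(ok)
  if (n == 0) return(list(v = numeric(nbins), empty = TRUE))
  list(v = tabulate(codes[ok] + 1L, nbins) / n, empty = FALSE)
}

.rna_row <- function(seq, cfg) {
  num <- .dna_codes(chartr("U", "T", toupper(seq)))
  L <- length(num)
  counts <- tabulate(num[!is.na(num)] + 1L, 4L)
  nv <- sum(counts)
  f <- if (nv > 0) counts / nv else numeric(4)
  A <- counts[1]; C <- counts[2]; G <- counts[3]; T <- counts[4]
  warns <- character(0)
  kc <- lapply(1:3, function(k) .kmer_codes(num, k))
  out <- numeric(0)
  for (d in cfg$rna) {
    v <- switch(d,
      zCurve = c((f[1] + f[3]) - (f[2] + f[4]),
                 (f[1] + f[2]) - (f[3] + f[4]),
                 (f[1] + f[4]) - (f[3] + f[2])),
      gcContent = if (nv > 0) (G + C) / nv else 0,
      atgcRatio = {
        if (G + C == 0) {
          warns <- c(warns, "atgcRatio with G+C = 0; using (A+T)/1")
          A + T
        } else (A + T) / (G + C)
      },
      cumulativeSkew = c(if (G + C > 0) (G - C) / (G + C) else 0,
                         if (A + T > 0) (A - T) / (A + T) else 0),
      kTuple = unlist(lapply(seq_len(cfg$k_tuple), function(k) {
        r <- .norm_counts(kc[[k]], 4L^k)
        if (r$empty) warns <<- c(warns, sprintf("no valid %d-mer window", k))
        r$v
      })),
      { # gapped family d
        ab <- GAP_FAMILIES[[d]]
        a <- ab[1]; b <- ab[2]
        nbins <- 4L^(a + b)
        xc <- kc[[a]]; yc <- kc[[b]]
        unlist(lapply(seq_len(cfg$k_gap), function(g) {
          win <- a + g + b
          nw <- L - win + 1L
          if (nw < 1L) {
            warns <<- c(warns, sprintf("%s g=%d window longer than sequence", d, g))
            return(numeric(nbins))
          }
          i <- seq_len(nw)
          comb <- xc[i] * 4L^b + yc[i + a + g]
          r <- .norm_counts(comb, nbins)
          if (r$empty) {
            warns <<- c(warns, sprintf("%s g=%d has no unambiguous window", d, g))
          }
          r$v
        }))
      })
    out <- c(out, v)
  }
  list(values = out, warnings = warns)
}

#' RNA descriptor table
#'
#' Computes the enabled nucleotide descriptors for each sequence and
#' returns an entities-by-features matrix.  See [feature_config()] for the
#' families and `feature_names(cfg, "rna")` for the column order.
#'
#' @param seqs named character vector of RNA sequences (as from
#'   [read_lpi_fasta()]; `U` and `T` are both accepted).
#' @param cfg a [feature_config()].
#' @return numeric matrix with sequence ids as row names and deterministic
#'   descriptor names as column names.
#' @export
rna_features <- function(seqs, cfg = feature_config()) {
  .feature_table(seqs, cfg, .rna_row, rna_feature_names(cfg))
}
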