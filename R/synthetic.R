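# Seeded synthetic LPI data with a planted, recoverable motif signal.
#
# A fraction of lncRNAs carries an RNA motif and a fraction of proteins a
# protein motif, inserted at a uniform random position in otherwise
# uniform-random sequences.  A (lncRNA, protein) cell interacts with
# probability p_interact_match when BOTH entities carry their motif and
# p_background otherwise.  The signal is therefore motif-based: the
# descriptor pipeline has to carry it through PCA into the trees for the
# classifier to recover it.

#' Synthetic dataset specification
#'
#' Defaults produce a 120 x 30 interaction matrix with roughly a quarter
#' positive cells — within the imbalance range of published LPI datasets —
#' small enough for full cross-validated runs in minutes on one CPU.
#'
#' @param n_lnc,n_prot entity counts.
#' @param lnc_len,prot_len length ranges (min, max) for the random
#'   sequences.
#' @param motif_r RNA motif (DNA alphabet); the GC-dinucleotide repeat
#'   default leaves a strong trace in k-mer and GC-content descriptors.
#' @param motif_p protein motif; the His-Lys repeat default marks the
#'   conjoint-triad and CTD blocks.
#' @param p_interact_match interaction probability when both entities
#'   carry their motif.
#' @param p_background interaction probability otherwise.
#' @param motif_prevalence fraction of entities (per kind) carrying the
#'   motif.
#' @param seed integer seed; everything downstream is deterministic in it.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_lnc = 120, n_prot = 30,
                           lnc_len = c(80, 120), prot_len = c(60, 100),
                           motif_r = "GCGCGCGCGCGC", motif_p = "HKHKHKHKHK",
                           p_interact_match = 0.9, p_background = 0.05,
                           motif_prevalence = 0.5, seed = 1) {
  if (!(p_background >= 0 && p_background < p_interact_match &&
        p_interact_match <= 1)) {
    stopf("need 0 <= p_background < p_interact_match <= 1")
  }
  if (motif_prevalence <= 0 || motif_prevalence > 1) {
    stopf("motif_prevalence in (0, 1]")
  }
  if (lnc_len[1] < nchar(motif_r) || prot_len[1] < nchar(motif_p)) {
    stopf("sequence length ranges must accommodate the motifs")
  }
  structure(list(n_lnc = as.integer(n_lnc), n_prot = as.integer(n_prot),
                 lnc_len = as.integer(lnc_len),
                 prot_len = as.integer(prot_len),
                 motif_r = motif_r, motif_p = motif_p,
                 p_interact_match = p_interact_match,
                 p_background = p_background,
                 motif_prevalence = motif_prevalence,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Expected positive fraction of a synthetic spec
#'
#' `q^2 * p_match + (1 - q^2) * p_background` with `q` the motif
#' prevalence.
#'
#' @param spec a [synthetic_spec()].
#' @return expected fraction of interacting cells.
#' @export
expected_pos_fraction <- function(spec) {
  q2 <- spec$motif_prevalence^2
  q2 * spec$p_interact_match + (1 - q2) * spec$p_background
}

.random_seqs <- function(n, len_range, alphabet, prefix) {
  lens <- if (len_range[1] == len_range[2]) rep(len_range[1], n) else
    sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- sprintf("%s%03d", prefix, seq_len(n))
  seqs
}

.plant_motif <- function(seqs, motif, carriers) {
  ml <- nchar(motif)
  for (i in which(carriers)) {
    L <- nchar(seqs[i])
    pos <- sample.int(L - ml + 1L, 1L)
    substr(seqs[i], pos, pos + ml - 1L) <- motif
  }
  seqs
}

#' Generate a synthetic LPI dataset
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `lpi_synthetic`: `rna` and `protein` sequence
#'   collections, `matrix` (an `lpi_matrix`), and `truth` (carrier flags
#'   and the cell probability matrix).
#' @export
simulate_lpi <- function(spec = synthetic_spec()) {
  if (expected_pos_fraction(spec) * spec$n_lnc * spec$n_prot < 1) {
    stopf("spec implies an expected positive count below 1")
  }
  with_seed(spec$seed, {
    rna <- .random_seqs(spec$n_lnc, spec$lnc_len, DNA_BASES, "L")
    prot <- .random_seqs(spec$n_prot, spec$prot_len, AA_ORDER, "P")
    n_carry_l <- round(spec$motif_prevalence * spec$n_lnc)
    n_carry_p <- round(spec$motif_prevalence * spec$n_prot)
    carrier_l <- seq_len(spec$n_lnc) %in% sample.int(spec$n_lnc, n_carry_l)
    carrier_p <- seq_len(spec$n_prot) %in% sample.int(spec$n_prot, n_carry_p)
    rna <- .plant_motif(rna, spec$motif_r, carrier_l)
    prot <- .plant_motif(prot, spec$motif_p, carrier_p)
    prob <- outer(carrier_l, carrier_p,
                  function(a, b) ifelse(a & b, spec$p_interact_match,
                                        spec$p_background))
    y <- matrix(as.integer(runif(length(prob)) < prob), nrow(prob))
    dimnames(y) <- list(names(rna), names(prot))
    m <- interaction_matrix(names(rna), names(prot))
    m$y <- y
    structure(list(rna = new_lpi_seqs(rna, "rna"),
                   protein = new_lpi_seqs(prot, "protein"),
                   matrix = m,
                   truth = list(lnc_carrier = setNames(carrier_l, names(rna)),
                                prot_carrier = setNames(carrier_p,
                                                        names(prot)),
                                prob = prob),
                   spec = spec),
              class = "lpi_synthetic")
  })
}

#' Spec tuned to an expected positive ratio
#'
#' Returns a copy of `base` with `p_background = ratio / 2` and
#' `p_interact_match` solved from
#' `ratio = q^2 p_match + (1 - q^2) p_background` (with `q` the motif
#' prevalence), so the expected positive fraction equals `ratio`.  Errors
#' when the solution leaves `(p_background, 1]`.
#'
#' @param ratio target expected positive fraction in (0, 1).
#' @param base a [synthetic_spec()] supplying everything else.
#' @return a `synthetic_spec`.
#' @export
target_ratio_spec <- function(ratio, base = synthetic_spec()) {
  if (ratio <= 0 || ratio >= 1) stopf("ratio must be in (0, 1)")
  q2 <- base$motif_prevalence^2
  pb <- if (q2 >= 1) 0 else ratio / 2
  pm <- (ratio - (1 - q2) * pb) / q2
  if (pm <= pb || pm > 1) {
    stopf("ratio %.4f infeasible with motif prevalence %.2f", ratio,
          base$motif_prevalence)
  }
  base$p_background <- pb
  base$p_interact_match <- pm
  base
}

#' Write a synthetic dataset in the formats the loaders consume
#'
#' Emits `lnc.fasta`, `prot.fasta`, `pairs.tsv` (known positives) and
#' `truth.tsv` (carrier flags).  Byte-identical for identical specs.
#'
#' @param data an `lpi_synthetic`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_lpi_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta <- function(seqs, path) {
    con <- file(path, "wb") # binary mode: fixed newlines across platforms
    on.exit(close(con))
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con, sep = "\n")
  }
  write_fasta(data$rna, file.path(dir, "lnc.fasta"))
  write_fasta(data$protein, file.path(dir, "prot.fasta"))
  pp <- positive_pairs(data$matrix)
  write.table(pp, file.path(dir, "pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  truth <- data.frame(
    id = c(names(data$truth$lnc_carrier), names(data$truth$prot_carrier)),
    kind = c(rep("rna", length(data$truth$lnc_carrier)),
             rep("protein", length(data$truth$prot_carrier))),
    carrier = c(data$truth$lnc_carrier, data$truth$prot_carrier))
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
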