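#' Read lncRNA or protein sequences from FASTA
#'
#' Sequences are case-folded to upper case.  RNA sequences are normalized to
#' a single internal alphabet (by default `U -> T`, i.e. DNA letters) so
#' that all k-mer machinery is shared between the two conventions.
#'
#' @param path path to a FASTA file.
#' @param kind `"rna"` or `"protein"`.
#' @param ambiguity how to treat ambiguity codes (`N` for RNA; `B`, `Z`,
#'   `X`, `U`, `O` for protein): `"mask"` (keep them; descriptor code drops
#'   affected windows from counts) or `"error"`.
#' @param rna_alphabet store RNA as `"dna"` (U -> T, the default) or
#'   `"rna"` (T -> U).
#' @return a named character vector of sequences with attributes `kind`
#'   and class `lpi_seqs`.  Ids are the first whitespace-delimited token of
#'   each FASTA header.
#' @export
read_lpi_fasta <- function(path, kind = c("rna", "protein"),
                           ambiguity = c("mask", "error"),
                           rna_alphabet = c("dna", "rna")) {
  kind <- match.arg(kind)
  ambiguity <- match.arg(ambiguity)
  rna_alphabet <- match.arg(rna_alphabet)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  if (file.size(path) == 0) {
    return(new_lpi_seqs(character(0), kind))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (anyDuplicated(ids)) {
    stopf("duplicate sequence ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stopf("empty sequence for id(s): %s",
          paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  if (kind == "rna") {
    seqs <- if (rna_alphabet == "dna") chartr("U", "T", seqs) else
      chartr("T", "U", seqs)
    core <- if (rna_alphabet == "dna") DNA_BASES else c("A", "C", "G", "U")
    ambig <- RNA_AMBIG
  } else {
    core <- AA_ORDER
    ambig <- AA_AMBIG
  }
  allowed <- c(core, ambig)
  bad <- vapply(seqs, function(s) {
    ch <- unique(strsplit(s, "")[[1]])
    paste(setdiff(ch, allowed), collapse = "")
  }, character(1))
  if (any(nzchar(bad))) {
    stopf("illegal characters (%s) in sequence(s): %s",
          paste(unique(unlist(strsplit(bad[nzchar(bad)], ""))), collapse = ","),
          paste(ids[nzchar(bad)], collapse = ", "))
  }
  if (ambiguity == "error") {
    has_ambig <- vapply(seqs, function(s)
      any(strsplit(s, "")[[1]] %in% ambig), logical(1))
    if (any(has_ambig)) {
      stopf("ambiguity codes present (policy 'error') in: %s",
            paste(ids[has_ambig], collapse = ", "))
    }
  }
  new_lpi_seqs(seqs, kind)
}

new_lpi_seqs <- function(seqs, kind) {
  structure(seqs, kind = kind, class = "lpi_seqs")
}

#' @export
print.lpi_seqs <- function(x, ...) {
  cat(sprintf("<lpi_seqs> %d %s sequence(s)\n", length(x), attr(x, "kind")))
  invisible(x)
}

#' Build a binary interaction matrix from id lists and a pair list
#'
#' The matrix `y` has one row per lncRNA and one column per protein,
#' `y[i, j] = 1` iff the pair is listed as interacting, 0 otherwise.
#' Unlabeled cells are candidate negatives, not verified non-interactions.
#'
#' @param lnc_ids,prot_ids ordered id vectors (rows / columns).
#' @param pairs optional 2-column data frame or matrix of
#'   (lncRNA id, protein id) positives.
#' @return an object of class `lpi_matrix`: a list with `lnc_ids`,
#'   `prot_ids` and the binary matrix `y` (dimnamed).
#' @export
interaction_matrix <- function(lnc_ids, prot_ids, pairs = NULL) {
  lnc_ids <- as.character(lnc_ids)
  prot_ids <- as.character(prot_ids)
  if (anyDuplicated(lnc_ids) || anyDuplicated(prot_ids)) {
    stopf("entity ids must be unique")
  }
  y <- matrix(0L, length(lnc_ids), length(prot_ids),
              dimnames = list(lnc_ids, prot_ids))
  if (!is.null(pairs) && nrow(pairs) > 0) {
    pl <- as.character(pairs[[1]])
    pp <- as.character(pairs[[2]])
    bad <- !(pl %in% lnc_ids) | !(pp %in% prot_ids)
    if (any(bad)) {
      stopf("unknown id(s) in pair rows: %s",
            paste(which(bad), collapse = ", "))
    }
    key <- paste(pl, pp, sep = "\t")
    if (anyDuplicated(key)) {
      warnf("%d duplicate pair(s) collapsed", sum(duplicated(key)))
    }
    y[cbind(match(pl, lnc_ids), match(pp, prot_ids))] <- 1L
  }
  structure(list(lnc_ids = lnc_ids, prot_ids = prot_ids, y = y),
            class = "lpi_matrix")
}

#' Read a two-column TSV pair list into an interaction matrix
#'
#' @param path TSV file with two columns (lncRNA id, protein id), no header.
#' @param lnc_ids,prot_ids the full ordered id universes (typically the
#'   FASTA ids); every id in the file must be present.
#' @return an `lpi_matrix`.
#' @export
read_interactions <- function(path, lnc_ids, prot_ids) {
  if (!file.exists(path)) stopf("pair file not found: %s", path)
  if (file.size(path) == 0) {
    return(interaction_matrix(lnc_ids, prot_ids))
  }
  tab <- read.delim(path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stopf("pair list must have two tab-separated columns")
  interaction_matrix(lnc_ids, prot_ids, tab[, 1:2])
}

#' Positive pairs of an interaction matrix
#'
#' @param m an `lpi_matrix`.
#' @return data frame with columns `lnc_id`, `prot_id`, one row per known
#'   interaction, in row-major matrix order.
#' @export
positive_pairs <- function(m) {
  idx <- which(m$y == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(lnc_id = m$lnc_ids[idx[, 1]],
             prot_id = m$prot_ids[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' @export
print.lpi_matrix <- function(x, ...) {
  s <- dataset_stats(x)
  cat(sprintf("<lpi_matrix> %d lncRNAs x %d proteins, %d known LPIs (ratio %s)\n",
              s$n_lnc, s$n_prot, s$n_pos, format_ratio(s$pos_ratio)))
  invisible(x)
}

#' Dataset bookkeeping statistics
#'
#' Counts of entities, known interactions, candidate pairs, and the
#' positive ratio `n_pos / (n_lnc * n_prot)` that quantifies how imbalanced
#' an interaction dataset is.  The ratio is kept exact internally; use
#' [format_ratio()] for the conventional 4-decimal display.
#'
#' @param m an `lpi_matrix`.
#' @return a list of class `lpi_stats` with `n_lnc`, `n_prot`, `n_pos`,
#'   `n_pairs`, `pos_ratio`.
#' @export
dataset_stats <- function(m) {
  stopifnot(inherits(m, "lpi_matrix"))
  dataset_stats_counts(length(m$lnc_ids), length(m$prot_ids), sum(m$y))
}

#' @rdname dataset_stats
#' @param n_lnc,n_prot,n_pos entity and positive counts, for computing the
#'   same statistics directly from published dataset tables.
#' @export
dataset_stats_counts <- function(n_lnc, n_prot, n_pos) {
  n_lnc <- as.integer(n_lnc); n_prot <- as.integer(n_prot)
  n_pos <- as.integer(n_pos)
  n_pairs <- n_lnc * n_prot
  if (n_pos < 0 || n_pos > n_pairs) stopf("n_pos out of range")
  structure(list(n_lnc = n_lnc, n_prot = n_prot, n_pos = n_pos,
                 n_pairs = n_pairs,
                 pos_ratio = if (n_pairs > 0) n_pos / n_pairs else 0),
            class = "lpi_stats")
}

#' @rdname dataset_stats
#' @param x a ratio in `[0, 1]`.
#' @param digits display precision.
#' @return `format_ratio()`: the ratio rounded half-even to `digits`
#'   decimals, as a string.
#' @export
format_ratio <- function(x, digits = 4) {
  # base round() is IEC 60559 half-even, matching conventional table display
  formatC(round(x, digits), format = "f", digits = digits)
}

#' @export
print.lpi_stats <- function(x, ...) {
  cat(sprintf("lncRNAs: %d  proteins: %d  known LPIs: %d  pairs: %d  ratio: %s\n",
              x$n_lnc, x$n_prot, x$n_pos, x$n_pairs,
              format_ratio(x$pos_ratio)))
  invisible(x)
}

#' Export ranked pair predictions
#'
#' Sorts scored pairs by descending score (ties broken lexicographically by
#' lncRNA id then protein id), assigns ranks, and keeps the top `k`.
#'
#' @param scores data frame with columns `lnc_id`, `prot_id`, `score` and
#'   optionally `known` (logical flag for already-annotated pairs).
#' @param k number of top pairs to keep; if larger than the number of
#'   scored pairs the full table is returned with a warning.
#' @param path optional TSV output path.
#' @return the ranked data frame (`lnc_id`, `prot_id`, `score`, `rank`,
#'   `known`), invisibly if `path` is given.
#' @export
export_predictions <- function(scores, k, path = NULL) {
  stopifnot(all(c("lnc_id", "prot_id", "score") %in% names(scores)))
  if (any(!is.finite(scores$score))) stopf("non-finite prediction score")
  if (is.null(scores$known)) scores$known <- FALSE
  ord <- order(-scores$score, scores$lnc_id, scores$prot_id)
  out <- scores[ord, c("lnc_id", "prot_id", "score", "known")]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("lnc_id", "prot_id", "score", "rank", "known")]
  if (k > nrow(out)) {
    warnf("requested top %d but only %d pairs scored", k, nrow(out))
    k <- nrow(out)
  }
  out <- head(out, k)
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
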