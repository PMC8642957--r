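#' Deterministic seed derivation
#'
#' Fans a single master seed out into per-stage / per-iteration seeds so that
#' every stochastic stage of a run is independently reproducible.  The
#' derivation is a fixed multiplicative-congruential mix over the index path;
#' results are always in `[0, 2^31 - 2]` and therefore valid `set.seed()`
#' inputs.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the stage (e.g. repeat number,
#'   fold number, iteration).
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(42, 1, 3)
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483629 # large prime < 2^31
  s <- (abs(as.double(master)) + 1) %% m
  for (k in idx) {
    s <- (s * 48271 + (abs(as.double(k)) + 1) * 16807) %% m
  }
  as.integer(s)
}

# Binary Shannon entropy (base 2) of proportion p, with 0*log(0) := 0.
entropy2 <- function(p) {
  p <- pmin(pmax(p, 0), 1)
  q <- 1 - p
  h <- numeric(length(p))
  nz <- p > 0 & p < 1
  h[nz] <- -(p[nz] * log2(p[nz]) + q[nz] * log2(q[nz]))
  h
}

# Entropy (base 2) of an arbitrary proportion vector.
entropy_vec <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
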