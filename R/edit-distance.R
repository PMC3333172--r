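#' Levenshtein edit distance between two sequences
#'
#' Unit-cost substitutions, insertions and deletions. This is the distance
#' behind family assignment: a tag belongs to a miRNA family when it is within
#' `max_mismatch` (default 3) edits of the family's mature sequence, which is
#' also how length-variant isomiRs (21-24 nt within one family) are scored —
#' a Hamming distance could not compare sequences of unequal length.
#'
#' @param a,b nucleotide strings (normalized to the same alphabet by the
#'   caller; [rna_normalize()] is applied defensively).
#' @return non-negative integer; 0 iff the sequences are equal.
#' @examples
#' edit_distance("UUGGCAUUCUGUCCACCUCCC", "UUUGGCAUUCUGUCCACCUCC")  # 2
#' @export
edit_distance <- function(a, b) {
  a <- rna_normalize(a); b <- rna_normalize(b)
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("edit_distance requires nonempty sequences", call. = FALSE)
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    sub <- prev[1:m] + (x[i] != y)
    # row-wise DP; the cumulative pass resolves left-to-right insertions
    cand <- pmin(sub, prev[2:(m + 1L)] + 1L)
    cur[2:(m + 1L)] <- cand
    for (j in 2:(m + 1L)) {
      if (m >= 1L && j >= 2L) {
        v <- cur[j - 1L] + 1L
        if (v < cur[j]) cur[j] <- v
      }
    }
    prev <- cur
  }
  prev[m + 1L]
}

## Banded Levenshtein with early abort: returns the exact distance when it is
## <= k, otherwise k + 1. Used for catalog matching and generator rejection
## sampling, where only "within k edits?" matters (k = 3 by default).
edit_distance_bounded <- function(a, b, k) {
  k <- as.integer(k)
  n <- nchar(a); m <- nchar(b)
  if (abs(n - m) > k) return(k + 1L)
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  big <- k + 1L
  prev <- c(0:min(k, m), rep.int(big, max(0L, m - k)))
  for (i in seq_len(n)) {
    lo <- max(1L, i - k); hi <- min(m, i + k)
    cur <- rep.int(big, m + 1L)
    cur[1L] <- if (i <= k) i else big
    for (j in lo:hi) {
      v <- min(prev[j] + (x[i] != y[j]),
               prev[j + 1L] + 1L,
               cur[j] + 1L)
      cur[j + 1L] <- min(v, big)
    }
    if (min(cur[(lo + 1L):(hi + 1L)]) >= big) return(big)
    prev <- cur
  }
  min(prev[m + 1L], big)
}

## Bounded distances from each query to each reference: integer matrix
## (length(queries) x length(refs)) with entries in 0..(k+1), k+1 meaning "> k".
bounded_distance_matrix <- function(queries, refs, k) {
  out <- matrix(k + 1L, nrow = length(queries), ncol = length(refs))
  for (j in seq_along(refs)) {
    rj <- refs[[j]]
    out[, j] <- vapply(queries, edit_distance_bounded, integer(1),
                       b = rj, k = k, USE.NAMES = FALSE)
  }
  out
}

#' Group sequences into families by single-linkage under an edit threshold
#'
#' Two sequences belong to the same family when they are connected by a chain
#' of pairwise distances \eqn{\le} `max_edits`. With well-separated mature
#' sequences (pairwise distance > `max_edits`) each family is a singleton; with
#' isomiR clouds the cloud collapses onto its family.
#'
#' @param sequences character vector (RNA or DNA; normalized internally).
#' @param max_edits integer edit threshold (default 3).
#' @return integer vector of family indices (1-based, in order of first
#'   appearance), one per input sequence.
#' @export
cluster_families <- function(sequences, max_edits = 3L) {
  seqs <- rna_normalize(sequences)
  n <- length(seqs)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (edit_distance_bounded(seqs[i], seqs[j], max_edits) <= max_edits) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
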