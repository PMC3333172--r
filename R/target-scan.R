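#' Position-weighted plant duplex scoring scheme
#'
#' The established plant target-scoring convention: each mismatch costs 1,
#' each G:U wobble 0.5, penalties opposite miRNA positions 2-13 (the seed
#' region, counted from the miRNA 5' end) are doubled, and sites scoring at
#' most `max_score` (default 3) are reported. Plant miRNAs bind their targets
#' with perfect or near-perfect complementarity, so a cheap ungapped scheme
#' captures essentially all true sites; `gap_penalty` is reserved.
#'
#' @param mismatch_penalty cost of a non-pairing position (default 1).
#' @param gu_penalty cost of a G:U wobble (default 0.5).
#' @param gap_penalty reserved; gapped alignment is not performed (default 2).
#' @param seed_range miRNA positions whose penalties are doubled
#'   (default 2:13).
#' @param seed_multiplier penalty multiplier inside the seed (default 2).
#' @param max_score maximum reportable score (default 3).
#' @return list of class `duplex_scheme`.
#' @export
duplex_scheme <- function(mismatch_penalty = 1.0, gu_penalty = 0.5,
                          gap_penalty = 2.0, seed_range = 2:13,
                          seed_multiplier = 2.0, max_score = 3.0) {
  stopifnot(mismatch_penalty >= 0, gu_penalty >= 0, gap_penalty >= 0,
            seed_multiplier >= 0, all(seed_range >= 1))
  structure(list(mismatch_penalty = mismatch_penalty,
                 gu_penalty = gu_penalty, gap_penalty = gap_penalty,
                 seed_range = as.integer(seed_range),
                 seed_multiplier = seed_multiplier, max_score = max_score),
            class = "duplex_scheme")
}

#' Score an ungapped miRNA:site duplex
#'
#' The site (sense strand, 5'->3') is compared position by position against
#' the reverse complement of the miRNA, so miRNA position i (from the miRNA
#' 5' end) faces site position L - i + 1. A perfect complement scores 0.
#'
#' @param mirna miRNA sequence (RNA).
#' @param site candidate site (RNA), same length as `mirna`.
#' @param scheme a [duplex_scheme()].
#' @return list with `score` and `alignment` (three lines: miRNA 3'->5',
#'   pairing symbols `|` = Watson-Crick, `o` = G:U, space = mismatch, site
#'   5'->3').
#' @export
score_duplex <- function(mirna, site, scheme = duplex_scheme()) {
  mirna <- rna_normalize(mirna); site <- rna_normalize(site)
  if (nchar(mirna) != nchar(site))
    stop("ungapped scoring requires equal lengths", call. = FALSE)
  assert_rna(mirna, "mirna")
  L <- nchar(mirna)
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  s <- strsplit(site, "", fixed = TRUE)[[1]]
  # miRNA position i faces site position L - i + 1 (antiparallel duplex)
  s_f <- rev(s)
  wc <- (m == "A" & s_f == "U") | (m == "U" & s_f == "A") |
        (m == "G" & s_f == "C") | (m == "C" & s_f == "G")
  gu <- (m == "G" & s_f == "U") | (m == "U" & s_f == "G")
  pen <- ifelse(wc, 0, ifelse(gu, scheme$gu_penalty,
                              scheme$mismatch_penalty))
  in_seed <- seq_len(L) %in% scheme$seed_range
  pen[in_seed] <- pen[in_seed] * scheme$seed_multiplier
  sym <- ifelse(wc, "|", ifelse(gu, "o", " "))
  alignment <- paste(
    paste(rev(m), collapse = ""),         # miRNA 3'->5'
    paste(rev(sym), collapse = ""),
    paste(s, collapse = ""),              # site 5'->3'
    sep = "\n")
  list(score = sum(pen), alignment = alignment)
}

#' Scan transcripts for miRNA target sites
#'
#' Scores every sense-strand window of miRNA length on every transcript,
#' reports windows with score <= `scheme$max_score`, merges overlapping hits
#' of the same miRNA/transcript keeping the best (lowest) score, and sorts by
#' ascending score then coordinates. Coordinates are 0-based half-open on the
#' transcript. Degenerate bases count as mismatches; transcripts shorter than
#' the miRNA are skipped with a warning.
#'
#' @param mirna_id identifier for the miRNA.
#' @param mirna miRNA sequence (RNA).
#' @param transcripts named character vector of transcript sequences, or a
#'   path to a FASTA file.
#' @param scheme a [duplex_scheme()].
#' @return data.frame: mirna_id, transcript_id, start, end, score, alignment.
#' @export
scan_transcripts <- function(mirna_id, mirna, transcripts,
                             scheme = duplex_scheme()) {
  if (length(transcripts) == 1L && is.character(transcripts) &&
      is.null(names(transcripts)) && file.exists(transcripts)) {
    x <- Biostrings::readBStringSet(transcripts)
    transcripts <- stats::setNames(as.character(x), names(x))
  }
  if (length(transcripts) == 0L)
    stop("transcripts must be nonempty", call. = FALSE)
  mirna <- rna_normalize(mirna)
  L <- nchar(mirna)
  hits <- list()
  for (tx in names(transcripts)) {
    seq_tx <- rna_normalize(transcripts[[tx]])
    Tn <- nchar(seq_tx)
    if (Tn < L) {
      warning("transcript ", tx, " shorter than miRNA; skipped",
              call. = FALSE)
      next
    }
    sc <- score_windows(mirna, seq_tx, scheme)
    keep <- which(sc <= scheme$max_score)
    if (length(keep) == 0L) next
    # merge overlapping windows, keeping the best score (ties: leftmost)
    keep <- keep[order(sc[keep], keep)]
    chosen <- integer(0)
    for (w in keep) {
      if (!any(abs(chosen - w) < L)) chosen <- c(chosen, w)
    }
    for (w in sort(chosen)) {
      site <- substr(seq_tx, w, w + L - 1L)
      d <- score_duplex(mirna, site, scheme)
      hits[[length(hits) + 1L]] <- data.frame(
        mirna_id = mirna_id, transcript_id = tx,
        start = w - 1L, end = w + L - 1L,
        score = d$score, alignment = d$alignment,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), alignment = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$score, out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Vectorized window scores of a miRNA along one transcript: for each miRNA
## position the facing transcript base across all windows is one strided
## slice, so the scan is O(miRNA length) vector operations.
score_windows <- function(mirna, transcript, scheme) {
  L <- nchar(mirna)
  Tn <- nchar(transcript)
  nwin <- Tn - L + 1L
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  t_ch <- strsplit(transcript, "", fixed = TRUE)[[1]]
  pen <- numeric(nwin)
  for (i in seq_len(L)) {
    face <- t_ch[(L - i + 1L):(L - i + nwin)]  # site pos L-i+1 per window
    wc <- (m[i] == "A" & face == "U") | (m[i] == "U" & face == "A") |
          (m[i] == "G" & face == "C") | (m[i] == "C" & face == "G")
    gu <- (m[i] == "G" & face == "U") | (m[i] == "U" & face == "G")
    p <- ifelse(wc, 0, ifelse(gu, scheme$gu_penalty,
                              scheme$mismatch_penalty))
    if (i %in% scheme$seed_range) p <- p * scheme$seed_multiplier
    pen <- pen + p
  }
  pen
}
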