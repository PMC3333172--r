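# Independent oracles, deliberately naive: plain recursion and exhaustive
# enumeration, never sharing code with the implementation they check.

# Brute-force recursive Levenshtein distance (exponential; lengths <= 8).
oracle_levenshtein <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  ha <- substr(a, 1, 1); hb <- substr(b, 1, 1)
  ta <- substr(a, 2, nchar(a)); tb <- substr(b, 2, nchar(b))
  min(oracle_levenshtein(ta, tb) + (ha != hb),
      oracle_levenshtein(ta, b) + 1,
      oracle_levenshtein(a, tb) + 1)
}

oracle_can_pair <- function(a, b, allow_gu = TRUE) {
  wc <- paste0(a, b) %in% c("AU", "UA", "GC", "CG")
  if (allow_gu) wc || paste0(a, b) %in% c("GU", "UG") else wc
}

# Maximum nested pairs by exhaustive enumeration over all nested structures
# (exponential; lengths <= 12).
oracle_max_pairs <- function(seq, min_loop = 3, allow_gu = TRUE) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  memo <- new.env()
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i, j - 1)                    # j unpaired
    for (k in i:(j - min_loop - 1)) {
      if (oracle_can_pair(ch[k], ch[j], allow_gu)) {
        left <- if (k > i) rec(i, k - 1) else 0L
        best <- max(best, left + 1L + rec(k + 1, j - 1))
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1, length(ch))
}

# All-window duplex scores of a miRNA along a transcript, one window at a
# time through score_duplex (no striding, no vectorized scan).
oracle_window_scores <- function(mirna, transcript, scheme) {
  L <- nchar(mirna)
  starts <- seq_len(nchar(transcript) - L + 1)
  vapply(starts, function(s)
    score_duplex(mirna, substr(transcript, s, s + L - 1), scheme)$score,
    numeric(1))
}

# Leftmost qualifying adapter alignment by trying every offset explicitly.
oracle_trim_cut <- function(read, adapter, min_overlap, max_rate) {
  rl <- nchar(read); al <- nchar(adapter)
  for (p in seq_len(rl)) {
    ov <- min(al, rl - p + 1)
    if (ov < al && ov < min_overlap) next
    mm <- sum(strsplit(substr(read, p, p + ov - 1), "")[[1]] !=
                strsplit(substr(adapter, 1, ov), "")[[1]])
    if (mm / ov <= max_rate) return(p - 1)
  }
  NA_integer_
}

random_rna_str <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Small two-library tag table built by hand for unit tests.
make_tags <- function(seqs, count_A, count_B) {
  tags <- collapse_tags(list(A = rep(seqs, count_A), B = rep(seqs, count_B)))
  assign_tag_ids(tags)
}
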