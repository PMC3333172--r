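#' Read a mature-miRNA catalog from FASTA
#'
#' Headers are `>family|source` (source optional); sequences are normalized
#' to the RNA alphabet.
#'
#' @param path FASTA file.
#' @return data.frame with columns family, mature_sequence, source.
#' @export
read_mirna_catalog <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  parts <- strsplit(names(x), "|", fixed = TRUE)
  data.frame(
    family = vapply(parts, `[`, character(1), 1L),
    mature_sequence = rna_normalize(as.character(x)),
    source = vapply(parts, function(p)
      if (length(p) > 1L) p[2L] else "unknown", character(1)),
    stringsAsFactors = FALSE)
}

#' Assign sequence tags to miRNA families by mismatch-tolerant matching
#'
#' Each tag inside the annotation length window is compared with every
#' catalog entry under the Levenshtein distance; the tag is assigned to the
#' family minimizing the distance when that minimum is at most `max_mismatch`
#' edits. Equidistant entries are resolved by the lexicographically smallest
#' family name, so assignment is deterministic.
#'
#' @param tags a tag table (see [collapse_tags()]), or a character vector of
#'   sequences.
#' @param catalog reference catalog (family, mature_sequence).
#' @param max_mismatch maximum edit distance for family membership
#'   (default 3).
#' @param window annotation length window, inclusive (default c(19, 24));
#'   tags outside it are not matched.
#' @return data.frame with one row per assigned tag: tag_id, sequence,
#'   family, edit_distance, isoform_index (NA until [group_isoforms()]).
#' @export
match_catalog <- function(tags, catalog, max_mismatch = 3L,
                          window = c(19L, 24L)) {
  if (is.null(catalog) || nrow(catalog) == 0L)
    stop("catalog must be nonempty", call. = FALSE)
  if (is.character(tags))
    tags <- data.frame(tag_id = tags, sequence = tags,
                       length = nchar(tags), stringsAsFactors = FALSE)
  empty <- data.frame(tag_id = character(0), sequence = character(0),
                      family = character(0), edit_distance = integer(0),
                      isoform_index = integer(0), stringsAsFactors = FALSE)
  if (nrow(tags) == 0L) return(empty)
  in_win <- tags$length >= window[1] & tags$length <= window[2]
  cand <- tags[in_win, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  refs <- rna_normalize(catalog$mature_sequence)
  # resolve ties toward the lexicographically smallest family name
  fam_order <- order(catalog$family)
  refs <- refs[fam_order]
  fams <- catalog$family[fam_order]
  d <- bounded_distance_matrix(rna_normalize(cand$sequence), refs,
                               k = max_mismatch)
  best <- max.col(-d, ties.method = "first")
  bestd <- d[cbind(seq_len(nrow(d)), best)]
  hit <- bestd <= max_mismatch
  data.frame(tag_id = cand$tag_id[hit],
             sequence = cand$sequence[hit],
             family = fams[best[hit]],
             edit_distance = as.integer(bestd[hit]),
             isoform_index = rep(NA_integer_, sum(hit)),
             stringsAsFactors = FALSE)
}

#' Enumerate isoforms within each assigned family
#'
#' Within a family, the distinct assigned tag sequences are numbered 1..k in
#' order of descending total read count (ties broken lexicographically), so
#' isoform 1 is the family's most abundant variant. The numbering is a
#' permutation of 1..k and invariant under row order.
#'
#' @param assignments output of [match_catalog()].
#' @param tags the tag table the assignments refer to.
#' @return `assignments` with `isoform_index` filled.
#' @export
group_isoforms <- function(assignments, tags) {
  if (nrow(assignments) == 0L) return(assignments)
  if (!all(assignments$tag_id %in% tags$tag_id))
    stop("assignments reference tags absent from the tag table",
         call. = FALSE)
  tot <- tag_totals(tags)[match(assignments$tag_id, tags$tag_id)]
  assignments$isoform_index <- NA_integer_
  for (fam in unique(assignments$family)) {
    rows <- which(assignments$family == fam)
    ord <- rows[order(-tot[rows], assignments$sequence[rows])]
    assignments$isoform_index[ord] <- seq_along(ord)
  }
  assignments
}

#' Flag tags that are exact fragments of abundant non-coding RNAs
#'
#' A tag is a contaminant when it occurs verbatim (forward strand,
#' RNA-normalized) inside an entry of the rRNA/tRNA/snRNA catalog. Exact
#' substring match only; contaminant flagging runs before family matching so
#' ncRNA fragments never enter the miRNA classes.
#'
#' @param tags tag table or character vector of sequences.
#' @param ncrna_catalog data.frame with columns name, sequence (may have
#'   zero rows).
#' @return character vector (one per tag): matching catalog name or NA.
#' @export
flag_contaminant <- function(tags, ncrna_catalog) {
  seqs <- if (is.character(tags)) tags else tags$sequence
  seqs <- rna_normalize(seqs)
  out <- rep(NA_character_, length(seqs))
  if (is.null(ncrna_catalog) || nrow(ncrna_catalog) == 0L) return(out)
  cat_seq <- rna_normalize(ncrna_catalog$sequence)
  for (i in seq_along(seqs)) {
    hit <- which(vapply(cat_seq, function(s)
      grepl(seqs[i], s, fixed = TRUE), logical(1)))
    if (length(hit)) out[i] <- ncrna_catalog$name[hit[1L]]
  }
  out
}
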