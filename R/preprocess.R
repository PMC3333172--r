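#' Adapter trimming parameters
#'
#' @param adapter 3' adapter sequence (DNA or RNA alphabet).
#' @param min_overlap minimum adapter bases that must align at the read's 3'
#'   end for a truncated (suffix) match (default 6).
#' @param max_mismatch_rate maximum per-alignment mismatch rate (default 0.1).
#' @param require_adapter reject reads without an adapter match (default TRUE).
#' @return list of class `trim_params`.
#' @export
trim_params <- function(adapter, min_overlap = 6L, max_mismatch_rate = 0.1,
                        require_adapter = TRUE) {
  if (is.null(adapter) || !nzchar(adapter))
    stop("adapter must be a nonempty sequence", call. = FALSE)
  stopifnot(min_overlap >= 1, max_mismatch_rate >= 0, max_mismatch_rate < 0.5)
  structure(list(adapter = toupper(chartr("U", "T", adapter)),
                 min_overlap = as.integer(min_overlap),
                 max_mismatch_rate = max_mismatch_rate,
                 require_adapter = isTRUE(require_adapter)),
            class = "trim_params")
}

#' Trim the 3' adapter from reads
#'
#' Finds, for each read, the leftmost alignment of the adapter — either the
#' full adapter internally, or a 3'-truncated adapter suffix of at least
#' `min_overlap` bases at the read end — whose mismatch rate does not exceed
#' `max_mismatch_rate`, and removes it together with everything 3' of it.
#' No indels are allowed in the adapter alignment. Reads with no qualifying
#' alignment are rejected with reason `no_adapter` when `require_adapter` is
#' set, and reads whose insert is empty after trimming are rejected with
#' reason `empty_insert`.
#'
#' @param reads character vector of read sequences (DNA alphabet as
#'   sequenced).
#' @param params a [trim_params()].
#' @return data.frame with columns `read` (the input), `insert` (trimmed
#'   sequence or NA) and `status` ("ok", "no_adapter" or "empty_insert").
#' @export
trim_adapter <- function(reads, params) {
  stopifnot(inherits(params, "trim_params"))
  reads <- toupper(reads)
  n <- length(reads)
  if (n == 0L)
    return(data.frame(read = character(0), insert = character(0),
                      status = character(0), stringsAsFactors = FALSE))
  # small-RNA libraries are dominated by duplicated reads: trim each distinct
  # read sequence once and map the result back
  uread <- unique(reads)
  idx <- match(reads, uread)
  adapter <- params$adapter
  cut <- rep(NA_integer_, length(uread))
  for (i in seq_along(uread))
    cut[i] <- trim_scan_one(uread[i], adapter, params$min_overlap,
                            params$max_mismatch_rate)
  u_insert <- rep(NA_character_, length(uread))
  u_status <- rep("ok", length(uread))
  no_hit <- is.na(cut)
  if (params$require_adapter) {
    u_status[no_hit] <- "no_adapter"
  } else {
    u_insert[no_hit] <- uread[no_hit]
  }
  hit <- !no_hit
  u_insert[hit] <- substr(uread[hit], 1L, cut[hit])
  empty <- !is.na(u_insert) & u_insert == ""
  u_status[empty] <- "empty_insert"
  u_insert[u_status != "ok"] <- NA_character_
  data.frame(read = reads, insert = u_insert[idx], status = u_status[idx],
             stringsAsFactors = FALSE)
}

## Exhaustive leftmost alignment scan for one read; returns the 0-based cut
## position (insert length) or NA. Offsets are tried left to right; at each,
## the overlap is min(adapter length, bases left in the read).
trim_scan_one <- function(read, adapter, min_overlap, max_mismatch_rate) {
  rl <- nchar(read); al <- nchar(adapter)
  rch <- strsplit(read, "", fixed = TRUE)[[1]]
  ach <- strsplit(adapter, "", fixed = TRUE)[[1]]
  for (p in seq_len(rl)) {
    ov <- min(al, rl - p + 1L)
    if (ov < min(al, min_overlap)) next
    if (ov < al && rl - p + 1L > ov) next  # truncated match only at read end
    mm <- sum(rch[p:(p + ov - 1L)] != ach[1:ov])
    if (mm / ov <= max_mismatch_rate) return(p - 1L)
  }
  NA_integer_
}

#' Length selection for trimmed inserts
#'
#' @param sequences character vector of insert sequences.
#' @param min_len,max_len inclusive retention window (defaults 7 and 35 nt).
#' @return logical vector: keep (TRUE) / reject (FALSE).
#' @export
filter_length <- function(sequences, min_len = 7L, max_len = 35L) {
  if (min_len > max_len)
    stop("min_len must not exceed max_len", call. = FALSE)
  L <- nchar(sequences)
  L >= min_len & L <= max_len
}

#' Collapse identical reads into counted sequence tags
#'
#' All identical insert sequences (after T->U normalization and uppercasing)
#' are counted per library; the resulting unique sequences with their
#' per-library read counts are the sequence tags that every downstream stage
#' operates on. Reads containing N are dropped and reported via the
#' `n_rejected_N` attribute.
#'
#' @param reads_by_library named list: library id -> character vector of
#'   retained insert sequences.
#' @return data.frame with columns `tag_id` (NA until [assign_tag_ids()]),
#'   `sequence`, `length`, and one `count_<lib>` column per library; attribute
#'   `libraries` holds the library ids.
#' @export
collapse_tags <- function(reads_by_library) {
  libs <- names(reads_by_library)
  if (is.null(libs) || any(!nzchar(libs)))
    stop("reads_by_library must be a named list", call. = FALSE)
  cleaned <- lapply(reads_by_library, function(x) {
    x <- rna_normalize(x)
    x[!grepl("N", x, fixed = TRUE)]
  })
  n_rejected_N <- sum(lengths(reads_by_library)) - sum(lengths(cleaned))
  all_seq <- sort(unique(unlist(cleaned, use.names = FALSE)))
  out <- data.frame(tag_id = rep(NA_character_, length(all_seq)),
                    sequence = all_seq, length = nchar(all_seq),
                    stringsAsFactors = FALSE)
  for (lib in libs) {
    tb <- table(factor(cleaned[[lib]], levels = all_seq))
    out[[paste0("count_", lib)]] <- as.integer(tb)
  }
  attr(out, "libraries") <- libs
  attr(out, "n_rejected_N") <- n_rejected_N
  out
}

## Count columns of a tag table, in library order.
count_columns <- function(tags) {
  libs <- attr(tags, "libraries") %||%
    sub("^count_", "", grep("^count_", names(tags), value = TRUE))
  paste0("count_", libs)
}

## Total count per tag across libraries.
tag_totals <- function(tags) {
  cc <- count_columns(tags)
  if (length(cc) == 0L) return(integer(nrow(tags)))
  as.integer(rowSums(as.matrix(tags[, cc, drop = FALSE])))
}

#' Assign rank-based tag identifiers
#'
#' Ids have the form `<rank>(<length>)`, ranking tags by descending total
#' count across libraries with ties broken by lexicographic sequence order,
#' mirroring the `15212(24)`-style identifiers of two-library small-RNA
#' studies. The assignment is deterministic and stable under permutation of
#' the input rows.
#'
#' @param tags a tag table from [collapse_tags()].
#' @return the same table, reordered by rank, with `tag_id` filled.
#' @export
assign_tag_ids <- function(tags) {
  if (nrow(tags) == 0L) return(tags)
  tot <- tag_totals(tags)
  ord <- order(-tot, tags$sequence)
  tags <- tags[ord, , drop = FALSE]
  tags$tag_id <- sprintf("%d(%d)", seq_len(nrow(tags)), tags$length)
  rownames(tags) <- NULL
  tags
}

#' Per-library length profile of a tag set
#'
#' For every library and insert length, the number of unique tags with a
#' positive count and the total read count — the two length distributions
#' (unique vs total) that characterize a small-RNA library.
#'
#' @param tags a tag table.
#' @return data.frame with columns `library`, `length`, `n_unique`,
#'   `n_total`.
#' @export
length_histogram <- function(tags) {
  libs <- attr(tags, "libraries") %||%
    sub("^count_", "", grep("^count_", names(tags), value = TRUE))
  out <- list()
  for (lib in libs) {
    cnt <- tags[[paste0("count_", lib)]]
    pos <- cnt > 0
    if (!any(pos)) next
    lens <- sort(unique(tags$length[pos]))
    out[[lib]] <- data.frame(
      library = lib, length = lens,
      n_unique = vapply(lens, function(L)
        sum(pos & tags$length == L), integer(1)),
      n_total = vapply(lens, function(L)
        as.integer(sum(cnt[tags$length == L])), integer(1)),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(library = character(0), length = integer(0),
                      n_unique = integer(0), n_total = integer(0)))
  ret <- do.call(rbind, out)
  rownames(ret) <- NULL
  ret
}

#' Read a small-RNA library from FASTA or FASTQ
#'
#' Format is taken from the file extension (.fastq/.fq vs anything else);
#' sequences are returned as uppercase character strings in the alphabet of
#' the file.
#'
#' @param path input file.
#' @return named character vector of read sequences (names are record ids).
#' @export
read_small_rna <- function(path) {
  if (!file.exists(path)) stop("input not found: ", path, call. = FALSE)
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  x <- Biostrings::readBStringSet(path, format = fmt)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write a tag table as TSV
#'
#' @param tags a tag table.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tag_table <- function(tags, path) {
  utils::write.table(tags, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
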