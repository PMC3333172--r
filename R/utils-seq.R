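RNA_BASES <- c("A", "C", "G", "U")

#' Normalize sequences to the uppercase RNA alphabet
#'
#' Uppercases and converts T to U. Tags, catalog entries and transcripts are
#' all compared in RNA space, so normalization happens once, up front.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over \{A,C,G,U,N,...\}.
#' @export
rna_normalize <- function(x) {
  chartr("t", "U", chartr("T", "U", toupper(x)))
}

#' Reverse complement in RNA space
#'
#' @param x character vector of RNA sequences (A/C/G/U).
#' @return character vector of reverse complements.
#' @export
revcomp_rna <- function(x) {
  comp <- chartr("ACGU", "UGCA", rna_normalize(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Random RNA strings of the given lengths.
random_rna <- function(lengths) {
  vapply(lengths, function(L)
    paste(sample(RNA_BASES, L, replace = TRUE), collapse = ""), character(1))
}

#' Dinucleotide-preserving shuffle
#'
#' Shuffles a sequence while preserving its exact dinucleotide composition
#' (Altschul-Erickson Eulerian-path shuffle). Used to build null sequences for
#' the hairpin-foldability check: a shuffle keeps mono- and di-nucleotide
#' content but destroys the long stem of a genuine precursor.
#'
#' @param x a single RNA/DNA sequence.
#' @param seed optional integer seed.
#' @return a shuffled sequence with identical dinucleotide counts.
#' @export
shuffle_dinucleotide <- function(x, seed = NULL) {
  with_seed(seed, {
    ch <- strsplit(x, "", fixed = TRUE)[[1]]
    n <- length(ch)
    if (n < 3) return(x)
    from <- ch[-n]; to <- ch[-1]
    verts <- unique(ch)
    s_end <- ch[n]
    # adjacency: edge list per vertex
    edges <- split(to, factor(from, levels = verts))
    repeat {
      # pick a random last edge out of each vertex (except the end vertex);
      # accept if those last edges form a tree rooted at s_end
      last <- vapply(verts, function(v) {
        if (v == s_end || length(edges[[v]]) == 0) return(NA_character_)
        sample(edges[[v]], 1)
      }, character(1))
      ok <- TRUE
      for (v in verts) {
        if (v == s_end || is.na(last[[v]])) next
        # walk last-edge chain; must reach s_end without cycling
        seen <- character(0); cur <- v
        while (cur != s_end) {
          if (cur %in% seen || is.na(last[[cur]])) { ok <- FALSE; break }
          seen <- c(seen, cur)
          cur <- last[[cur]]
        }
        if (!ok) break
      }
      if (ok) break
    }
    # permute non-last edges, append the chosen last edge
    ord <- lapply(verts, function(v) {
      e <- edges[[v]]
      if (v != s_end && !is.na(last[[v]])) {
        i <- match(last[[v]], e)
        e <- e[-i]
      }
      e <- if (length(e) > 1) sample(e) else e
      if (v != s_end && !is.na(last[[v]])) e <- c(e, last[[v]])
      e
    })
    names(ord) <- verts
    used <- stats::setNames(integer(length(verts)), verts)
    out <- character(n); out[1] <- ch[1]; cur <- ch[1]
    for (i in 2:n) {
      used[cur] <- used[cur] + 1L
      nxt <- ord[[cur]][used[cur]]
      out[i] <- nxt
      cur <- nxt
    }
    paste(out, collapse = "")
  })
}

## Validate that a sequence vector is over the RNA alphabet.
assert_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad))
    stop(what, " contains characters outside {A,C,G,U}: ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  invisible(x)
}
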