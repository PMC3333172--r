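#' Abundance thresholds for small-RNA classification
#'
#' Unannotated tags are separated by expression level: abundant tags
#' (>= `novel_min_count`, i.e. counts in the thousands) are putative novel
#' miRNAs when nothing contradicts hairpin origin; rare tags
#' (<= `sirna_max_count`, i.e. below 100 counts) are siRNA-like; the
#' intermediate band cannot be differentiated without a genome and stays
#' unclassified.
#'
#' @param novel_min_count minimum count for a putative novel miRNA
#'   (default 1000).
#' @param sirna_max_count maximum count for an siRNA-like tag (default 99).
#' @param count_scope which per-library count is compared: "max" (default;
#'   at least one library carries the high count) or "sum".
#' @return list of class `class_thresholds`.
#' @export
class_thresholds <- function(novel_min_count = 1000L, sirna_max_count = 99L,
                             count_scope = c("max", "sum")) {
  count_scope <- match.arg(count_scope)
  if (!(sirna_max_count < novel_min_count))
    stop("sirna_max_count must be below novel_min_count", call. = FALSE)
  structure(list(novel_min_count = novel_min_count,
                 sirna_max_count = sirna_max_count,
                 count_scope = count_scope),
            class = "class_thresholds")
}

CLASS_LABELS <- c("conserved_miRNA", "putative_novel_miRNA",
                  "unclassified_smallRNA", "siRNA_like", "ncRNA_fragment")

#' Classify sequence tags
#'
#' Decision order: an ncRNA fragment is `ncRNA_fragment`; a tag assigned to a
#' catalog family is `conserved_miRNA` regardless of count; an unannotated
#' tag whose count (per `count_scope`) reaches `novel_min_count` is
#' `putative_novel_miRNA` provided its hairpin check, when available, passes
#' (tags without a precursor candidate skip the check, as expression level is
#' then the only usable evidence); a tag at or below `sirna_max_count` is
#' `siRNA_like`; everything else is `unclassified_smallRNA`.
#'
#' @param tags tag table.
#' @param assignments family assignments from [match_catalog()] (may be
#'   empty).
#' @param contaminants character vector from [flag_contaminant()] (or NULL).
#' @param thresholds a [class_thresholds()].
#' @param hairpins optional named list mapping tag sequence -> result of
#'   [is_hairpin()] for tags with known precursor candidates.
#' @return data.frame: tag_id, sequence, label, family, edit_distance,
#'   per-library counts, hairpin_pairs, paired_fraction_mature.
#' @export
classify_tags <- function(tags, assignments = NULL, contaminants = NULL,
                          thresholds = class_thresholds(),
                          hairpins = NULL) {
  stopifnot(inherits(thresholds, "class_thresholds"))
  n <- nrow(tags)
  cc <- count_columns(tags)
  cnt <- as.matrix(tags[, cc, drop = FALSE])
  scope_count <- if (thresholds$count_scope == "max")
    apply(cnt, 1L, max) else rowSums(cnt)
  if (n == 0L) scope_count <- numeric(0)
  fam <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  if (!is.null(assignments) && nrow(assignments) > 0L) {
    m <- match(tags$tag_id, assignments$tag_id)
    fam <- assignments$family[m]
    dist <- assignments$edit_distance[m]
  }
  contam <- if (is.null(contaminants)) rep(NA_character_, n) else contaminants
  hp_pairs <- rep(NA_integer_, n)
  hp_frac <- rep(NA_real_, n)
  hp_ok <- rep(NA, n)
  if (!is.null(hairpins) && length(hairpins)) {
    m <- match(tags$sequence, names(hairpins))
    for (i in which(!is.na(m))) {
      hp <- hairpins[[m[i]]]
      hp_pairs[i] <- hp$n_pairs
      hp_frac[i] <- hp$paired_fraction_mature
      hp_ok[i] <- hp$is_hairpin
    }
  }
  label <- character(n)
  for (i in seq_len(n)) {
    label[i] <- classify_tag(
      scope_count[i], has_family = !is.na(fam[i]),
      is_contaminant = !is.na(contam[i]),
      thresholds = thresholds, hairpin_pass = hp_ok[i])
  }
  # conserved tags keep no hairpin columns; contaminants keep no family
  fam[!is.na(contam)] <- NA_character_
  out <- data.frame(tag_id = tags$tag_id, sequence = tags$sequence,
                    label = label, family = fam, edit_distance = dist,
                    stringsAsFactors = FALSE)
  out <- cbind(out, tags[, cc, drop = FALSE])
  out$hairpin_pairs <- hp_pairs
  out$paired_fraction_mature <- hp_frac
  out$contaminant <- contam
  rownames(out) <- NULL
  out
}

#' Classification rule for a single tag
#'
#' @param count the tag's count under the configured scope.
#' @param has_family TRUE when the tag is assigned to a catalog family.
#' @param is_contaminant TRUE when the tag is an ncRNA fragment.
#' @param thresholds a [class_thresholds()].
#' @param hairpin_pass TRUE/FALSE result of the hairpin check, or NA when no
#'   precursor candidate exists.
#' @return one of the five class labels.
#' @export
classify_tag <- function(count, has_family, is_contaminant,
                         thresholds = class_thresholds(),
                         hairpin_pass = NA) {
  if (is_contaminant) return("ncRNA_fragment")
  if (has_family) return("conserved_miRNA")
  if (count >= thresholds$novel_min_count &&
      (is.na(hairpin_pass) || isTRUE(hairpin_pass)))
    return("putative_novel_miRNA")
  if (count <= thresholds$sirna_max_count) return("siRNA_like")
  "unclassified_smallRNA"
}

## Watson-Crick (+ optional G:U) pairing predicate on single bases.
can_pair <- function(a, b, allow_gu = TRUE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
        (a == "G" & b == "C") | (a == "C" & b == "G")
  if (allow_gu) wc | (a == "G" & b == "U") | (a == "U" & b == "G") else wc
}

#' Fold an RNA by nested base-pair maximization
#'
#' Nussinov-style dynamic program: maximizes the number of nested
#' Watson-Crick (plus G:U when allowed) base pairs with hairpin loops of at
#' least `min_loop` unpaired bases. One optimal structure is recovered by a
#' deterministic traceback (3'-most base left unpaired when co-optimal,
#' otherwise paired with its 5'-most co-optimal partner). This is a
#' combinatorial foldability criterion, not a thermodynamic model: it backs
#' the binary hairpin-precursor check, where only the existence of a long
#' uninterrupted stem matters.
#'
#' @param sequence RNA string over \{A,C,G,U\}.
#' @param min_loop minimum hairpin loop size (default 3).
#' @param allow_gu allow G:U wobble pairs (default TRUE).
#' @return list of class `hairpin_result` with `structure` (dot-bracket),
#'   `n_pairs`, `pairs` (2-column matrix of paired positions),
#'   `paired_fraction_mature` = NA, `arm` = NA, `is_hairpin` = NA.
#' @export
nussinov_fold <- function(sequence, min_loop = 3L, allow_gu = TRUE) {
  sequence <- rna_normalize(sequence)
  assert_rna(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < min_loop + 2L)
    stop("sequence shorter than min_loop + 2", call. = FALSE)
  N <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- N[i, j - 1L]                      # j unpaired
      ks <- i:(j - min_loop - 1L)
      ks <- ks[can_pair(ch[ks], ch[j], allow_gu)]
      if (length(ks)) {
        left <- ifelse(ks > i, N[cbind(pmax(i, 1L), pmax(ks - 1L, 1L))], 0L)
        left[ks == i] <- 0L
        inner <- N[cbind(pmin(ks + 1L, n), max(j - 1L, 1L))]
        inner[ks + 1L > j - 1L] <- 0L
        best <- max(best, max(left + inner + 1L))
      }
      N[i, j] <- best
    }
  }
  # deterministic traceback
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (i >= j || j - i < min_loop + 1L) next
    if (N[i, j] == N[i, j - 1L]) { stack[[length(stack) + 1L]] <- c(i, j - 1L); next }
    for (k in i:(j - min_loop - 1L)) {
      if (!can_pair(ch[k], ch[j], allow_gu)) next
      left <- if (k > i) N[i, k - 1L] else 0L
      inner <- if (k + 1L <= j - 1L) N[k + 1L, j - 1L] else 0L
      if (left + inner + 1L == N[i, j]) {
        pairs <- rbind(pairs, c(k, j))
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        break
      }
    }
  }
  db <- rep(".", n)
  if (nrow(pairs)) { db[pairs[, 1]] <- "("; db[pairs[, 2]] <- ")" }
  structure(list(structure = paste(db, collapse = ""),
                 n_pairs = N[1L, n],
                 pairs = pairs,
                 paired_fraction_mature = NA_real_,
                 arm = NA_character_,
                 is_hairpin = NA),
            class = "hairpin_result")
}

#' Hairpin-precursor check for a mature sequence
#'
#' Folds the precursor by base-pair maximization and accepts it as a miRNA
#' hairpin when (i) one dominant stem-loop — the run of pairs nested around a
#' single hairpin loop, walked outward until an unpaired gap on either strand
#' exceeds `max_unpaired_run_in_stem` — carries at least `min_stem_pairs`
#' pairs, (ii) the
#' fraction of paired bases over the mature span is at least
#' `min_paired_fraction_mature`, and (iii) no unpaired run inside the mature
#' span exceeds `max_unpaired_run_in_stem`. The stem walk tolerates bulges of
#' at most `max_stem_bulge` nt: larger internal loops terminate a stem, which
#' is what keeps the check selective — unconstrained base-pair maximization
#' will thread long nested chains through random RNA, but almost never an
#' uninterrupted helix. The mature arm is called 5p or 3p
#' by the side of the dominant loop holding the mature midpoint. Foldability
#' into such a hairpin is the accepted evidence separating miRNAs from
#' siRNAs.
#'
#' @param precursor RNA string containing `mature` verbatim.
#' @param mature mature RNA sequence.
#' @param min_stem_pairs minimum pairs in the dominant stem (default 14).
#' @param min_paired_fraction_mature minimum paired fraction over the mature
#'   span (default 0.6).
#' @param max_unpaired_run_in_stem maximum unpaired run inside the mature
#'   span (default 4).
#' @param max_stem_bulge maximum per-step bulge (nt, on either strand)
#'   tolerated when walking pairs outward from a hairpin loop (default 1).
#' @param min_loop,allow_gu folding parameters, see [nussinov_fold()].
#' @return `hairpin_result` with all fields filled.
#' @export
is_hairpin <- function(precursor, mature, min_stem_pairs = 14L,
                       min_paired_fraction_mature = 0.6,
                       max_unpaired_run_in_stem = 4L,
                       max_stem_bulge = 1L,
                       min_loop = 3L, allow_gu = TRUE) {
  precursor <- rna_normalize(precursor)
  mature <- rna_normalize(mature)
  at <- regexpr(mature, precursor, fixed = TRUE)
  if (at < 0L) stop("mature not found in precursor", call. = FALSE)
  m_start <- as.integer(at)
  m_end <- m_start + nchar(mature) - 1L
  hp <- nussinov_fold(precursor, min_loop = min_loop, allow_gu = allow_gu)
  pairs <- hp$pairs
  n <- nchar(precursor)
  paired <- logical(n)
  if (nrow(pairs)) paired[c(pairs[, 1], pairs[, 2])] <- TRUE
  span <- m_start:m_end
  frac <- mean(paired[span])
  runs <- rle(paired[span])
  max_run <- if (any(!runs$values)) max(runs$lengths[!runs$values]) else 0L
  # hairpin loops: pairs enclosing no other paired base; the stem of a loop
  # is the run of pairs nested around it, walked outward from the closing
  # pair and broken at a bulge larger than max_stem_bulge on either strand
  # (a stem interrupted by an internal loop is not one stem)
  dominant <- 0L; dom_loop <- c(NA_integer_, NA_integer_)
  if (nrow(pairs)) {
    inner <- vapply(seq_len(nrow(pairs)), function(r) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      j - i > 1L && !any(paired[(i + 1L):(j - 1L)])
    }, logical(1))
    loops <- pairs[inner, , drop = FALSE]
    if (nrow(loops)) {
      stem_sizes <- vapply(seq_len(nrow(loops)), function(l) {
        li <- loops[l, 1]; lj <- loops[l, 2]
        enclosing <- pairs[pairs[, 1] <= li & pairs[, 2] >= lj, ,
                           drop = FALSE]
        ord <- order(-enclosing[, 1])  # innermost (the loop pair) first
        enclosing <- enclosing[ord, , drop = FALSE]
        size <- 1L
        for (r in seq_len(nrow(enclosing))[-1]) {
          gap5 <- enclosing[r - 1L, 1] - enclosing[r, 1] - 1L
          gap3 <- enclosing[r, 2] - enclosing[r - 1L, 2] - 1L
          if (max(gap5, gap3) > max_stem_bulge) break
          size <- size + 1L
        }
        size
      }, integer(1))
      d <- which.max(stem_sizes)
      dominant <- stem_sizes[d]
      dom_loop <- loops[d, ]
    }
  }
  m_mid <- (m_start + m_end) / 2
  arm <- if (is.na(dom_loop[1])) "ambiguous"
         else if (m_mid < dom_loop[1]) "5p"
         else if (m_mid > dom_loop[2]) "3p"
         else "ambiguous"
  hp$paired_fraction_mature <- frac
  hp$arm <- arm
  hp$is_hairpin <- dominant >= min_stem_pairs &&
    frac >= min_paired_fraction_mature &&
    max_run <= max_unpaired_run_in_stem
  hp
}
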