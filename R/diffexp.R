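#' Reads-per-million normalization
#'
#' Scales a tag count by its library's retained read total so abundance is
#' comparable across libraries of unequal depth (the two-library design
#' compared here differs by ~40% in depth).
#'
#' @param count non-negative tag count(s).
#' @param total positive library total of retained reads.
#' @return count / total * 1e6.
#' @export
rpm_normalize <- function(count, total) {
  if (any(total <= 0)) stop("library total must be positive", call. = FALSE)
  if (any(count < 0) || any(count > total))
    stop("counts must lie in [0, total]", call. = FALSE)
  count / total * 1e6
}

#' Pseudocounted log2 fold change (library B over A)
#'
#' @param rpm_A,rpm_B reads-per-million in each library.
#' @param pseudocount added to both sides before the ratio (default 1 RPM),
#'   protecting zero counts, which are common among low-abundance tags.
#' @return log2((rpm_B + pseudocount) / (rpm_A + pseudocount)).
#' @export
log2_fold_change <- function(rpm_A, rpm_B, pseudocount = 1.0) {
  stopifnot(pseudocount > 0)
  log2((rpm_B + pseudocount) / (rpm_A + pseudocount))
}

#' Exact conditional binomial test for a two-library count difference
#'
#' Under the null of equal relative abundance, conditional on the tag's
#' combined count n = count_A + count_B, count_B is Binomial(n, p) with
#' p = total_B / (total_A + total_B) — the classic exact comparison for
#' unreplicated tag-count libraries. Two-sided p-value by doubling the
#' smaller tail (capped at 1).
#'
#' @param count_A,count_B integer tag counts (vectorized).
#' @param total_A,total_B positive library totals.
#' @return p-value(s) in [0, 1].
#' @export
count_test <- function(count_A, count_B, total_A, total_B) {
  stopifnot(total_A > 0, total_B > 0)
  n <- count_A + count_B
  p <- total_B / (total_A + total_B)
  lower <- stats::pbinom(count_B, n, p)
  upper <- 1 - stats::pbinom(count_B - 1, n, p)
  out <- pmin(1, 2 * pmin(lower, upper))
  out[n == 0] <- 1
  out
}

#' Two-library differential abundance table
#'
#' RPM normalization, pseudocounted log2 fold change (B over A), the exact
#' conditional binomial test, Benjamini-Hochberg adjustment across all tested
#' tags, and a call: `up`/`down` when q <= alpha and |log2fc| >=
#' `lfc_threshold`, signed by the fold change, else `unchanged`. Tags whose
#' combined count falls below `min_total` are reported but not tested
#' (q = NA): testing singletons is powerless and inflates the correction
#' burden.
#'
#' @param tags tag table with exactly two count columns.
#' @param alpha q-value threshold for a call (default 0.05).
#' @param lfc_threshold minimum |log2fc| for a call (default 1).
#' @param pseudocount RPM pseudocount (default 1).
#' @param min_total minimum combined raw count for testing (default 10).
#' @return data.frame: tag_id, sequence, count_A, count_B, rpm_A, rpm_B,
#'   log2fc, p_value, q_value, status.
#' @export
diffexp_table <- function(tags, alpha = 0.05, lfc_threshold = 1.0,
                          pseudocount = 1.0, min_total = 10L) {
  cc <- count_columns(tags)
  if (length(cc) != 2L)
    stop("diffexp_table requires a two-library tag table", call. = FALSE)
  cA <- tags[[cc[1]]]; cB <- tags[[cc[2]]]
  tA <- sum(cA); tB <- sum(cB)
  if (nrow(tags) == 0L)
    return(data.frame(tag_id = character(0), sequence = character(0),
                      count_A = integer(0), count_B = integer(0),
                      rpm_A = numeric(0), rpm_B = numeric(0),
                      log2fc = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), status = character(0)))
  rA <- rpm_normalize(cA, tA)
  rB <- rpm_normalize(cB, tB)
  lfc <- log2_fold_change(rA, rB, pseudocount)
  pv <- count_test(cA, cB, tA, tB)
  tested <- (cA + cB) >= min_total
  qv <- rep(NA_real_, nrow(tags))
  qv[tested] <- stats::p.adjust(pv[tested], method = "BH")
  status <- rep("unchanged", nrow(tags))
  call_up <- tested & !is.na(qv) & qv <= alpha & lfc >= lfc_threshold
  call_dn <- tested & !is.na(qv) & qv <= alpha & lfc <= -lfc_threshold
  status[call_up] <- "up"
  status[call_dn] <- "down"
  out <- data.frame(tag_id = tags$tag_id, sequence = tags$sequence,
                    count_A = cA, count_B = cB, rpm_A = rA, rpm_B = rB,
                    log2fc = lfc, p_value = pv, q_value = qv,
                    status = status, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
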