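#' Published reference tables for the A. mangium secondary-xylem study
#'
#' Small plain-text tables shipped with the package: the per-library totals
#' of the twelve conserved miRNA families (libraries Am54, low lignin, and
#' Am48, high lignin), the four mature miRNA sequences used as qPCR forward
#' primers, and the printed non-conserved tag counts with their predicted
#' targets. These serve as worked-example inputs and schema contracts; the
#' study's raw reads were never deposited, so no raw-data result is
#' recomputable from them.
#'
#' @return a data.frame (see the individual accessor).
#' @name amg_reference
NULL

amg_extdata <- function(file) {
  p <- system.file("extdata", file, package = "xylomir")
  if (!nzchar(p)) stop("missing extdata file ", file, call. = FALSE)
  utils::read.delim(p, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @describeIn amg_reference per-family totals in Am54/Am48 (columns family,
#'   count_am54, count_am48).
#' @export
amg_family_counts <- function() amg_extdata("amg_family_counts.tsv")

#' @describeIn amg_reference the four validated mature sequences (columns
#'   seq_id, sequence (DNA as printed), family).
#' @export
amg_qpcr_matures <- function() amg_extdata("amg_qpcr_matures.tsv")

#' @describeIn amg_reference printed non-conserved tags with per-library
#'   counts and predicted target descriptions.
#' @export
amg_novel_tags <- function() amg_extdata("amg_novel_tags.tsv")

#' Total retained reads of the two study libraries
#'
#' The published depths: 14,582,383 retained reads in the low-lignin Am54
#' library and 10,281,313 in the high-lignin Am48 library. Used for
#' reads-per-million arithmetic on the printed family counts.
#'
#' @return named numeric vector c(am54 = ..., am48 = ...).
#' @export
amg_library_depths <- function() {
  c(am54 = 14582383, am48 = 10281313)
}
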