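#' Pipeline configuration
#'
#' Collects the inputs and parameters of the end-to-end two-library run:
#' trim -> length filter -> collapse -> annotate -> classify -> compare.
#' Reads may be supplied as file paths (FASTQ/FASTA) or in-memory character
#' vectors; the catalog and contaminant catalog as paths or data.frames.
#'
#' @param reads_A,reads_B read files or character vectors for the two
#'   libraries.
#' @param lib_ids names of the two libraries (default c("A", "B")).
#' @param catalog mature-miRNA catalog: FASTA path or data.frame
#'   (family, mature_sequence).
#' @param ncrna_catalog optional contaminant catalog: FASTA path or
#'   data.frame (name, sequence).
#' @param precursors optional named character vector mapping a tag sequence
#'   to a precursor candidate, enabling the hairpin check for those tags.
#' @param trim a [trim_params()].
#' @param retain_window inclusive insert-length window kept for profiling
#'   (default c(7, 35)).
#' @param annotation_window inclusive length window submitted to annotation
#'   and classification (default c(19, 24)).
#' @param max_mismatch family-membership edit threshold (default 3).
#' @param thresholds a [class_thresholds()].
#' @param alpha,lfc_threshold differential-call parameters (defaults 0.05
#'   and 1).
#' @param seed integer seed recorded in the run metadata.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads_A, reads_B, catalog,
                            lib_ids = c("A", "B"),
                            ncrna_catalog = NULL, precursors = NULL,
                            trim = trim_params("TGGAATTCTCGGGTGCCAAGG"),
                            retain_window = c(7L, 35L),
                            annotation_window = c(19L, 24L),
                            max_mismatch = 3L,
                            thresholds = class_thresholds(),
                            alpha = 0.05, lfc_threshold = 1.0,
                            seed = 1L) {
  stopifnot(retain_window[1] <= retain_window[2],
            annotation_window[1] <= annotation_window[2],
            length(lib_ids) == 2L)
  structure(list(reads_A = reads_A, reads_B = reads_B, lib_ids = lib_ids,
                 catalog = catalog, ncrna_catalog = ncrna_catalog,
                 precursors = precursors, trim = trim,
                 retain_window = retain_window,
                 annotation_window = annotation_window,
                 max_mismatch = as.integer(max_mismatch),
                 thresholds = thresholds, alpha = alpha,
                 lfc_threshold = lfc_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_reads <- function(x) {
  looks_like_path <- is.character(x) && length(x) == 1L &&
    grepl("\\.(fa|fasta|fq|fastq)(\\.gz)?$", x, ignore.case = TRUE)
  if (looks_like_path) read_small_rna(x) else as.character(x)
}

resolve_catalog <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) x else reader(x)
}

#' Run the full two-library pipeline
#'
#' Executes trimming, length selection, collapse into tags, family
#' annotation with isoform grouping, contaminant flagging, classification
#' and differential abundance, and returns a report bundle. Per-stage read
#' counts and rejection reasons are collected so the read funnel is
#' auditable; every retained read is accounted for in exactly one tag and
#' every tag receives exactly one class.
#'
#' @param config a [pipeline_config()].
#' @return list of class `report_bundle`: `tags`, `length_profile`,
#'   `assignments`, `family_summary`, `classification`, `diffexp`, `funnel`
#'   (per-stage counts), `meta` (version, seed, parameter echo).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  raw <- list(resolve_reads(config$reads_A), resolve_reads(config$reads_B))
  names(raw) <- config$lib_ids
  catalog <- resolve_catalog(config$catalog, read_mirna_catalog)
  ncrna <- resolve_catalog(config$ncrna_catalog, function(p) {
    x <- Biostrings::readBStringSet(p)
    data.frame(name = names(x), sequence = as.character(x),
               stringsAsFactors = FALSE)
  })

  funnel <- list()
  retained <- list()
  for (lib in config$lib_ids) {
    tr <- trim_adapter(raw[[lib]], config$trim)
    ok <- tr$status == "ok"
    keep_len <- rep(FALSE, nrow(tr))
    keep_len[ok] <- filter_length(tr$insert[ok],
                                  config$retain_window[1],
                                  config$retain_window[2])
    retained[[lib]] <- tr$insert[ok & keep_len]
    funnel[[lib]] <- data.frame(
      library = lib,
      n_raw = length(raw[[lib]]),
      n_no_adapter = sum(tr$status == "no_adapter"),
      n_empty_insert = sum(tr$status == "empty_insert"),
      n_length_rejected = sum(ok & !keep_len),
      n_retained = sum(ok & keep_len),
      stringsAsFactors = FALSE)
  }
  funnel <- do.call(rbind, funnel)

  tags <- collapse_tags(retained)
  funnel$n_N_rejected <- attr(tags, "n_rejected_N")
  tags <- assign_tag_ids(tags)
  profile <- length_histogram(tags)

  contam <- flag_contaminant(tags, ncrna)
  non_contam <- tags[is.na(contam), , drop = FALSE]
  attr(non_contam, "libraries") <- attr(tags, "libraries")
  assignments <- match_catalog(non_contam, catalog,
                               max_mismatch = config$max_mismatch,
                               window = config$annotation_window)
  assignments <- group_isoforms(assignments, tags)

  hairpins <- NULL
  if (!is.null(config$precursors) && length(config$precursors)) {
    shared <- intersect(tags$sequence, names(config$precursors))
    hairpins <- lapply(stats::setNames(shared, shared), function(s)
      is_hairpin(config$precursors[[s]], s))
  }
  classification <- classify_tags(tags, assignments, contam,
                                  thresholds = config$thresholds,
                                  hairpins = hairpins)
  fam_summary <- summarize_families(assignments, tags)
  de <- diffexp_table(tags, alpha = config$alpha,
                      lfc_threshold = config$lfc_threshold)

  structure(list(
    tags = tags, length_profile = profile, assignments = assignments,
    family_summary = fam_summary, classification = classification,
    diffexp = de, funnel = funnel,
    meta = list(package = "xylomir",
                version = as.character(utils::packageVersion("xylomir")),
                seed = config$seed,
                lib_ids = config$lib_ids,
                retain_window = config$retain_window,
                annotation_window = config$annotation_window,
                max_mismatch = config$max_mismatch,
                alpha = config$alpha,
                lfc_threshold = config$lfc_threshold)),
    class = "report_bundle")
}

#' Per-family count summary
#'
#' One row per assigned family with per-library totals equal to the sum of
#' the member tags' counts, plus the number of distinct isoforms — the shape
#' of a conserved-family count table.
#'
#' @param assignments output of [group_isoforms()] (or [match_catalog()]).
#' @param tags the tag table.
#' @return data.frame: family, n_isoforms, one `count_<lib>` column per
#'   library.
#' @export
summarize_families <- function(assignments, tags) {
  cc <- count_columns(tags)
  if (is.null(assignments) || nrow(assignments) == 0L) {
    out <- data.frame(family = character(0), n_isoforms = integer(0))
    for (col in cc) out[[col]] <- integer(0)
    return(out)
  }
  fams <- sort(unique(assignments$family))
  rows <- lapply(fams, function(fam) {
    ids <- assignments$tag_id[assignments$family == fam]
    m <- match(ids, tags$tag_id)
    r <- data.frame(family = fam, n_isoforms = length(unique(
      assignments$sequence[assignments$family == fam])),
      stringsAsFactors = FALSE)
    for (col in cc) r[[col]] <- as.integer(sum(tags[[col]][m]))
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a report bundle to a directory of TSV files plus JSON metadata
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tbl <- c("tags", "length_profile", "assignments", "family_summary",
           "classification", "diffexp", "funnel")
  paths <- character(0)
  for (nm in tbl) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    df <- bundle[[nm]]
    if (nm == "tags") df$tag_id <- as.character(df$tag_id)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "metadata.json")
  jsonlite::write_json(bundle$meta, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, mp))
}
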