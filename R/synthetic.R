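#' Configuration for the two-library synthetic small-RNA generator
#'
#' The generator emulates the statistical structure of a pair of deeply
#' sequenced secondary-xylem small-RNA libraries: a bimodal insert-length
#' mixture with peaks at 21 and 24 nt and ~80% of reads at 24 nt, a dozen
#' conserved miRNA families each with isomiR variants within a few edits of
#' the mature sequence, a handful of abundant novel hairpin-derived miRNA
#' loci, a large low-count siRNA background, non-coding-RNA fragments, and a
#' 3' sequencing adapter appended to every insert. Expected per-species counts
#' are specified at `reference_depth` and scaled linearly to
#' `n_reads_per_library`; realized counts are drawn Poisson so downstream
#' count statistics see genuine sampling noise.
#'
#' @param n_reads_per_library target depth per library (default 2e5).
#' @param frac_len24 fraction of inserts at 24 nt (default 0.80).
#' @param length_mixture named probability vector over insert lengths; the
#'   default places `frac_len24` at 24 nt with a secondary peak at 21 nt
#'   (lengths 19-24). Must sum to 1.
#' @param n_conserved_families number of conserved miRNA families (default 12).
#' @param isoforms_per_family isomiR variants planted per family, including
#'   the mature itself (default 3).
#' @param max_isoform_edits maximum edits of an isoform from its mature
#'   (default 3).
#' @param n_novel_loci number of novel hairpin-derived loci (default 6).
#' @param novel_min_count minimum expected count of a novel locus at reference
#'   depth (default 1000); loci draw expectations in
#'   `novel_min_count * c(1.5, 6)`.
#' @param n_sirna_background number of background siRNA-like species, or NULL
#'   (default) to auto-fill the depth left after the planted classes.
#' @param sirna_count_range range of expected background counts at reference
#'   depth (default c(1, 80), keeping Poisson realizations below the 100-count
#'   siRNA ceiling).
#' @param contaminant_frac fraction of reads that are ncRNA fragments
#'   (default 0.02).
#' @param adapter_sequence 3' adapter appended to every insert (default the
#'   standard Illumina small-RNA 3' adapter).
#' @param fold_changes optional named vector mapping locus names (family names
#'   or "novel-###") to library-B/library-A abundance ratios; NULL (default)
#'   assigns reciprocal mass-balanced pairs (conserved ratios up to 3, novel
#'   ratios up to 8) so both libraries keep the same expected depth and
#'   length mixture.
#' @param conserved_count_range range of expected family base counts at
#'   reference depth (default c(300, 1500), log-uniform).
#' @param reference_depth depth at which expected counts are stated
#'   (default 2e5).
#' @param seed integer seed; fixed seed gives byte-identical libraries.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_reads_per_library = 200000L,
                             frac_len24 = 0.80,
                             length_mixture = NULL,
                             n_conserved_families = 12L,
                             isoforms_per_family = 3L,
                             max_isoform_edits = 3L,
                             n_novel_loci = 6L,
                             novel_min_count = 1000,
                             n_sirna_background = NULL,
                             sirna_count_range = c(1, 80),
                             contaminant_frac = 0.02,
                             adapter_sequence = "TGGAATTCTCGGGTGCCAAGG",
                             fold_changes = NULL,
                             conserved_count_range = c(300, 1500),
                             reference_depth = 200000,
                             seed = 1L) {
  if (is.null(length_mixture)) {
    stopifnot(frac_len24 >= 0, frac_len24 <= 1)
    rest <- 1 - frac_len24
    # secondary peak at 21 nt; shoulders at 19/20/22/23
    w <- c(`19` = 0.05, `20` = 0.10, `21` = 0.50, `22` = 0.15, `23` = 0.20)
    length_mixture <- c(w * rest, `24` = frac_len24)
  } else {
    if (is.null(names(length_mixture)))
      stop("length_mixture must be named by insert length", call. = FALSE)
    frac_len24 <- unname(length_mixture[["24"]] %||% 0)
  }
  if (abs(sum(length_mixture) - 1) > 1e-9)
    stop("length_mixture probabilities must sum to 1", call. = FALSE)
  stopifnot(n_reads_per_library >= 0,
            max_isoform_edits >= 0,
            isoforms_per_family >= 1,
            n_conserved_families >= 0, n_novel_loci >= 0,
            length(sirna_count_range) == 2,
            sirna_count_range[1] >= 0,
            diff(sirna_count_range) >= 0,
            contaminant_frac >= 0, contaminant_frac < 1,
            nchar(adapter_sequence) > 0,
            reference_depth > 0)
  structure(list(
    n_reads_per_library = n_reads_per_library,
    frac_len24 = frac_len24,
    length_mixture = length_mixture,
    n_conserved_families = as.integer(n_conserved_families),
    isoforms_per_family = as.integer(isoforms_per_family),
    max_isoform_edits = as.integer(max_isoform_edits),
    n_novel_loci = as.integer(n_novel_loci),
    novel_min_count = novel_min_count,
    n_sirna_background = n_sirna_background,
    sirna_count_range = sirna_count_range,
    contaminant_frac = contaminant_frac,
    adapter_sequence = toupper(adapter_sequence),
    fold_changes = fold_changes,
    conserved_count_range = conserved_count_range,
    reference_depth = reference_depth,
    seed = as.integer(seed)
  ), class = "generator_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## The twelve conserved family names of the reference study, used verbatim
## when a 12-family catalog is generated.
AMG_FAMILY_NAMES <- c("amg-miR159", "amg-miR156", "amg-miR166", "amg-miR164",
                      "amg-miR168", "amg-miR172", "amg-miR394", "amg-miR396",
                      "amg-miR160", "amg-miR167", "amg-miR162", "amg-miR403")

#' Generate a mature-miRNA reference catalog
#'
#' Draws `n_families` random mature sequences with pairwise edit distance
#' strictly greater than `min_separation - 1`, regenerating colliding entries.
#' With 12 families the entries carry the twelve conserved family names of the
#' reference study; otherwise families are named `fam-001`, `fam-002`, ...
#'
#' @param n_families number of families (>= 1).
#' @param length_range c(min, max) mature length in nt, within 19-24.
#' @param seed integer seed.
#' @param min_separation minimum pairwise edit distance between entries
#'   (default 4, i.e. strictly more than the 3-edit isoform threshold).
#' @param max_tries regeneration attempts per entry before failing.
#' @return data.frame with columns family, mature_sequence, source.
#' @export
generate_reference_catalog <- function(n_families, length_range = c(21L, 21L),
                                       seed = 1L, min_separation = 4L,
                                       max_tries = 200L) {
  stopifnot(n_families >= 1, length_range[1] >= 19, length_range[2] <= 24,
            length_range[1] <= length_range[2])
  with_seed(seed, {
    seqs <- character(0)
    for (i in seq_len(n_families)) {
      ok <- FALSE
      lens <- length_range[1]:length_range[2]
      for (t in seq_len(max_tries)) {
        cand <- random_rna(if (length(lens) == 1L) lens else sample(lens, 1))
        if (length(seqs) == 0L ||
            all(vapply(seqs, edit_distance_bounded, integer(1),
                       b = cand, k = min_separation - 1L) >= min_separation)) {
          seqs <- c(seqs, cand); ok <- TRUE; break
        }
      }
      if (!ok)
        stop("could not generate ", n_families, " families with pairwise ",
             "distance >= ", min_separation, " at lengths ",
             length_range[1], "-", length_range[2], call. = FALSE)
    }
    fams <- if (n_families == 12L) AMG_FAMILY_NAMES
            else sprintf("fam-%03d", seq_len(n_families))
    data.frame(family = fams, mature_sequence = seqs,
               source = "synthetic", stringsAsFactors = FALSE)
  })
}

#' Generate isomiR variants of a mature sequence
#'
#' Returns `k` distinct sequences each within `max_edits` of `mature`
#' (unit-cost substitutions, insertions, deletions), with lengths clamped to
#' 19-24 nt. The first variant is the mature sequence itself.
#'
#' @param mature mature RNA sequence (19-24 nt).
#' @param k number of variants to return (>= 1).
#' @param max_edits maximum edit distance from the mature.
#' @param seed integer seed.
#' @param avoid optional character vector of sequences the variants must stay
#'   more than `max_edits` edits away from (other families' matures).
#' @return character vector of k distinct RNA sequences.
#' @export
generate_isoform_set <- function(mature, k, max_edits = 3L, seed = 1L,
                                 avoid = character(0)) {
  stopifnot(k >= 1, max_edits >= 0)
  mature <- rna_normalize(mature)
  if (max_edits == 0L && k > 1L)
    stop("only one distinct sequence exists within 0 edits", call. = FALSE)
  with_seed(seed, {
    out <- mature
    tries <- 0L
    while (length(out) < k) {
      tries <- tries + 1L
      if (tries > 500L * k)
        stop("cannot construct ", k, " distinct variants within ",
             max_edits, " edits", call. = FALSE)
      cand <- mutate_sequence(mature, sample.int(max_edits, 1))
      L <- nchar(cand)
      if (L < 19L || L > 24L) next
      if (cand %in% out) next
      if (edit_distance_bounded(cand, mature, max_edits) > max_edits) next
      if (length(avoid) &&
          any(vapply(avoid, edit_distance_bounded, integer(1),
                     b = cand, k = max_edits) <= max_edits)) next
      out <- c(out, cand)
    }
    out
  })
}

## Apply n random edits (substitution 70%, insertion 15%, deletion 15%).
mutate_sequence <- function(x, n_edits) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  for (e in seq_len(n_edits)) {
    op <- sample(c("sub", "ins", "del"), 1, prob = c(0.7, 0.15, 0.15))
    pos <- sample.int(length(ch), 1)
    if (op == "sub") {
      ch[pos] <- sample(setdiff(RNA_BASES, ch[pos]), 1)
    } else if (op == "ins") {
      ch <- append(ch, sample(RNA_BASES, 1), after = pos)
    } else if (length(ch) > 1L) {
      ch <- ch[-pos]
    }
  }
  paste(ch, collapse = "")
}

#' Build a hairpin precursor around a mature sequence
#'
#' Constructs mature + loop + reverse complement (5p arm) or reverse
#' complement + loop + mature (3p arm), with up to two planted G:U wobbles in
#' the complementary arm. The loop is drawn from \{A, C\} so it cannot pair
#' internally. The construction is verified with [is_hairpin()] under default
#' criteria and re-drawn if the check fails.
#'
#' @param mature mature RNA sequence, 19-24 nt.
#' @param arm "5p" or "3p": which arm carries the mature sequence.
#' @param loop_len loop length in nt (>= 3, default 6).
#' @param seed integer seed.
#' @return precursor RNA string containing `mature` verbatim.
#' @export
generate_hairpin_precursor <- function(mature, arm = c("5p", "3p"),
                                       loop_len = 6L, seed = 1L) {
  arm <- match.arg(arm)
  mature <- rna_normalize(mature)
  assert_rna(mature, "mature")
  L <- nchar(mature)
  stopifnot(L >= 19, L <= 24, loop_len >= 3)
  with_seed(seed, {
    for (attempt in 1:25) {
      loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE),
                    collapse = "")
      comp <- strsplit(revcomp_rna(mature), "", fixed = TRUE)[[1]]
      n_wob <- if (attempt < 20) sample(0:2, 1) else 0L
      if (n_wob > 0) {
        mch <- strsplit(mature, "", fixed = TRUE)[[1]]
        elig <- which(mch %in% c("G", "U"))
        if (length(elig)) {
          pos <- sample(elig, min(n_wob, length(elig)))
          for (p in pos)  # partner of mature position p sits at L - p + 1
            comp[L - p + 1L] <- if (mch[p] == "G") "U" else "G"
        }
      }
      comp <- paste(comp, collapse = "")
      pre <- if (arm == "5p") paste0(mature, loop, comp)
             else paste0(comp, loop, mature)
      hp <- is_hairpin(pre, mature)
      if (hp$is_hairpin) return(pre)
    }
    stop("failed to construct a folding hairpin precursor", call. = FALSE)
  })
}

#' Random background sequences kept away from a catalog
#'
#' Draws uniform random RNA sequences of the given lengths, rejecting any
#' within `max_edits` edits of a catalog entry or colliding with `exclude`,
#' so background species can never be annotated as conserved miRNAs.
#'
#' @param n number of sequences.
#' @param lengths integer vector (recycled) of sequence lengths.
#' @param catalog reference catalog data.frame (or NULL).
#' @param max_edits rejection radius around catalog entries (default 3).
#' @param exclude sequences that must not be duplicated.
#' @param seed integer seed.
#' @return character vector of n distinct RNA sequences.
#' @export
random_background_sequences <- function(n, lengths, catalog = NULL,
                                        max_edits = 3L,
                                        exclude = character(0), seed = NULL) {
  lengths <- rep_len(lengths, max(n, 1L))
  refs <- if (is.null(catalog)) character(0) else catalog$mature_sequence
  with_seed(seed, {
    out <- character(0)
    taken <- c(exclude)
    i <- 1L
    guard <- 0L
    while (length(out) < n) {
      guard <- guard + 1L
      if (guard > 50L * n + 100L)
        stop("rejection sampling failed to find background sequences",
             call. = FALSE)
      cand <- random_rna(lengths[i])
      if (cand %in% taken) next
      if (length(refs) &&
          any(vapply(refs, edit_distance_bounded, integer(1),
                     b = cand, k = max_edits) <= max_edits)) next
      out <- c(out, cand); taken <- c(taken, cand); i <- i + 1L
    }
    out
  })
}

#' Generate a small synthetic catalog of abundant non-coding RNAs
#'
#' Random rRNA/tRNA/snRNA-like sequences used as the source of contaminant
#' fragments. Labelled synthetic: these are placeholders with the role, not
#' the sequence, of real ncRNAs.
#'
#' @param seed integer seed.
#' @param lengths lengths of the three entries.
#' @return data.frame with columns name, sequence.
#' @export
generate_ncrna_catalog <- function(seed = 1L, lengths = c(260L, 180L, 150L)) {
  with_seed(seed, {
    data.frame(name = c("synthetic-rRNA-1", "synthetic-tRNA-1",
                        "synthetic-snRNA-1")[seq_along(lengths)],
               sequence = random_rna(lengths), stringsAsFactors = FALSE)
  })
}

## Reciprocal mass-balanced fold-change assignment: loci are paired, the pair
## gets base counts (c, r*c) and ratios (r, 1/r), so each pair contributes
## equal expected mass to both libraries and neither library's depth or
## length mixture drifts. `base` holds one draw per locus; the second member
## of each pair reuses the first member's draw scaled by r.
balanced_fold_pairs <- function(n, ratios, base) {
  ratio <- rep(1, n)
  n_pairs <- n %/% 2L
  for (p in seq_len(n_pairs)) {
    r <- ratios[((p - 1L) %% length(ratios)) + 1L]
    i <- 2L * p - 1L; j <- 2L * p
    ratio[i] <- r; ratio[j] <- 1 / r
    base[j] <- base[i] * r
  }
  list(ratio = ratio, base = base)
}

#' Generate a synthetic two-library read pair with ground truth
#'
#' Plants conserved families (with isomiRs), novel hairpin loci, ncRNA
#' fragments and a low-count siRNA background; appends the 3' adapter to every
#' insert; realizes per-library counts as Poisson draws around the planted
#' expectations (library B scaled by the locus fold change); and returns the
#' reads together with a truth table for recovery testing. Background species
#' lengths are apportioned so the pooled insert-length distribution matches
#' the configured mixture in expectation.
#'
#' @param config a [generator_config()].
#' @param catalog a reference catalog (see [generate_reference_catalog()]);
#'   NULL generates one from the config.
#' @return list with elements `reads_A`, `reads_B` (character vectors of
#'   DNA-alphabet reads, insert + adapter), `truth` (data.frame: sequence,
#'   true_class, true_family, true_isoform_of, planted_count_A,
#'   planted_count_B, precursor), `catalog`, `ncrna_catalog`, and `config`.
#' @export
generate_library_pair <- function(config = generator_config(),
                                  catalog = NULL) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  if (is.null(catalog) && cfg$n_conserved_families > 0)
    catalog <- generate_reference_catalog(cfg$n_conserved_families,
                                          seed = cfg$seed + 1L)
  if (cfg$n_conserved_families > 0 && is.null(catalog))
    stop("catalog required when n_conserved_families > 0", call. = FALSE)

  n_reads <- cfg$n_reads_per_library
  scale <- n_reads / cfg$reference_depth
  mix_len <- as.integer(names(cfg$length_mixture))
  mix_p <- as.numeric(cfg$length_mixture)

  with_seed(cfg$seed, {
    truth <- list()
    add_truth <- function(sequence, true_class, true_family = NA_character_,
                          true_isoform_of = NA_character_, cA, cB,
                          precursor = NA_character_) {
      truth[[length(truth) + 1L]] <<- data.frame(
        sequence = sequence, true_class = true_class,
        true_family = true_family, true_isoform_of = true_isoform_of,
        planted_count_A = cA, planted_count_B = cB,
        precursor = precursor, stringsAsFactors = FALSE)
    }

    ## --- conserved families -------------------------------------------------
    if (cfg$n_conserved_families > 0) {
      ccr <- cfg$conserved_count_range
      fc_cons <- balanced_fold_pairs(
        cfg$n_conserved_families, c(3, 2, 1.5, 2.5),
        exp(stats::runif(cfg$n_conserved_families, log(ccr[1]), log(ccr[2]))))
      base <- fc_cons$base
      user_fc <- cfg$fold_changes
      for (f in seq_len(cfg$n_conserved_families)) {
        fam <- catalog$family[f]
        mature <- rna_normalize(catalog$mature_sequence[f])
        r <- if (!is.null(user_fc) && fam %in% names(user_fc))
          unname(user_fc[[fam]]) else fc_cons$ratio[f]
        isos <- generate_isoform_set(
          mature, cfg$isoforms_per_family, cfg$max_isoform_edits,
          seed = sample.int(2^30, 1),
          avoid = catalog$mature_sequence[-f])
        # the canonical mature carries most of the family mass
        w <- if (length(isos) == 1L) 1 else
          c(0.7, rep(0.3 / (length(isos) - 1L), length(isos) - 1L))
        for (i in seq_along(isos)) {
          cA <- round(base[f] * w[i] * scale)
          add_truth(isos[i], "conserved_miRNA", true_family = fam,
                    true_isoform_of = mature,
                    cA = cA, cB = round(cA * r))
        }
      }
    }

    ## --- novel hairpin loci -------------------------------------------------
    if (cfg$n_novel_loci > 0) {
      fc_nov <- balanced_fold_pairs(
        cfg$n_novel_loci, c(8, 4, 2),
        exp(stats::runif(cfg$n_novel_loci,
                         log(1.5 * cfg$novel_min_count),
                         log(6 * cfg$novel_min_count))))
      planted_so_far <- vapply(truth, function(d) d$sequence, character(1))
      novel_seqs <- random_background_sequences(
        cfg$n_novel_loci, lengths = 24L, catalog = catalog,
        max_edits = cfg$max_isoform_edits, exclude = planted_so_far)
      nb <- fc_nov$base
      user_fc <- cfg$fold_changes
      for (v in seq_len(cfg$n_novel_loci)) {
        nm <- sprintf("novel-%03d", v)
        r <- if (!is.null(user_fc) && nm %in% names(user_fc))
          unname(user_fc[[nm]]) else fc_nov$ratio[v]
        pre <- generate_hairpin_precursor(novel_seqs[v],
                                          arm = sample(c("5p", "3p"), 1),
                                          seed = sample.int(2^30, 1))
        cA <- round(nb[v] * scale)
        add_truth(novel_seqs[v], "putative_novel_miRNA",
                  cA = cA, cB = round(cA * r), precursor = pre)
      }
    }

    ## --- ncRNA fragments ----------------------------------------------------
    ncrna <- generate_ncrna_catalog(seed = sample.int(2^30, 1))
    if (cfg$contaminant_frac > 0) {
      n_frag_species <- 20L
      frag_mass <- cfg$contaminant_frac * n_reads
      planted_so_far <- vapply(truth, function(d) d$sequence, character(1))
      frags <- character(0)
      guard <- 0L
      while (length(frags) < n_frag_species && guard < 500L) {
        guard <- guard + 1L
        src <- sample.int(nrow(ncrna), 1)
        L <- sample(mix_len, 1, prob = mix_p)
        maxs <- nchar(ncrna$sequence[src]) - L + 1L
        if (maxs < 1L) next
        st <- sample.int(maxs, 1)
        fr <- substr(ncrna$sequence[src], st, st + L - 1L)
        if (fr %in% c(frags, planted_so_far)) next
        frags <- c(frags, fr)
      }
      per <- frag_mass / length(frags)
      for (fr in frags)
        add_truth(fr, "ncRNA_fragment", cA = round(per), cB = round(per))
    }

    ## --- siRNA background fills the residual length mass --------------------
    truth_df <- do.call(rbind, truth)
    if (is.null(truth_df))
      truth_df <- data.frame(sequence = character(0),
                             true_class = character(0),
                             true_family = character(0),
                             true_isoform_of = character(0),
                             planted_count_A = numeric(0),
                             planted_count_B = numeric(0),
                             precursor = character(0),
                             stringsAsFactors = FALSE)
    if (n_reads > 0) {
      planted_len <- nchar(truth_df$sequence)
      planted_mass <- (truth_df$planted_count_A + truth_df$planted_count_B) / 2
      target <- mix_p * n_reads
      got <- vapply(mix_len, function(L)
        sum(planted_mass[planted_len == L]), numeric(1))
      residual <- pmax(target - got, 0)
      mean_cnt <- mean(cfg$sirna_count_range) * scale
      n_bg <- cfg$n_sirna_background %||%
        max(0L, as.integer(round(sum(residual) / max(mean_cnt, 1e-9))))
      if (n_bg > 0) {
        cnt <- stats::runif(n_bg, cfg$sirna_count_range[1] * scale,
                            cfg$sirna_count_range[2] * scale)
        # greedy apportionment: give each species the length with the largest
        # remaining *relative* deficit, so per-length expected mass tracks the
        # residual proportionally and the mixture fractions stay exact even
        # when the drawn counts do not sum exactly to the residual
        deficit <- residual
        lens <- integer(n_bg)
        for (i in order(cnt, decreasing = TRUE)) {
          rel <- ifelse(residual > 0, deficit / residual, -Inf)
          j <- which.max(rel)
          lens[i] <- mix_len[j]
          deficit[j] <- deficit[j] - cnt[i]
        }
        bg_seqs <- random_background_sequences(
          n_bg, lengths = lens, catalog = catalog,
          max_edits = cfg$max_isoform_edits,
          exclude = truth_df$sequence)
        bg <- data.frame(sequence = bg_seqs, true_class = "siRNA_like",
                         true_family = NA_character_,
                         true_isoform_of = NA_character_,
                         planted_count_A = round(cnt),
                         planted_count_B = round(cnt),
                         precursor = NA_character_, stringsAsFactors = FALSE)
        truth_df <- rbind(truth_df, bg)
      }
    }
    truth_df$planted_count_A <- as.integer(truth_df$planted_count_A)
    truth_df$planted_count_B <- as.integer(truth_df$planted_count_B)

    ## --- realize reads ------------------------------------------------------
    adapter <- chartr("U", "T", cfg$adapter_sequence)
    realize <- function(expected) {
      k <- stats::rpois(length(expected), expected)
      reads <- rep(chartr("U", "T", truth_df$sequence), k)
      if (length(reads)) reads <- paste0(reads, adapter)
      if (length(reads) > 1L) reads <- sample(reads)
      reads
    }
    reads_A <- realize(truth_df$planted_count_A)
    reads_B <- realize(truth_df$planted_count_B)

    list(reads_A = reads_A, reads_B = reads_B, truth = truth_df,
         catalog = catalog, ncrna_catalog = ncrna, config = cfg)
  })
}

#' Write a generated library pair to FASTQ plus truth and config files
#'
#' @param pair result of [generate_library_pair()].
#' @param dir output directory (created if needed).
#' @param lib_ids names of the two libraries (default c("A", "B")).
#' @return invisibly, the paths written.
#' @export
write_library_pair <- function(pair, dir, lib_ids = c("A", "B")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    A = file.path(dir, paste0("lib_", lib_ids[1], ".fastq")),
    B = file.path(dir, paste0("lib_", lib_ids[2], ".fastq")),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml"))
  write_fastq(pair$reads_A, paths[["A"]], prefix = lib_ids[1])
  write_fastq(pair$reads_B, paths[["B"]], prefix = lib_ids[2])
  utils::write.table(pair$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- pair$config
  cfg$length_mixture <- as.list(cfg$length_mixture)
  yaml::write_yaml(unclass(cfg), paths[["config"]])
  invisible(paths)
}

## FASTQ writer over Biostrings; constant high qualities, as the pipeline
## performs no quality filtering.
write_fastq <- function(reads, path, prefix = "read") {
  ids <- sprintf("%s_%07d", prefix, seq_along(reads))
  x <- Biostrings::BStringSet(reads)
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Score predicted classifications against generator truth
#'
#' @param predicted data.frame with columns `sequence`, `label` and optionally
#'   `family`; sequences absent from `predicted` count as recall misses.
#' @param truth generator truth table (one row per planted species).
#' @param diffexp optional data.frame with columns `sequence` and `log2fc`
#'   for fold-change recovery.
#' @param min_planted minimum planted per-library count for a species to enter
#'   the fold-change RMSE (default 50).
#' @return list with `per_class` (data.frame: class, n_truth, precision,
#'   recall), `family_accuracy`, and `fold_change_rmse` (NA when `diffexp`
#'   is not supplied).
#' @export
compare_truth <- function(predicted, truth, diffexp = NULL,
                          min_planted = 50) {
  if (anyDuplicated(truth$sequence))
    stop("duplicate sequences in truth", call. = FALSE)
  pred_label <- predicted$label[match(truth$sequence, predicted$sequence)]
  classes <- sort(unique(c(truth$true_class, predicted$label)))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    n_truth <- sum(truth$true_class == cl)
    n_pred <- sum(predicted$label == cl, na.rm = TRUE)
    tp <- sum(!is.na(pred_label) & pred_label == cl & truth$true_class == cl)
    data.frame(class = cl, n_truth = n_truth, n_pred = n_pred,
               precision = if (n_pred > 0) tp / n_pred else NA_real_,
               recall = if (n_truth > 0) tp / n_truth else NA_real_,
               stringsAsFactors = FALSE)
  }))
  fam_acc <- NA_real_
  is_cons <- truth$true_class == "conserved_miRNA"
  if (any(is_cons) && "family" %in% names(predicted)) {
    pred_fam <- predicted$family[match(truth$sequence[is_cons],
                                       predicted$sequence)]
    fam_acc <- mean(!is.na(pred_fam) & pred_fam == truth$true_family[is_cons])
  }
  fc_rmse <- NA_real_
  if (!is.null(diffexp)) {
    keep <- pmin(truth$planted_count_A, truth$planted_count_B) >= min_planted
    if (any(keep)) {
      est <- diffexp$log2fc[match(truth$sequence[keep], diffexp$sequence)]
      planted <- log2(truth$planted_count_B[keep] /
                        truth$planted_count_A[keep])
      ok <- !is.na(est)
      fc_rmse <- sqrt(mean((est[ok] - planted[ok])^2))
    }
  }
  list(per_class = per_class, family_accuracy = fam_acc,
       fold_change_rmse = fc_rmse)
}
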