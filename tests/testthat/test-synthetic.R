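test_that("reference catalogs are well separated and deterministically named", {
  cat12 <- generate_reference_catalog(12, c(21, 21), seed = 7)
  expect_identical(nrow(cat12), 12L)
  expect_true(all(nchar(cat12$mature_sequence) == 21L))
  expect_identical(cat12$family[1], "amg-miR159")
  expect_identical(cat12$family[12], "amg-miR403")
  d <- utils::combn(cat12$mature_sequence, 2,
                    function(p) edit_distance(p[1], p[2]))
  expect_true(all(d > 3))

  cat1 <- generate_reference_catalog(1, c(21, 21), seed = 1)
  expect_identical(nrow(cat1), 1L)
  expect_identical(nchar(cat1$mature_sequence), 21L)
  expect_identical(cat1$family, "fam-001")

  # oracle check of the separation guarantee on a tiny catalog
  cat2 <- generate_reference_catalog(2, c(21, 21), seed = 3)
  a <- substr(cat2$mature_sequence[1], 1, 8)
  b <- substr(cat2$mature_sequence[2], 1, 8)
  expect_identical(edit_distance(cat2$mature_sequence[1],
                                 cat2$mature_sequence[2]),
                   as.integer(adist(cat2$mature_sequence[1],
                                    cat2$mature_sequence[2])))
  expect_gt(edit_distance(cat2$mature_sequence[1],
                          cat2$mature_sequence[2]), 3L)
  expect_identical(edit_distance(a, b), as.integer(oracle_levenshtein(a, b)))

  # unattainable separation fails explicitly rather than looping forever
  expect_error(generate_reference_catalog(50, c(19, 19), seed = 1,
                                          min_separation = 16L,
                                          max_tries = 3),
               "pairwise")
})

test_that("isoform sets stay within the edit radius and respect k", {
  m <- "UUGGCAUUCUGUCCACCUCCC"
  expect_identical(generate_isoform_set(m, 1, 0, seed = 5), m)
  iso <- generate_isoform_set(m, 2, 3, seed = 5)
  expect_identical(length(iso), 2L)
  for (s in iso) expect_lte(edit_distance(s, m), 3L)
  # cross-check the radius with utils::adist as an independent distance
  expect_true(all(drop(adist(iso, m)) <= 3))

  # eleven distinct variants of one mature, as large isomiR families show
  iso11 <- generate_isoform_set(m, 11, 3, seed = 9)
  expect_identical(length(unique(iso11)), 11L)
  expect_true(all(vapply(iso11, edit_distance, integer(1), b = m) <= 3L))
  expect_true(all(nchar(iso11) >= 19 & nchar(iso11) <= 24))

  expect_error(generate_isoform_set(m, 5, 0, seed = 1), "distinct")
})

test_that("hairpin precursors contain the mature on the requested arm and fold", {
  m <- "GGGAAACCCUUUGGGAAACCC"
  pre5 <- generate_hairpin_precursor(m, "5p", 6, seed = 2)
  expect_true(grepl(m, pre5, fixed = TRUE))
  hp5 <- is_hairpin(pre5, m)
  expect_true(hp5$is_hairpin)
  expect_identical(hp5$arm, "5p")
  expect_gte(hp5$paired_fraction_mature, 0.75)

  pre3 <- generate_hairpin_precursor(m, "3p", 3, seed = 4)
  expect_true(grepl(m, pre3, fixed = TRUE))
  expect_identical(is_hairpin(pre3, m)$arm, "3p")
})

test_that("library pairs are deterministic, conserved and truth-complete", {
  cfg <- generator_config(n_reads_per_library = 2000, seed = 21)
  p1 <- generate_library_pair(cfg)
  p2 <- generate_library_pair(cfg)
  expect_identical(p1$reads_A, p2$reads_A)
  expect_identical(p1$reads_B, p2$reads_B)
  expect_identical(p1$truth, p2$truth)

  # an empty configuration produces empty, well-formed output
  cfg0 <- generator_config(n_reads_per_library = 0, n_conserved_families = 0,
                           n_novel_loci = 0, contaminant_frac = 0, seed = 1)
  p0 <- generate_library_pair(cfg0)
  expect_identical(length(p0$reads_A), 0L)
  expect_identical(nrow(p0$truth), 0L)

  # byte-identical files on re-write
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_library_pair(p1, d1); f2 <- write_library_pair(p1, d2)
  expect_identical(readLines(f1[["A"]]), readLines(f2[["A"]]))
  expect_identical(readLines(f1[["truth"]]), readLines(f2[["truth"]]))

  # every read carries the adapter appended to a truth insert
  expect_true(all(grepl(paste0(cfg$adapter_sequence, "$"), p1$reads_A)))
  ins <- sub(paste0(cfg$adapter_sequence, "$"), "", p1$reads_A)
  expect_true(all(rna_normalize(ins) %in% p1$truth$sequence))

  # no duplicate species in truth
  expect_identical(anyDuplicated(p1$truth$sequence), 0L)
})

test_that("planted classes obey the generator's separation guarantees", {
  cfg <- generator_config(n_reads_per_library = 20000, seed = 33)
  pair <- generate_library_pair(cfg)
  tr <- pair$truth
  refs <- pair$catalog$mature_sequence

  cons <- tr[tr$true_class == "conserved_miRNA", ]
  expect_true(all(!is.na(cons$true_family)))
  d_own <- mapply(function(s, f) edit_distance(s,
      refs[match(f, pair$catalog$family)]), cons$sequence, cons$true_family)
  expect_true(all(d_own <= cfg$max_isoform_edits))

  other <- tr[tr$true_class %in% c("siRNA_like", "putative_novel_miRNA"), ]
  dmin <- vapply(other$sequence, function(s)
    min(vapply(refs, function(r)
      xylomir:::edit_distance_bounded(s, r, 3L), integer(1))), integer(1))
  expect_true(all(dmin > 3L))

  # non-conserved truth has no family; only novel loci carry precursors
  expect_true(all(is.na(other$true_family)))
  nov <- tr[tr$true_class == "putative_novel_miRNA", ]
  expect_true(all(!is.na(nov$precursor)))
  expect_true(all(is.na(tr$precursor[tr$true_class != "putative_novel_miRNA"])))
  for (i in seq_len(nrow(nov)))
    expect_true(is_hairpin(nov$precursor[i], nov$sequence[i])$is_hairpin)

  # siRNA background planted below the 100-count ceiling
  bg <- tr[tr$true_class == "siRNA_like", ]
  expect_true(all(pmax(bg$planted_count_A, bg$planted_count_B) < 100 *
                    cfg$n_reads_per_library / cfg$reference_depth))
})

test_that("read counts are conserved between truth realization and emitted reads", {
  cfg <- generator_config(n_reads_per_library = 5000, seed = 12)
  pair <- generate_library_pair(cfg)
  ins_A <- rna_normalize(sub(paste0(cfg$adapter_sequence, "$"), "",
                             pair$reads_A))
  tab <- table(ins_A)
  expect_identical(sum(tab), length(pair$reads_A))
  expect_true(all(names(tab) %in% pair$truth$sequence))
})

test_that("the 24-nt insert fraction matches the configured mixture within sampling error", {
  cfg <- generator_config(n_reads_per_library = 50000, seed = 77)
  pair <- generate_library_pair(cfg)
  L <- nchar(c(pair$reads_A, pair$reads_B)) - nchar(cfg$adapter_sequence)
  n <- length(L)
  se <- sqrt(cfg$frac_len24 * (1 - cfg$frac_len24) / n)
  expect_lt(abs(mean(L == 24) - cfg$frac_len24), 3 * se)
})

test_that("compare_truth scores perfect, empty and partially wrong predictions", {
  truth <- data.frame(
    sequence = c("AAAA", "CCCC", "GGGG", "UUUU"),
    true_class = c("conserved_miRNA", "conserved_miRNA", "siRNA_like",
                   "siRNA_like"),
    true_family = c("fam-001", "fam-002", NA, NA),
    true_isoform_of = NA_character_,
    planted_count_A = c(100L, 100L, 10L, 10L),
    planted_count_B = c(100L, 100L, 10L, 10L),
    precursor = NA_character_, stringsAsFactors = FALSE)
  perfect <- data.frame(sequence = truth$sequence,
                        label = truth$true_class,
                        family = truth$true_family,
                        stringsAsFactors = FALSE)
  res <- compare_truth(perfect, truth)
  expect_true(all(res$per_class$precision == 1))
  expect_true(all(res$per_class$recall == 1))
  expect_identical(res$family_accuracy, 1)

  res0 <- compare_truth(perfect[0, ], truth)
  expect_true(all(res0$per_class$recall == 0))

  one_wrong <- perfect
  one_wrong$family[2] <- "fam-001"
  expect_identical(compare_truth(one_wrong, truth)$family_accuracy, 0.5)

  expect_error(compare_truth(perfect, rbind(truth, truth[1, ])), "duplicate")
})
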