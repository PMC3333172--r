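test_that("base-pair maximization handles canonical small cases", {
  f <- nussinov_fold("AAAAAA")
  expect_identical(f$n_pairs, 0L)
  expect_identical(f$structure, "......")

  f <- nussinov_fold("GGGAAACCC")
  expect_identical(f$n_pairs, 3L)
  expect_identical(f$structure, "(((...)))")

  expect_identical(nussinov_fold("GGGGAAAACCCC")$n_pairs, 4L)

  expect_error(nussinov_fold("GGGANACCC"), "outside")
  expect_error(nussinov_fold("GCG"), "min_loop")
})

test_that("maximum pair count matches exhaustive enumeration on short sequences", {
  set.seed(71)
  for (i in 1:200) {
    s <- random_rna_str(sample(5:12, 1))
    f <- nussinov_fold(s)
    expect_identical(f$n_pairs, oracle_max_pairs(s), info = s)
    # the returned structure realizes the optimum and is balanced
    expect_identical(nrow(f$pairs), f$n_pairs)
    expect_identical(sum(strsplit(f$structure, "")[[1]] == "("), f$n_pairs)
    if (nrow(f$pairs) > 0) {
      expect_true(all(f$pairs[, 2] - f$pairs[, 1] > 3))
      base <- strsplit(rna_normalize(s), "")[[1]]
      expect_true(all(xylomir:::can_pair(base[f$pairs[, 1]],
                                         base[f$pairs[, 2]])))
    }
  }
})

test_that("pair count is invariant under reverse complementation for Watson-Crick pairing", {
  # with G:U wobble the property cannot hold (a G:U pair maps to A:C under
  # reverse complementation), so it is asserted for strict pairing
  set.seed(72)
  for (i in 1:50) {
    s <- random_rna_str(sample(8:14, 1))
    expect_identical(nussinov_fold(s, allow_gu = FALSE)$n_pairs,
                     nussinov_fold(revcomp_rna(s), allow_gu = FALSE)$n_pairs,
                     info = s)
  }
})

test_that("hairpin check accepts constructed precursors and rejects unstructured RNA", {
  set.seed(73)
  m <- random_rna_str(21)
  pre <- generate_hairpin_precursor(m, "5p", 6, seed = 15)
  hp <- is_hairpin(pre, m)
  expect_true(hp$is_hairpin)
  expect_gte(hp$paired_fraction_mature, 0.9)
  expect_identical(hp$arm, "5p")

  # poly-A precursor with an A-rich mature: nothing pairs
  polyA <- strrep("A", 60)
  hpA <- is_hairpin(polyA, strrep("A", 21))
  expect_false(hpA$is_hairpin)
  expect_identical(hpA$n_pairs, 0L)

  expect_error(is_hairpin(pre, "GGGGGGGGGGGGGGGGGGGGG"), "not found")
})

test_that("dinucleotide-shuffled precursors almost never pass the hairpin check", {
  m <- "GACUGAGGUCAGGCAUCGAUC"
  pre <- generate_hairpin_precursor(m, "5p", 6, seed = 8)
  n_pass <- 0L
  for (i in 1:100) {
    shuf <- shuffle_dinucleotide(pre, seed = i)
    # judge the span where the mature used to sit
    mat <- substr(shuf, 1, nchar(m))
    if (is_hairpin(shuf, mat)$is_hairpin) n_pass <- n_pass + 1L
  }
  expect_lte(n_pass, 10L)
})

test_that("dinucleotide shuffling preserves dinucleotide composition", {
  dinucs <- function(x) {
    ch <- strsplit(x, "")[[1]]
    sort(paste0(ch[-length(ch)], ch[-1]))
  }
  set.seed(74)
  for (i in 1:20) {
    s <- random_rna_str(40)
    sh <- shuffle_dinucleotide(s, seed = i)
    expect_identical(dinucs(sh), dinucs(s))
    expect_identical(nchar(sh), nchar(s))
  }
})

test_that("the classification rule follows the count thresholds and precedence", {
  th <- class_thresholds()
  # low-count unannotated tags are siRNA-like (printed example: counts 17/18)
  expect_identical(classify_tag(18, has_family = FALSE,
                                is_contaminant = FALSE, th), "siRNA_like")
  # abundant unannotated tags with a passing hairpin are putative novel
  expect_identical(classify_tag(12000, FALSE, FALSE, th,
                                hairpin_pass = TRUE), "putative_novel_miRNA")
  # ... but a failing hairpin demotes them
  expect_identical(classify_tag(12000, FALSE, FALSE, th,
                                hairpin_pass = FALSE),
                   "unclassified_smallRNA")
  # a catalog hit dominates regardless of count
  expect_identical(classify_tag(5, TRUE, FALSE, th), "conserved_miRNA")
  # contaminants dominate everything
  expect_identical(classify_tag(50000, TRUE, TRUE, th), "ncRNA_fragment")
  # the 100..999 band is unclassifiable
  expect_identical(classify_tag(500, FALSE, FALSE, th),
                   "unclassified_smallRNA")

  expect_error(class_thresholds(novel_min_count = 50, sirna_max_count = 99),
               "below")
})

test_that("every tag receives exactly one label and the novel rule is monotone", {
  set.seed(75)
  counts <- sample(c(0:5, 90:110, 900:1100, 5000), 60, replace = TRUE)
  tags <- make_tags(replicate(60, random_rna_str(21)), counts,
                    rep(0L, 60))
  cls <- classify_tags(tags, thresholds = class_thresholds())
  expect_identical(nrow(cls), nrow(tags))
  expect_true(all(cls$label %in% xylomir:::CLASS_LABELS))

  # raising novel_min_count never moves a tag INTO the novel class
  cls_hi <- classify_tags(tags,
                          thresholds = class_thresholds(novel_min_count = 5000))
  was_novel <- cls$label == "putative_novel_miRNA"
  now_novel <- cls_hi$label == "putative_novel_miRNA"
  expect_true(all(!now_novel | was_novel))
})
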