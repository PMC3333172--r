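ref_catalog <- function() {
  qpcr <- amg_qpcr_matures()
  data.frame(family = qpcr$family,
             mature_sequence = rna_normalize(qpcr$sequence),
             source = "test", stringsAsFactors = FALSE)
}

test_that("catalog matching assigns the closest family within three edits", {
  cat <- ref_catalog()
  # exact hit on the miR394 mature sequence
  hit <- match_catalog("UUGGCAUUCUGUCCACCUCCC", cat)
  expect_identical(hit$family, "amg-miR394")
  expect_identical(hit$edit_distance, 0L)

  # the printed tag 1391(21) sits two edits from the miR394 mature
  hit2 <- match_catalog("UUUGGCAUUCUGUCCACCUCC", cat)
  expect_identical(hit2$family, "amg-miR394")
  expect_identical(hit2$edit_distance, 2L)

  # beyond three edits from everything: no assignment
  expect_identical(nrow(match_catalog("GGGGGGGGGGCCCCCCCCCC", cat)), 0L)

  # the closer of two entries wins
  cat2 <- data.frame(family = c("near", "far"),
                     mature_sequence = c("UUGGCAUUCUGUCCACCUACC",
                                         "UUGGCAUUCUGUCCACCAAAA"),
                     source = "t", stringsAsFactors = FALSE)
  hit3 <- match_catalog("UUGGCAUUCUGUCCACCUCCC", cat2)
  expect_identical(hit3$family, "near")

  # equidistant entries resolve to the lexicographically smaller family
  cat3 <- data.frame(family = c("zfam", "afam"),
                     mature_sequence = c("UUGGCAUUCUGUCCACCUCCA",
                                         "UUGGCAUUCUGUCCACCUCCG"),
                     source = "t", stringsAsFactors = FALSE)
  hit4 <- match_catalog("UUGGCAUUCUGUCCACCUCCU", cat3)
  expect_identical(hit4$family, "afam")

  expect_error(match_catalog("ACGU", cat[0, ]), "nonempty")
})

test_that("matching respects the annotation length window and never exceeds the threshold", {
  cat <- ref_catalog()
  tags <- make_tags(c("UUGGCAUUCUGUCCACCUCCC", strrep("AC", 9)),
                    count_A = c(5, 5), count_B = c(0, 0))
  hits <- match_catalog(tags, cat, window = c(19L, 24L))
  expect_identical(nrow(hits), 1L)  # the 18-mer is outside the window
  expect_true(all(hits$edit_distance <= 3L))

  # removing the winning entry never decreases the reported distance
  set.seed(14)
  for (i in 1:25) {
    tag <- xylomir:::mutate_sequence(cat$mature_sequence[sample(4, 1)],
                                     sample(0:3, 1))
    if (nchar(tag) < 19 || nchar(tag) > 24) next
    h <- match_catalog(tag, cat)
    if (nrow(h) == 0L) next
    rest <- cat[cat$family != h$family, , drop = FALSE]
    h2 <- match_catalog(tag, rest)
    if (nrow(h2) > 0L) expect_gte(h2$edit_distance, h$edit_distance)
  }
})

test_that("isoform indices rank by abundance and are order-invariant", {
  cat <- ref_catalog()
  seqs <- c("UUGGCAUUCUGUCCACCUCCC",  # exact mature
            "UUUGGCAUUCUGUCCACCUCC",  # 2 edits away
            "UUGGCAUUCUGUCCACCUCCA")  # 1 edit away
  tags <- make_tags(seqs, count_A = c(500, 50, 5), count_B = c(22, 7, 1))
  asn <- group_isoforms(match_catalog(tags, cat), tags)
  expect_identical(sort(asn$isoform_index), 1:3)
  expect_identical(asn$isoform_index[asn$sequence == seqs[1]], 1L)
  expect_identical(asn$isoform_index[asn$sequence == seqs[2]], 2L)

  # permuting the tag table leaves the numbering unchanged
  perm <- tags[c(3, 1, 2), ]
  attr(perm, "libraries") <- attr(tags, "libraries")
  asn2 <- group_isoforms(match_catalog(perm, cat), perm)
  m <- match(asn$sequence, asn2$sequence)
  expect_identical(asn$isoform_index, asn2$isoform_index[m])

  # a single assigned tag is isoform 1
  t1 <- make_tags(seqs[1], 10, 10)
  expect_identical(group_isoforms(match_catalog(t1, cat), t1)$isoform_index,
                   1L)

  # eleven distinct isomiRs enumerate 1..11
  iso11 <- generate_isoform_set("UUGGCAUUCUGUCCACCUCCC", 11, 3, seed = 6,
                                avoid = cat$mature_sequence[cat$family !=
                                                              "amg-miR394"])
  t11 <- make_tags(iso11, count_A = 11:1 * 10, count_B = rep(1, 11))
  a11 <- group_isoforms(match_catalog(t11, cat), t11)
  expect_identical(sort(a11$isoform_index[a11$family == "amg-miR394"]), 1:11)
})

test_that("contaminant flagging is exact-substring only", {
  ncrna <- generate_ncrna_catalog(seed = 10)
  frag <- substr(ncrna$sequence[1], 30, 50)
  expect_identical(flag_contaminant(frag, ncrna), ncrna$name[1])

  # one mismatch breaks the flag
  mut <- frag
  substr(mut, 11, 11) <- setdiff(c("A","C","G","U"),
                                 substr(frag, 11, 11))[1]
  expect_identical(flag_contaminant(mut, ncrna), NA_character_)

  expect_identical(flag_contaminant(frag, ncrna[0, ]), NA_character_)
})
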