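adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming recovers the insert and matches the offset-scan oracle", {
  p <- trim_params(adapter)
  tr <- trim_adapter(paste0("ACGTACGTAA", adapter), p)
  expect_identical(tr$insert, "ACGTACGTAA")
  expect_identical(tr$status, "ok")

  # read without any adapter occurrence is rejected under require_adapter
  expect_identical(trim_adapter("ACGTACGTACGTACGTACGTAC", p)$status,
                   "no_adapter")
  # ... and passed through unchanged when the adapter is optional
  p2 <- trim_params(adapter, require_adapter = FALSE)
  tr2 <- trim_adapter("ACGTACGTACGTACGTACGTAC", p2)
  expect_identical(tr2$insert, "ACGTACGTACGTACGTACGTAC")

  # one substitution inside a full 21-nt adapter match (rate 1/21 <= 0.1)
  mut <- adapter
  substr(mut, 10, 10) <- "A"
  tr3 <- trim_adapter(paste0("ACGTACGTAA", mut), p)
  expect_identical(tr3$insert, "ACGTACGTAA")

  # randomized agreement with the exhaustive-offset oracle, including
  # truncated 3' matches and mismatch-rate boundary cases
  set.seed(7)
  for (i in 1:200) {
    ins <- chartr("U", "T", random_rna_str(sample(5:30, 1), c("A","C","G","T")))
    keep <- sample(4:nchar(adapter), 1)
    read <- paste0(ins, substr(adapter, 1, keep))
    if (i %% 3 == 0) { # sprinkle mismatches into the adapter part
      pos <- nchar(ins) + sample(keep, 1)
      substr(read, pos, pos) <- sample(c("A","C","G","T"), 1)
    }
    cut <- oracle_trim_cut(read, adapter, 6, 0.1)
    got <- trim_adapter(read, p)
    if (is.na(cut)) {
      expect_identical(got$status, "no_adapter", info = read)
    } else if (cut == 0) {
      expect_identical(got$status, "empty_insert", info = read)
    } else {
      expect_identical(got$insert, substr(read, 1, cut), info = read)
    }
  }
})

test_that("trimming is idempotent on adapter-free inserts", {
  p <- trim_params(adapter, require_adapter = FALSE)
  once <- trim_adapter(paste0("ACGTACGTACGTACGTACGTACGT", adapter), p)$insert
  twice <- trim_adapter(once, p)$insert
  expect_identical(twice, once)
})

test_that("empty adapter is a configuration error", {
  expect_error(trim_params(""), "adapter")
})

test_that("length filter keeps the inclusive 7-35 nt window", {
  expect_false(filter_length(strrep("A", 6)))
  expect_true(filter_length(strrep("A", 7)))
  expect_true(filter_length(strrep("A", 35)))
  expect_false(filter_length(strrep("A", 36)))
  expect_error(filter_length("ACGU", min_len = 10, max_len = 5), "min_len")
})

test_that("collapse counts identical sequences per library and conserves reads", {
  tags <- collapse_tags(list(A = rep("ACGUACGUACGU", 5)))
  expect_identical(nrow(tags), 1L)
  expect_identical(tags$count_A, 5L)

  tags <- collapse_tags(list(A = c("ACGU", "ACGU", "GGGG"), B = "GGGG"))
  expect_identical(tags$count_A[tags$sequence == "ACGU"], 2L)
  expect_identical(tags$count_B[tags$sequence == "ACGU"], 0L)
  expect_identical(tags$count_A[tags$sequence == "GGGG"], 1L)
  expect_identical(tags$count_B[tags$sequence == "GGGG"], 1L)

  expect_identical(nrow(collapse_tags(list(A = character(0)))), 0L)

  # T/U and case normalization merge equivalent reads; N-reads are dropped
  tags <- collapse_tags(list(A = c("acgt", "ACGU", "ANGU")))
  expect_identical(tags$count_A, 2L)
  expect_identical(attr(tags, "n_rejected_N"), 1L)
})

test_that("collapse then re-expansion then collapse is the identity", {
  set.seed(8)
  reads <- list(A = sample(c(rep("ACGUACGU", 4), rep("GGGGCCCC", 2), "AUAUAUAU")),
                B = c(rep("GGGGCCCC", 3), "AUAUAUAU"))
  tags <- collapse_tags(reads)
  re <- list(A = rep(tags$sequence, tags$count_A),
             B = rep(tags$sequence, tags$count_B))
  tags2 <- collapse_tags(re)
  expect_identical(tags[order(tags$sequence), c("sequence","count_A","count_B")],
                   tags2[order(tags2$sequence), c("sequence","count_A","count_B")])
})

test_that("tag ids rank by total count with deterministic tie-breaking", {
  tags <- make_tags(c("ACGUACGUACGUACGUACGUAC", "ACGUACGUACGUACGUACGUA"),
                    count_A = c(60, 5), count_B = c(40, 2))
  expect_identical(tags$tag_id, c("1(22)", "2(21)"))

  # equal totals: lexicographically smaller sequence ranks first
  tags <- make_tags(c("GGGGGGGAAAAAAACCCCCCC", "AAAAAAACCCCCCCGGGGGGG"),
                    count_A = c(5, 5), count_B = c(5, 5))
  expect_identical(tags$sequence[tags$tag_id == "1(21)"],
                   "AAAAAAACCCCCCCGGGGGGG")

  # stability under permutation of input rows
  t1 <- make_tags(c("AAAAAAACCCCCCCGGGGGGG", "GGGGGGGAAAAAAACCCCCCC"),
                  count_A = c(5, 5), count_B = c(5, 5))
  expect_identical(t1$tag_id, tags$tag_id)
  expect_identical(t1$sequence, tags$sequence)

  tags1 <- make_tags("ACGUACGUACGUACGUACGUACGU", 3, 1)
  expect_identical(tags1$tag_id, "1(24)")
})

test_that("length histogram counts unique tags and total reads with conservation", {
  tags <- make_tags("AAAAAAACCCCCCCGGGGGGG", 10, 0)
  h <- length_histogram(tags)
  expect_identical(h$n_unique[h$library == "A"], 1L)
  expect_identical(h$n_total[h$library == "A"], 10L)
  expect_false("B" %in% h$library)  # zero-count library has no profile rows

  expect_identical(nrow(length_histogram(collapse_tags(list(A = character(0))))), 0L)

  # conservation: totals per library equal retained read counts
  set.seed(9)
  reads <- list(A = replicate(50, random_rna_str(sample(19:24, 1))),
                B = replicate(30, random_rna_str(sample(19:24, 1))))
  tags <- collapse_tags(reads)
  h <- length_histogram(tags)
  expect_identical(sum(h$n_total[h$library == "A"]), 50L)
  expect_identical(sum(h$n_total[h$library == "B"]), 30L)
})

test_that("FASTQ written by the generator round-trips through the reader", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(n_reads_per_library = 300, seed = 3)
  pair <- generate_library_pair(cfg)
  paths <- write_library_pair(pair, dir)
  back <- read_small_rna(paths[["A"]])
  expect_identical(unname(back), pair$reads_A)
  expect_identical(length(back), length(pair$reads_A))
})
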