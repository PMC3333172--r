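#!/usr/bin/env Rscript
# Assign tags to conserved miRNA families (<= 3 edits), enumerate isomiRs,
# flag ncRNA fragments, and classify the remainder by abundance with the
# hairpin check on loci whose precursors are known from the simulation
# truth.

suppressPackageStartupMessages(library(xylomir))

sim <- "results/simulation"
out_dir <- "results/annotation"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

tags <- utils::read.delim("results/preprocess/tags.tsv",
                          stringsAsFactors = FALSE)
attr(tags, "libraries") <- c("A", "B")
catalog <- read_mirna_catalog(file.path(sim, "catalog.fasta"))
ncx <- Biostrings::readBStringSet(file.path(sim, "ncrna.fasta"))
ncrna <- data.frame(name = names(ncx), sequence = as.character(ncx),
                    stringsAsFactors = FALSE)
truth <- utils::read.delim(file.path(sim, "truth.tsv"),
                           stringsAsFactors = FALSE)

contam <- flag_contaminant(tags, ncrna)
clean <- tags[is.na(contam), , drop = FALSE]
attr(clean, "libraries") <- c("A", "B")
assignments <- group_isoforms(match_catalog(clean, catalog), tags)

has_pre <- !is.na(truth$precursor)
hairpins <- lapply(stats::setNames(truth$precursor[has_pre],
                                   truth$sequence[has_pre]),
                   function(p) NULL)
for (s in names(hairpins)) hairpins[[s]] <-
  is_hairpin(truth$precursor[truth$sequence == s], s)

classification <- classify_tags(tags, assignments, contam,
                                thresholds = class_thresholds(),
                                hairpins = hairpins)
fam <- summarize_families(assignments, tags)

utils::write.table(assignments, file.path(out_dir, "assignments.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(classification, file.path(out_dir, "classification.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(fam, file.path(out_dir, "family_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("families detected:", nrow(fam), "\n")
print(fam)
cat("\nclassification of", nrow(classification), "tags:\n")
print(table(classification$label))
res <- compare_truth(classification, truth)
cat("\nrecovery against simulation truth:\n")
print(res$per_class)
cat("family assignment accuracy:", res$family_accuracy, "\n")
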