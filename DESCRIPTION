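Package: xylomir
Title: Small RNA Profiling and Classification in Secondary Xylem Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a two-library small RNA profiling
    workflow for woody-plant secondary xylem: adapter trimming, length
    selection and collapse of reads into counted sequence tags; assignment of
    tags to conserved miRNA families by mismatch-tolerant (Levenshtein)
    matching with isoform grouping; classification of unannotated tags into
    putative novel miRNAs, siRNA-like and unclassified small RNAs by abundance
    thresholds with a hairpin-foldability check (base-pair maximization);
    depth-normalized two-library differential abundance with an exact
    conditional binomial test; and position-weighted plant miRNA target
    complementarity scanning. Includes a synthetic two-library generator with
    ground truth (bimodal 21/24-nt length mixture, conserved families with
    isomiRs, novel hairpin loci, low-count siRNA background, ncRNA fragments,
    3' adapter) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
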