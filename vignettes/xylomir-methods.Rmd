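---
title: "Methods: small-RNA profiling of two secondary-xylem libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA profiling of two secondary-xylem libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how the pipeline's models and parameters were chosen,
what the synthetic generator does and does not emulate, and the numerical
decisions a maintainer would otherwise have to reverse-engineer from the
code.

## The study design the package addresses

Two small-RNA libraries from secondary xylem with contrasting lignin
content, one library per condition, no replicates, and no reference genome
for the species. That shapes everything downstream:

* all analysis operates on *sequence tags* — unique insert sequences with
  per-library read counts — because without a genome there is no mapping
  step;
* conserved miRNAs are recognized by sequence similarity to a mature-miRNA
  catalog, not by locus annotation;
* novel miRNAs cannot be confirmed by folding a genomic flanking region, so
  the hairpin criterion applies only where a precursor candidate is
  available (in the synthetic setting, from the generator truth; for real
  data, user-supplied), and expression level otherwise carries the
  classification;
* the differential comparison is an unreplicated two-library count
  comparison, for which the exact conditional binomial (the classic SAGE
  comparison) is the defensible test; no dispersion can be estimated from
  one library per condition.

## Preprocessing

Adapter removal takes the leftmost alignment of the 3' adapter — the full
adapter anywhere, or a 3'-truncated suffix of ≥ `min_overlap` (6) bases at
the read end — at a per-alignment mismatch rate ≤ 0.1, with no indels. The
contract is deliberately the simplest one with an exhaustive oracle: every
offset can be checked by brute force in the tests. Reads without a
qualifying alignment are rejected (`no_adapter`) by default; empty inserts
are rejected (`empty_insert`); reads containing N are rejected at collapse.
Qualities are carried but never used — no quality threshold is part of the
pipeline. The retention window is 7–35 nt inclusive for profiling, while
annotation and classification are restricted to 19–24 nt
(`annotation_window`), the biologically meaningful small-RNA range; both
windows are configuration, not constants.

Tag identifiers have the form `rank(length)` with rank by descending total
count and lexicographic tie-breaking, so identifiers are deterministic and
permutation-invariant.

## Family assignment and isomiRs

The distance is Levenshtein (unit-cost substitutions, insertions,
deletions), not Hamming: isomiRs within one family differ in length
(19–24 nt), which Hamming cannot score. The membership threshold is ≤ 3
edits. The source material is ambiguous between "not more than 3" and
"less than three"; the Methods-style wording (≤ 3) is taken as normative
and the threshold is exposed as `max_mismatch`. A tag equidistant from two
families goes to the lexicographically smaller family name — a single best
assignment is enforced, and determinism is preferred over an arbitrary
multi-assignment rule.

The implementation is a banded dynamic program (`edit_distance_bounded`)
that reports exact distances up to the threshold and "greater" beyond it;
the exported `edit_distance` is the full DP. Both are cross-checked in the
tests against a brute-force recursion and against `utils::adist`, which are
never used in the pipeline itself.

Contaminant flagging (exact substring of an rRNA/tRNA/snRNA catalog entry,
forward strand) runs *before* family matching, so an ncRNA fragment can
never be counted into a miRNA class.

## Classification thresholds

The count thresholds follow the study's stated bands: ≥ 1,000 counts for
putative novel miRNAs, < 100 for siRNA-like, and an explicitly
unclassifiable 100–999 band. The count scope is the maximum over the two
libraries, because novel loci are expected to show strong between-library
differences — at least one library carries the high count. Both thresholds
and the scope are configuration (`class_thresholds`).

## The hairpin criterion

Foldability into a stem-loop precursor is the accepted evidence separating
miRNAs from siRNAs. The folding model is base-pair maximization (Nussinov)
with G:U wobble and hairpin loops ≥ 3 nt — a combinatorial criterion, not a
thermodynamic one: the check is binary, and an energy model would import
large parameter tables without adding discriminative power at these lengths.
The acceptance test is:

* one dominant stem-loop with ≥ 14 pairs, where a stem is the run of pairs
  nested around a single hairpin loop walked outward until a bulge larger
  than `max_stem_bulge` (default 1 nt) interrupts it;
* ≥ 60% of mature-span bases paired;
* no unpaired run > 4 nt inside the mature span.

The 1-nt bulge tolerance in the stem walk is the load-bearing choice:
unconstrained base-pair maximization threads long nested chains with 2–4 nt
bulges through random RNA, and with a 4-nt tolerance roughly a quarter of
dinucleotide-shuffled precursors would still pass; with 1 nt the tests
find ≤ 10% of 100 shuffles passing while every generator-built precursor
(a perfect or wobble-only stem) passes. A consequence worth knowing:
genuine precursors with internal loops ≥ 2 nt in the mature-proximal stem
will fail the default check; `max_stem_bulge` is exposed for such data.

One caveat recorded as a property rather than hidden: the pair count is
invariant under reverse complementation only for strict Watson–Crick
pairing. With wobble the property cannot hold (a G:U pair maps to A:C under
reverse complementation), so the test asserts it with `allow_gu = FALSE`.

## Differential abundance

Counts are normalized to reads per million of retained reads; fold changes
are log2(B/A) with a 1-RPM pseudocount (zero counts are common among
low-abundance tags). The test conditions on the tag's combined count:
under the null, count_B ~ Binomial(n, N_B/(N_A+N_B)); two-sided p by
doubling the smaller tail, capped at 1 — conservative for discrete counts,
which the type-I simulations confirm (≤ 6% at nominal 5%). Tags with
combined count < 10 are reported but not tested: testing singletons is
powerless and inflates the Benjamini–Hochberg burden. Calls require
q ≤ 0.05 *and* |log2FC| ≥ 1; "strong difference" has no numeric definition
in the source material, so these defaults are stated, not inferred.

## Target scanning

The scoring scheme is the established plant convention — mismatch 1,
G:U 0.5, penalties doubled over miRNA positions 2–13, cutoff 3 — rather
than a duplex free-energy model; it is exactly testable window by window.
Gapped alignment is not implemented (`gap_penalty` is reserved): plant
target sites are perfect or near-perfect complements, and every contract in
the module is defined on ungapped windows. Coordinates are 0-based
half-open on the transcript sense strand. Overlapping qualifying windows of
one miRNA merge into the best-scoring hit. Degenerate transcript bases
count as mismatches.

## The synthetic generator

The generator is the package's substitute for the study's unavailable raw
data. It emulates:

* a bimodal insert-length mixture with peaks at 21 and 24 nt and 80% of
  reads at 24 nt (default mixture: 1/2/10/3/4/80% over 19–24 nt);
* 12 conserved families (pairwise mature distance > 3, so family identity
  is unambiguous) with 3 isomiRs each, the canonical mature carrying 70% of
  the family mass, isoforms within 3 edits of the mature and kept > 3 edits
  from every *other* mature so that recall can be 1.0 by construction;
* 6 novel 24-nt hairpin loci with expected counts ≥ 1,500 at reference
  depth, each with a generator-built precursor that passes the hairpin
  check;
* ncRNA fragments (2% of reads, drawn as substrings of a small synthetic
  rRNA/tRNA/snRNA catalog);
* a uniform random siRNA background, rejected within 3 edits of any mature,
  with expected per-species counts in [1, 80] at reference depth — capped
  at 80 rather than 99 so that Poisson-realized counts stay below the
  100-count siRNA ceiling with high probability;
* the standard Illumina small-RNA 3' adapter appended to every insert;
  constant high qualities (the pipeline does no quality filtering).

Counts are planted as expectations at a reference depth of 2×10^5 reads per
library, scaled linearly to the configured depth, and realized as Poisson
draws — so the differential test sees a correct sampling null. Fold changes
default to reciprocal mass-balanced pairs: a locus pair gets base counts
(c, r·c) with ratios (r, 1/r), contributing equal expected mass to both
libraries. This keeps both libraries at the same expected depth and the
same length mixture despite planted 8-fold changes. Background species
lengths are apportioned greedily against the *relative* residual length
mass left after all planted classes, which pins the expected mixture to the
target; the realized 24-nt fraction then fluctuates at essentially the
binomial standard error, which is what the acceptance checks assume.

What the generator does **not** emulate: sequencing error, PCR duplication
and ligation bias, quality variation, adapter-less or truncated reads, and
genomic clustering of loci. Passing recovery tests therefore demonstrate
the pipeline's correctness under clean sampling noise, not robustness to
platform artifacts.

## Problem sizes and determinism

Default analyses and recovery tests run at 2×10^5 reads per library
(~3,700 tag species); the length-distribution checks run at 1×10^5 per
library; oracle-equivalence suites use sequences ≤ 8 nt (edit distance),
≤ 12 nt (folding) and ≤ 2,000 nt (target scan), the sizes at which
brute-force enumeration is exact and fast. Every stochastic component takes
an explicit seed, and the generator restores the caller's RNG state, so
identical configurations are byte-identical end to end.

## Known limitations

* One library per condition: the "differential" calls are exact-test calls
  on a single pair of counts, not replicate-backed inference.
* The hairpin check needs a precursor candidate; without one, abundant
  unannotated tags are called novel on expression level alone, exactly as
  the genome-less study design forces.
* Base-pair maximization overestimates pairing relative to thermodynamic
  folding; the stem-walk bulge limit compensates, but borderline real
  precursors deserve a thermodynamic second opinion.
* The printed family-count and tag tables shipped in `inst/extdata/` are
  fixture inputs (schema and worked-example values); the study's raw-data
  results are not recomputable from them.
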