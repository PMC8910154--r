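---
title: "Methods: strict somatic piRNA identification, signatures, and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strict somatic piRNA identification, signatures, and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures somapiR implements, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical and design choices that were
genuinely open.

## 1. Strict piRNA identification

Somatic piRNA calls are easily inflated by fragments of other small ncRNAs
whose loci overlap piRNA annotations. The pipeline is therefore strict in
three specific ways:

* **Size filter** (`trim_and_filter`): reads must be 20–32 nt *after*
  adapter removal, both bounds inclusive. Adapter removal takes the longest
  read suffix equal to an adapter prefix, requiring at least 5 exact nt —
  below that, chance matches outnumber real adapter remnants.
* **Alignment** (`mini_align`): at most one substitution per placement;
  reads with more than 50 distinct placements are discarded entirely.
  The aligner is seed-and-extend with two disjoint 10-mers: with one
  allowed mismatch at least one seed is exact (pigeonhole), so candidate
  generation is provably complete, and every candidate is verified by
  bounded Hamming comparison. An exhaustive Hamming scanner with the same
  contract ships in the package purely as an independent test oracle.
* **Exclusion precedes annotation** (`classify_reads`): a read *any* of
  whose placements overlaps the other-ncRNA track by ≥ 1 bp (either
  strand) is excluded outright. Only then are the remaining reads matched
  to piRNA loci, requiring at least 50 % of the read length inside a locus
  (strand-agnostic, as piRNA annotations mix strands). The 1 bp exclusion
  and 50 % assignment thresholds are parameters; the asymmetry is
  deliberate — exclusion is meant to be aggressive, assignment substantive.

Multi-mappers are represented once per read with a placement list; every
count downstream uses weight 1/x (x = placements), and a placement inside
several piRNA loci splits its weight further as 1/(x · loci-at-placement),
so total count mass is conserved.

## 2. Quantification and presence

`build_counts` produces the piRNA × sample matrix of fractional counts.
Library size defaults to the total aligned reads per sample *before*
ncRNA exclusion (switchable): the pre-exclusion total is stable across
annotation choices, whereas a post-exclusion total would couple
normalization to the exclusion track version.

Presence (`call_present`) uses two strict branches: counts > `min_all`
(default 2) in **all** samples, or counts > `min_half` (default 10;
ovary-style designs use 5) in at least half the samples. "Half" is
`ceiling(n/2)` — at least half, the stricter common reading for odd n.
Thresholds apply to raw fractional counts, not normalized values, since
they encode sequencing-depth-scale evidence.

The chromosome profile uses the variant RPKM
(reads-on-chromosome × 10⁶)/(present piRNAs × chromosome length), with 1/x
weighting. "Number of piRNAs" is read as the *present* set of the analyzed
sample set, not a genome-wide annotation count: this makes panels
comparable across tissues with very different piRNA repertoires. The
formula inverts exactly to the total weighted read mass, which the tests
exploit as a conservation check.

## 3. Genomic context

`profile_context` reports three independent panels against the same
denominator (total fraction-weighted annotated piRNA reads): repeat
classes (LINE/SINE/LTR/DNA are transposons; everything else
`other_repeat`), transcript biotypes (protein-coding, lncRNA, pseudogene),
and feature kinds. A placement overlapping both a repeat and a gene
contributes to both panels — the panels are separate views, and their
ratios need not jointly sum below one. Within the feature panel one gene
contributes at most one feature per placement, with priority
3'UTR > 5'UTR > CDS > exon, so 3'UTR attribution is unambiguous.
Orientation is *sense* when the read strand equals the feature strand;
unstranded features count as sense.

piRNA-aligned genes use two standards on the gene × sample count matrix:
*stringent* (> 10 in ≥ 50 % of samples, or > 2 in all) and *relaxed*
(> 2 in more than 10 samples), all inequalities strict. Group differences
in context ratios use the two-sided Wilcoxon rank-sum test on per-sample
ratios with 0.05/0.01/0.001 significance stars.

## 4. Biogenesis signatures

The ping-pong cycle leaves two sequence fingerprints: a uridine at
position 1 of primary piRNAs and (by 10-nt 5'-complementarity) an adenine
at position 10 of secondary piRNAs, plus an excess of opposite-strand read
pairs whose 5' ends overlap by exactly 10 nt. `pingpong_statistic`
accumulates the 5'-overlap spectrum S_k for k = 1..20 with pair weight
1/(x₁x₂) and scores the k = 10 bin against the other 19 bins as its
empirical background: z = (S₁₀ − mean)/sd, one-sided signal at
z ≥ 1.645 (5 %). The 19-bin local background stands in for a full
pingpongpro-style HMM, which is out of scope; the threshold is a
parameter. Base biases are one-sided exact binomial tests against the
uniform 0.25 null. Position 10 is read on the read's own 5'→3' sequence,
as the biology dictates, and the ≥ 20 nt length floor guarantees it
exists. Samples with reads on only one strand report "no signal" with an
undefined z rather than a numeric zero.

## 5. Differential expression and enrichment

piRNA counts are small, non-normal, and tissue cohorts are modest, so the
implemented engine is the Wilcoxon rank-sum test on CPM-normalized counts:
exact two-sided law for combined n ≤ 20 without ties, otherwise the normal
approximation with tie and continuity correction. Significance follows the
raw p < α rule (α = 0.05 default); BH q-values are computed and reported
alongside but do not drive the significance flag — faithfulness to the
original decision rule first, rigor visible next to it. Kruskal–Wallis
covers ≥ 3 staged groups, and `progression_specific` reports features
significant across stages but not in the pooled two-group comparison —
the signature of monotone progression effects with balanced pooled means.
All-tied rows are defined to p = 1. A batch column is carried in the
sample sheet; batch correction itself is out of scope.

Enrichment is a self-contained hypergeometric upper tail P(X ≥ k) with BH
correction across sets and gene-ratio k/K; the universe defaults to all
genes of the transcript track (overridable), since externally curated
universes are opaque and irreproducible offline.

## 6. Sparse PLS-DA

The classifier is PLS2 regression of standardized features X on centered
class indicators Y. Per component the dominant singular pair of the
deflated X'Y is found by power iteration; the x-weight vector is
soft-thresholded so that exactly keepX entries survive (ties broken by
order, never exceeding keepX), renormalized to unit length, and X and Y
are deflated by regression on the component score. The largest-magnitude
weight entry is made positive for reproducible reports. Dense fits
(keepX = p) reproduce the leading singular vector of X'Y to 1e-8, which
the tests verify against a dense SVD and against mixOmics as an
independent implementation.

Prediction is max-indicator ("max.dist"): project, regress, argmax; the
continuous per-class values feed ROC analysis (positive-class score for
two classes, macro one-vs-rest averaging beyond). Tuning follows the
two-stage protocol: leave-one-out accuracy selects the number of
components (candidates 1–10, ties to the smaller model) on dense fits,
then keepX is grid-searched per component with earlier components fixed
(default grid 5/10/25/50/100/all, ties to the sparser model). The reported
accuracy and AUC come from the chosen configuration's pooled LOO
predictions. Because the maximum over candidate configurations is
reported, null-data accuracy sits slightly above 0.5 on average (selection
bias of the tuning protocol itself — visible in the acceptance checks and
left visible deliberately). Folds that lose a class are skipped with a
warning and the divisor adjusted. The whole procedure is deterministic:
no RNG is consumed, and a seed argument exists only for interface
stability. VIP scores use the standard definition
VIP_j = √(p · Σ_h SS_h w²_{jh} / Σ_h SS_h); dense fits satisfy
mean(VIP²) = 1, a normalization identity the tests assert.

## 7. The synthetic-data generator

`simulate_genome` plants, on a uniform-random genome (default 2 × 100 kb),
non-overlapping repeat loci (five classes), protein-coding genes
(100 nt 5'UTR / 600 nt CDS / 300 nt 3'UTR, exon spanning), lncRNAs,
pseudogenes (full sequence copies of genes — a realistic multi-mapping
source), decoy tRNA/rRNA/miRNA/snoRNA loci, and 60 nt piRNA loci nested in
configurable contexts (defaults: 25 % transposon, 15 % 3'UTR, 10 %
pseudogene, 5 % lncRNA, 45 % intergenic; repeat-hosted loci antisense with
probability 0.5). A quarter of genes carry an 80 nt transposon fragment in
their 3'UTR, and 10 % of intergenic piRNA loci are sequence-duplicated so
multi-mapping is exercised end to end.

`simulate_reads` draws per-sample library sizes log-normally (default
median 20 000 reads — a deliberate desk-scale stand-in for the tens of
millions in real cohorts), allocates 25 % of each library to decoy loci,
and samples piRNA locus counts from a multinomial over baseline abundance
(log-normal, σ = 1) × group fold change (default: 20 loci at 4× in the
disease group of a 14 + 14 cohort, the configured study design) ×
per-sample biological noise (log-normal, σ = 0.5). Germline-like samples
draw 24–32 nt reads with a 5'U start bias (0.75) and emit, for 30 % of
locus draws, a primary plus an opposite-strand mate whose 5' end lies
exactly 9 bases downstream in plus coordinates — 10 nt of 5'-overlap, so a
1U primary implies a 10A mate by complementarity; the `a10_fraction` knob
is therefore implemented as the 1U-forcing probability of *paired*
primaries. Somatic-like samples draw 20–30 nt reads with uniform starts.
5' offsets are confined to the first (locus length − max read length + 1)
positions so offset and length draw independently; paired primaries start
at offset ≥ 14 so the mate stays at least half inside the locus.

Reads are exact genome substrings. Sequencing error, quality scores and
PCR duplicates are *not* modeled; the aligner's mismatch tolerance is
exercised by a separate knob that plants exactly one substitution in a
configurable read fraction. Passing tests therefore demonstrate the
pipeline's logic and calibration, not robustness to platform noise, chimeric
reads, or annotation errors in real data.

## 8. Problem sizes and numerical choices

The test and acceptance workloads use: 100 kb genomes with 10⁴ reads for
aligner-oracle equality; cohorts of 28 × ~20 000 reads for recovery, power
and context checks; 100 seeded single-sample cohorts for the
germline/somatic ping-pong contrast; 5 000 null features for type-I
calibration; and 50 null + 20 planted seeds at n = 15, p = 500 for the
classifier. The planted biomarker separation is 2.5 standardized units on
6 of 500 features — a strong but attainable effect consistent with a
cross-validated accuracy above 90 % at that sample size. Power-iteration
convergence is 1e-9 on the weight vector (max 500 iterations);
orthogonality of scores holds to 1e-8; all-zero cross-products terminate
component extraction early.

## 9. Known limitations

* Interval annotation (featureCounts-style) rather than sequence-identity
  matching to a piRNA database; loci, not sequences, define identity.
* No indels, splicing, or quality-aware trimming in the built-in aligner;
  real-data users can ingest external SAM/BAM via `read_alignments` and
  skip `mini_align`.
* The ping-pong z uses a 19-bin local background, not a genome-wide
  false-discovery model.
* Batch effects are recorded but not corrected; DE alternatives for
  large, well-behaved designs (negative-binomial models) are intentionally
  not reimplemented.
* The classifier's two-stage tuning reports the selected configuration's
  CV performance without an outer validation loop, so reported accuracy
  carries the usual model-selection optimism; on null data this is about
  +0.1 over chance at n = 20.
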