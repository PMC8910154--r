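# Shared fixtures: tiny configs and hand-built genomes/tracks used across
# the suite. Everything is generated in code at test time.

# small two-group somatic cohort (fast; ~3k reads/sample)
small_cfg <- function(seed = 7, ...) {
  sim_config(seed = seed,
             groups = list(
               list(name = "control", n_samples = 4, germline = FALSE, de = FALSE),
               list(name = "case", n_samples = 4, germline = FALSE, de = TRUE)),
             libsize_lognormal = list(meanlog = log(3000), sigma = 0.2),
             ...)
}

# one germline-like + one somatic-like sample, for signature contrasts
signature_cfg <- function(seed = 1, pair_fraction = 0.3, n_reads = 3000) {
  sim_config(seed = seed,
             n_chroms = 1L, chrom_len = 30000L,
             n_pirna_loci = 60L, n_decoy_ncrna = 10L,
             n_repeats = c(LINE = 3L, SINE = 3L, LTR = 2L, DNA = 2L,
                           simple_repeat = 2L),
             n_genes = 6L, n_lncrna = 2L, n_pseudogenes = 2L,
             groups = list(
               list(name = "germ", n_samples = 1, germline = TRUE, de = FALSE),
               list(name = "soma", n_samples = 1, germline = FALSE, de = FALSE)),
             pingpong = list(enabled = TRUE, pair_fraction = pair_fraction),
             libsize_lognormal = list(meanlog = log(n_reads), sigma = 0.1))
}

# classify + annotate every sample of a cohort
annotate_cohort <- function(sim, max_mismatch = 1L) {
  lapply(sim$reads$samples, function(s) {
    tf <- trim_and_filter(s, adapter = sim$cfg$adapter %||% "")
    classify_reads(mini_align(tf$reads, sim$genome, max_mismatch = max_mismatch),
                   sim$tracks$ncrna, sim$tracks$pirna)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built annotated_reads object from explicit placements; category is
# recomputed against the given tracks
manual_annotated <- function(reads, placements, ncrna = GRanges(),
                             pirna = GRanges()) {
  classify_reads(aligned_reads(reads, placements), ncrna, pirna)
}

# count_matrix straight from a numeric matrix (bypassing alignment)
manual_cm <- function(counts, groups = NULL, lib_size = NULL) {
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("p%03d", seq_len(nrow(counts)))
  if (is.null(groups)) groups <- rep("g1", ncol(counts))
  structure(list(
    counts = counts,
    lib_size = lib_size %||% setNames(rep(1e6, ncol(counts)), colnames(counts)),
    samples = data.frame(sample = colnames(counts), group = groups,
                         tissue = "t", batch = "")),
    class = "count_matrix")
}

library(GenomicRanges)
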