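# piRNA x sample count matrices with 1/x fractional multi-mapper weighting,
# presence calling under per-tissue thresholds, the chromosome RPKM variant
# (reads on chromosome x 1e6 / (present piRNAs x chromosome length)), and
# Venn-partition set comparisons across tissues.

#' Presence rule for calling a piRNA expressed
#'
#' A piRNA is present when its counts exceed `min_all` in every sample OR
#' exceed `min_half` in at least half of the samples (ceiling for odd n);
#' both comparisons are strict. The default (2, 10) matches the standard for
#' most tissues; ovary-style designs use (2, 5).
#'
#' @param min_all strict lower bound applied to every sample.
#' @param min_half strict lower bound applied to at least 50% of samples.
#' @return object of class `presence_rule`.
#' @export
presence_rule <- function(min_all = 2, min_half = 10) {
  if (min_all > min_half) stopf("min_all must be <= min_half")
  structure(list(min_all = min_all, min_half = min_half),
            class = "presence_rule")
}

#' Build a piRNA x sample fractional count matrix
#'
#' `counts[p, s]` sums `1 / (x * loci-at-placement)` over every placement of
#' every read assigned to piRNA `p` in sample `s`. Library size is the total
#' aligned-read count per sample before ncRNA exclusion (switch with
#' `lib_size_post_exclusion`).
#'
#' @param annotated_samples named list of `annotated_reads`
#'   ([classify_reads()] outputs), names = sample ids.
#' @param sample_sheet data.frame with `sample`, `group`, `tissue`, `batch`;
#'   must cover exactly the sample names.
#' @param lib_size_post_exclusion if TRUE, library size counts only reads
#'   surviving ncRNA exclusion.
#' @return object of class `count_matrix`: `counts` (piRNA x sample),
#'   `lib_size`, `samples` (the sheet, ordered as columns).
#' @export
build_counts <- function(annotated_samples, sample_sheet,
                         lib_size_post_exclusion = FALSE) {
  stopifnot(length(annotated_samples) >= 1L)
  sids <- names(annotated_samples)
  if (is.null(sids) || !setequal(sids, sample_sheet$sample))
    stopf("sample sheet does not match the annotated sample names")
  sample_sheet <- sample_sheet[match(sids, sample_sheet$sample), , drop = FALSE]
  per <- lapply(sids, function(s) {
    a <- annotated_samples[[s]]$assignments
    if (nrow(a) == 0L) return(setNames(numeric(), character()))
    tapply(a$weight, a$pirna_id, sum)
  })
  ids <- sort(unique(unlist(lapply(per, names))))
  counts <- matrix(0, length(ids), length(sids),
                   dimnames = list(ids, sids))
  for (j in seq_along(per)) counts[names(per[[j]]), j] <- per[[j]]
  lib <- vapply(sids, function(s) {
    r <- annotated_samples[[s]]$reads
    if (lib_size_post_exclusion) sum(r$category != "excluded_ncRNA")
    else nrow(r)
  }, 0)
  structure(list(counts = counts, lib_size = lib, samples = sample_sheet),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d piRNAs x %d samples (%d groups)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$group))))
  invisible(x)
}

#' Counts per million library reads
#' @param cm a `count_matrix`.
#' @return matrix of CPM-normalized counts.
#' @export
cpm <- function(cm) {
  stopifnot(is(cm, "count_matrix"))
  sweep(cm$counts, 2L, cm$lib_size, "/") * 1e6
}

#' Call present (expressed) piRNAs under a presence rule
#'
#' @param cm a `count_matrix`.
#' @param rule a [presence_rule()].
#' @return character vector of present piRNA ids.
#' @export
call_present <- function(cm, rule = presence_rule()) {
  stopifnot(is(cm, "count_matrix"), is(rule, "presence_rule"))
  n <- ncol(cm$counts)
  all_branch <- rowSums(cm$counts > rule$min_all) == n
  half_branch <- rowSums(cm$counts > rule$min_half) >= ceiling(n / 2)
  rownames(cm$counts)[all_branch | half_branch]
}

#' Chromosome RPKM profile of annotated piRNA reads
#'
#' RPKM per chromosome = (fraction-weighted reads mapped to the chromosome
#' x 1e6) / (number of present piRNAs x chromosome length). Each placement
#' carries weight 1/x. The mitochondrial chromosome (chrM/MT) is flagged for
#' separate reporting.
#'
#' @param annotated an `annotated_reads` object (one sample).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param present character vector of present piRNA ids (non-empty).
#' @return data.frame with `chrom`, `reads` (weighted), `rpkm`, `is_mito`.
#' @export
chromosome_rpkm <- function(annotated, chrom_lengths, present) {
  if (length(present) == 0L) stopf("present piRNA set is empty")
  pl <- .pirna_placements(annotated)
  w <- tapply(mcols(pl)$weight, as.character(seqnames(pl)), sum)
  chroms <- names(chrom_lengths)
  reads <- setNames(rep(0, length(chroms)), chroms)
  reads[names(w)] <- w
  data.frame(chrom = chroms,
             reads = unname(reads),
             rpkm = unname(reads * 1e6 / (length(present) * chrom_lengths)),
             is_mito = chroms %in% c("chrM", "MT", "chrMT"),
             stringsAsFactors = FALSE)
}

#' Venn-partition cardinalities of presence sets
#'
#' @param sets named list (>= 2) of character vectors, e.g. present piRNAs
#'   per tissue.
#' @return data.frame with one row per non-empty-pattern region of the Venn
#'   partition: membership flags per set, `region` label and `size`.
#' @export
compare_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  univ <- unique(unlist(sets))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) memb <- matrix(memb, nrow = 1,
                                         dimnames = list(NULL, names(sets)))
  pat <- apply(memb, 1L, paste, collapse = "")
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))[-2^length(sets), ,
                                                                 drop = FALSE]
  names(combos) <- names(sets)
  combos <- combos[order(-rowSums(combos)), , drop = FALSE]
  key <- apply(combos, 1L, paste, collapse = "")
  sizes <- table(factor(pat, levels = key))
  out <- cbind(combos,
               region = vapply(seq_len(nrow(combos)), function(i)
                 paste(names(sets)[unlist(combos[i, ])], collapse = "&"), ""),
               size = as.integer(sizes))
  rownames(out) <- NULL
  out
}
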