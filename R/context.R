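# Genomic context of annotated piRNA reads: transposon-class and
# transcript-biotype ratios with sense/antisense orientation, a
# feature-resolved view (3'UTR > 5'UTR > CDS > exon priority), gene-level
# piRNA counts with the stringent/relaxed piRNA-aligned-gene standards, and
# group comparisons of per-sample ratios.

.transposon_classes <- c("LINE", "SINE", "LTR", "DNA")

#' Genomic-context profile of one sample's annotated piRNA reads
#'
#' Each piRNA-read placement (weight 1/x) is intersected with the repeat
#' track (classes LINE/SINE/LTR/DNA, everything else `other_repeat`) and the
#' transcript track (gene biotypes protein_coding / lncRNA / pseudogene;
#' feature kinds 3UTR/5UTR/CDS/exon with 3UTR > 5UTR > CDS > exon priority
#' per gene). Orientation is sense when the read strand equals the feature
#' strand ("*" features count as sense). Each panel is an independent view
#' against the same denominator: total fraction-weighted annotated piRNA
#' reads. A placement overlapping several classes contributes its weight to
#' each.
#'
#' @param annotated `annotated_reads` for one sample.
#' @param repeat_track GRanges with `attrs` (or `class`) = repeat class.
#' @param transcript_track GRanges with `gene_id`, `kind`, `biotype`.
#' @return data.frame: `panel` (repeat/biotype/feature), `class`,
#'   `orientation`, `count` (weighted), `ratio`.
#' @export
profile_context <- function(annotated, repeat_track, transcript_track) {
  pl <- .pirna_placements(annotated)
  denom <- sum(mcols(pl)$weight)
  if (denom == 0) stopf("sample has no annotated piRNA reads")

  orient <- function(read_strand, feat_strand) {
    ifelse(feat_strand == "*" | read_strand == feat_strand,
           "sense", "antisense")
  }
  tally <- function(hits_class, hits_orient, hits_weight, classes) {
    out <- expand.grid(class = classes,
                       orientation = c("sense", "antisense"),
                       stringsAsFactors = FALSE)
    key <- paste(hits_class, hits_orient)
    agg <- tapply(hits_weight, key, sum)
    out$count <- as.numeric(agg[paste(out$class, out$orientation)])
    out$count[is.na(out$count)] <- 0
    out$ratio <- out$count / denom
    out
  }

  panels <- list()
  # repeat panel
  rep_classes <- c(.transposon_classes, "other_repeat")
  if (length(repeat_track) > 0L) {
    rcls <- mcols(repeat_track)$attrs %||% mcols(repeat_track)$class
    rcls[!rcls %in% .transposon_classes] <- "other_repeat"
    ov <- findOverlaps(pl, repeat_track, ignore.strand = TRUE)
    panels$repeat_panel <- tally(
      rcls[subjectHits(ov)],
      orient(as.character(strand(pl))[queryHits(ov)],
             as.character(strand(repeat_track))[subjectHits(ov)]),
      mcols(pl)$weight[queryHits(ov)], rep_classes)
  } else {
    panels$repeat_panel <- tally(character(), character(), numeric(), rep_classes)
  }
  panels$repeat_panel$panel <- "repeat"

  # transcript biotype panel (gene-level: one hit per placement x gene)
  bio_classes <- c("protein_coding", "lncRNA", "pseudogene")
  feat_classes <- c("3UTR", "5UTR", "CDS", "exon")
  if (length(transcript_track) > 0L) {
    ov <- findOverlaps(pl, transcript_track, ignore.strand = TRUE)
    q <- queryHits(ov); s <- subjectHits(ov)
    gid <- mcols(transcript_track)$gene_id[s]
    dup <- duplicated(paste(q, gid))
    qb <- q[!dup]; sb <- s[!dup]
    panels$biotype <- tally(
      mcols(transcript_track)$biotype[sb],
      orient(as.character(strand(pl))[qb],
             as.character(strand(transcript_track))[sb]),
      mcols(pl)$weight[qb], bio_classes)

    # feature panel: per placement x gene keep the highest-priority kind
    prio <- match(mcols(transcript_track)$kind[s], feat_classes)
    ord <- order(q, gid, prio)
    keep <- ord[!duplicated(paste(q, gid)[ord])]
    panels$feature <- tally(
      mcols(transcript_track)$kind[s][keep],
      orient(as.character(strand(pl))[q[keep]],
             as.character(strand(transcript_track))[s][keep]),
      mcols(pl)$weight[q[keep]], feat_classes)
  } else {
    panels$biotype <- tally(character(), character(), numeric(), bio_classes)
    panels$feature <- tally(character(), character(), numeric(), feat_classes)
  }
  panels$biotype$panel <- "biotype"
  panels$feature$panel <- "feature"

  out <- do.call(rbind, panels)
  rownames(out) <- NULL
  out[, c("panel", "class", "orientation", "count", "ratio")]
}

#' Transposon-derived piRNA ratio of a context profile
#'
#' Convenience accessor: summed sense+antisense ratio over the four
#' transposon classes (LINE, SINE, LTR, DNA).
#'
#' @param profile output of [profile_context()].
#' @return numeric scalar.
#' @export
transposon_ratio <- function(profile) {
  sum(profile$ratio[profile$panel == "repeat" &
                    profile$class %in% .transposon_classes])
}

#' Gene x sample matrix of piRNA-read counts
#'
#' Per gene and sample, the fraction-weighted (1/x) count of annotated piRNA
#' read placements overlapping any feature of the gene (each placement
#' counted once per gene).
#'
#' @param annotated_samples named list of `annotated_reads`.
#' @param transcript_track GRanges with `gene_id`.
#' @return gene x sample numeric matrix.
#' @export
gene_pirna_counts <- function(annotated_samples, transcript_track) {
  genes <- unique(mcols(transcript_track)$gene_id)
  sids <- names(annotated_samples)
  m <- matrix(0, length(genes), length(sids), dimnames = list(genes, sids))
  for (s in sids) {
    pl <- .pirna_placements(annotated_samples[[s]])
    if (length(pl) == 0L) next
    ov <- findOverlaps(pl, transcript_track, ignore.strand = TRUE)
    if (length(ov) == 0L) next
    gid <- mcols(transcript_track)$gene_id[subjectHits(ov)]
    dup <- duplicated(paste(queryHits(ov), gid))
    agg <- tapply(mcols(pl)$weight[queryHits(ov)[!dup]], gid[!dup], sum)
    m[names(agg), s] <- agg
  }
  m
}

#' Filter genes by the piRNA-aligned-gene standard
#'
#' Stringent: counts > 10 in at least 50% of samples (ceiling for odd n) OR
#' counts > 2 in all samples. Relaxed: counts > 2 in more than 10 samples.
#' All comparisons strict.
#'
#' @param gene_counts gene x sample matrix from [gene_pirna_counts()].
#' @param mode "stringent" or "relaxed".
#' @return character vector of passing gene ids.
#' @export
pirna_aligned_genes <- function(gene_counts, mode = c("stringent", "relaxed")) {
  mode <- match.arg(mode)
  n <- ncol(gene_counts)
  pass <- if (mode == "stringent") {
    rowSums(gene_counts > 10) >= ceiling(n / 2) | rowSums(gene_counts > 2) == n
  } else {
    rowSums(gene_counts > 2) > 10
  }
  rownames(gene_counts)[pass]
}

#' Compare a context ratio between two groups
#'
#' Two-sided Wilcoxon rank-sum test on the per-sample ratios of one
#' class/orientation cell, with significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param profiles_a,profiles_b lists of [profile_context()] outputs (one
#'   per sample; >= 2 each, >= 3 recommended).
#' @param class context class (e.g. "LINE", "pseudogene").
#' @param orientation "sense", "antisense" or "both" (summed).
#' @return data.frame with group medians, W, p-value and `stars`.
#' @export
compare_context <- function(profiles_a, profiles_b, class,
                            orientation = "both") {
  if (length(profiles_a) < 2L || length(profiles_b) < 2L)
    stopf("need at least 2 samples per group")
  pull <- function(p) {
    rows <- p$class == class &
      (orientation == "both" | p$orientation == orientation)
    sum(p$ratio[rows])
  }
  a <- vapply(profiles_a, pull, 0)
  b <- vapply(profiles_b, pull, 0)
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  stars <- if (wt$p.value < 0.001) "***" else if (wt$p.value < 0.01) "**"
           else if (wt$p.value < 0.05) "*" else ""
  data.frame(class = class, orientation = orientation,
             median_a = median(a), median_b = median(b),
             W = unname(wt$statistic), p_value = wt$p.value, stars = stars,
             stringsAsFactors = FALSE)
}
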