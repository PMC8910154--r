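# Size filter / adapter trim, built-in one-mismatch alignment, hierarchical
# classification: reads touching the other-small-ncRNA exclusion track are
# discarded first; only then are the remaining reads annotated against piRNA
# loci. This exclusion-first order is what makes the identification strict.

#' Adapter-trim and size-filter reads
#'
#' If an adapter is configured, the longest read suffix equal to a prefix of
#' the adapter (at least 5 nt, exact match) is removed; reads are then kept
#' only if their length lies in `[min_len, max_len]` (both ends inclusive).
#'
#' @param reads data.frame with `read_id` and `seq` (e.g. from
#'   [read_fastq()]), or a named character vector of sequences.
#' @param adapter adapter sequence, or "" for no trimming.
#' @param min_len,max_len inclusive length window (defaults 20-32 nt).
#' @return list with `reads` (kept rows) and `report` (named counts:
#'   `input`, `trimmed`, `dropped_short`, `dropped_long`, `kept`).
#' @export
trim_and_filter <- function(reads, adapter = "", min_len = 20L, max_len = 32L) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = names(reads) %||% paste0("r", seq_along(reads)),
                        seq = unname(reads), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  if (nzchar(adapter) && nchar(adapter) < 5L)
    stopf("adapter must be at least 5 nt (got %d)", nchar(adapter))
  reads$seq <- toupper(reads$seq)
  n_in <- nrow(reads)
  n_trimmed <- 0L
  if (nzchar(adapter) && n_in > 0L) {
    len <- nchar(reads$seq)
    trim_at <- rep(NA_integer_, n_in)
    # longest suffix of the read matching an adapter prefix, >= 5 nt
    for (ov in seq(min(nchar(adapter), max(len)), 5L)) {
      cand <- is.na(trim_at) & len >= ov
      if (!any(cand)) next
      hit <- substring(reads$seq[cand], len[cand] - ov + 1L, len[cand]) ==
        substr(adapter, 1L, ov)
      trim_at[cand][hit] <- ov
    }
    has <- !is.na(trim_at)
    n_trimmed <- sum(has)
    reads$seq[has] <- substring(reads$seq[has], 1L, len[has] - trim_at[has])
  }
  len <- nchar(reads$seq)
  keep <- len >= min_len & len <= max_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out,
       report = c(input = n_in, trimmed = n_trimmed,
                  dropped_short = sum(len < min_len),
                  dropped_long = sum(len > max_len),
                  kept = sum(keep)))
}

#' Align reads to a genome with the built-in seed aligner
#'
#' Reports every placement with at most `max_mismatch` substitutions on
#' either strand (seed-and-extend with two disjoint 10-mer seeds, which is
#' complete for up to one mismatch). Reads with more than `max_positions`
#' distinct placements are discarded entirely; `x` is the placement count of
#' each kept read.
#'
#' @param reads data.frame with `read_id`, `seq` (all sequences >= 20 nt).
#' @param genome [Biostrings::DNAStringSet] (or named character vector).
#' @param max_mismatch 0 or 1 substitutions per placement.
#' @param max_positions discard reads with more placements than this.
#' @return [aligned_reads()] object (reads with zero placements are absent).
#' @export
mini_align <- function(reads, genome, max_mismatch = 1L, max_positions = 50L) {
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  chrom_names <- names(genome)
  res <- .align_seed_cpp(reads$seq, as.character(genome),
                         as.integer(max_mismatch), as.integer(max_positions))
  .hits_to_aligned(reads, res, chrom_names)
}

# shared conversion from the C++ hit list to an aligned_reads object
.hits_to_aligned <- function(reads, res, chrom_names) {
  if (length(res$read_idx) == 0L) {
    return(aligned_reads(
      data.frame(read_id = character(), seq = character(),
                 length = integer(), x = integer()),
      empty_gr(read_id = character(), mismatches = integer())))
  }
  rid <- reads$read_id[res$read_idx]
  len <- nchar(reads$seq)[res$read_idx]
  pl <- GRanges(chrom_names[res$chrom_idx],
                IRanges(res$start0 + 1L, width = len),
                strand = res$strand, read_id = rid,
                mismatches = res$mismatches)
  x <- table(rid)
  keep <- which(tabulate(res$read_idx, nbins = nrow(reads)) > 0L)
  rt <- data.frame(read_id = reads$read_id[keep], seq = reads$seq[keep],
                   length = nchar(reads$seq)[keep],
                   x = as.integer(x[reads$read_id[keep]]),
                   stringsAsFactors = FALSE)
  aligned_reads(rt, pl)
}

# brute-force oracle wrapper (exhaustive Hamming scan); used by the test
# suite to validate mini_align, never by the pipeline
.brute_align <- function(reads, genome, max_mismatch = 1L, max_positions = 50L) {
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  res <- .align_brute_cpp(reads$seq, as.character(genome),
                          as.integer(max_mismatch), as.integer(max_positions))
  .hits_to_aligned(reads, res, names(genome))
}

#' Classify aligned reads: ncRNA exclusion, then piRNA annotation
#'
#' A read ANY of whose placements overlaps the exclusion track by at least
#' `min_exclude_overlap` bp (either strand) is `excluded_ncRNA` — exclusion
#' strictly precedes annotation. Remaining reads with a placement covered at
#' least `pirna_overlap_frac` of the read length by a piRNA locus
#' (strand-agnostic) are `piRNA`; the rest are `unannotated`. When one
#' placement overlaps several loci the read's 1/x placement weight is split
#' evenly across them (1 / (x * loci-at-placement)), conserving total count
#' mass.
#'
#' @param aligned [aligned_reads()].
#' @param ncrna_track GRanges of other-small-ncRNA loci to exclude.
#' @param pirna_track GRanges of piRNA loci with `label` = piRNA id.
#' @param min_exclude_overlap minimum bp overlap triggering exclusion.
#' @param pirna_overlap_frac minimum fraction of read length inside a locus
#'   for assignment.
#' @return list of class `annotated_reads`: `reads` (with `category`),
#'   `placements`, `assignments` (read_id, pirna_id, weight per
#'   placement-locus pair), `summary` (category counts).
#' @export
classify_reads <- function(aligned, ncrna_track, pirna_track,
                           min_exclude_overlap = 1L,
                           pirna_overlap_frac = 0.5) {
  stopifnot(is(aligned, "aligned_reads"))
  reads <- aligned$reads
  pl <- aligned$placements
  category <- rep("unannotated", nrow(reads))
  names(category) <- reads$read_id

  if (length(ncrna_track) > 0L && length(pl) > 0L) {
    ov <- findOverlaps(pl, ncrna_track, minoverlap = min_exclude_overlap,
                       ignore.strand = TRUE)
    excl <- unique(mcols(pl)$read_id[queryHits(ov)])
    category[excl] <- "excluded_ncRNA"
  }

  assignments <- data.frame(read_id = character(), placement = integer(),
                            pirna_id = character(), loci_at_placement = integer(),
                            x = integer(), weight = numeric())
  if (length(pirna_track) == 0L) {
    warnf("empty piRNA track: all non-excluded reads left unannotated")
  } else if (length(pl) > 0L) {
    ok <- category[mcols(pl)$read_id] != "excluded_ncRNA"
    idx <- which(ok)
    if (length(idx) > 0L) {
      ov <- findOverlaps(pl[idx], pirna_track, ignore.strand = TRUE)
      if (length(ov) > 0L) {
        ow <- width(pintersect(pl[idx][queryHits(ov)],
                               pirna_track[subjectHits(ov)],
                               ignore.strand = TRUE))
        rlen <- width(pl[idx][queryHits(ov)])
        good <- ow >= pirna_overlap_frac * rlen
        if (any(good)) {
          q <- idx[queryHits(ov)[good]]
          pid <- mcols(pirna_track)$label[subjectHits(ov)[good]]
          rid <- mcols(pl)$read_id[q]
          loci_at <- as.integer(table(q)[as.character(q)])
          x <- reads$x[match(rid, reads$read_id)]
          assignments <- data.frame(
            read_id = rid, placement = q, pirna_id = pid,
            loci_at_placement = loci_at, x = x,
            weight = 1 / (x * loci_at), stringsAsFactors = FALSE)
          category[unique(rid)] <- "piRNA"
        }
      }
    }
  }
  reads$category <- unname(category[reads$read_id])
  structure(list(reads = reads, placements = pl, assignments = assignments,
                 summary = c(aligned = nrow(reads),
                             excluded_ncRNA = sum(reads$category == "excluded_ncRNA"),
                             piRNA = sum(reads$category == "piRNA"),
                             unannotated = sum(reads$category == "unannotated"))),
            class = "annotated_reads")
}

#' @export
print.annotated_reads <- function(x, ...) {
  cat("<annotated_reads>", paste(names(x$summary), x$summary, sep = "=",
                                 collapse = ", "), "\n")
  invisible(x)
}

# placements of piRNA-category reads with their 1/x weights; the work table
# for signatures, context and chromosome profiles
.pirna_placements <- function(annotated) {
  stopifnot(is(annotated, "annotated_reads"))
  keep_ids <- annotated$reads$read_id[annotated$reads$category == "piRNA"]
  pl <- annotated$placements[mcols(annotated$placements)$read_id %in% keep_ids]
  x <- annotated$reads$x[match(mcols(pl)$read_id, annotated$reads$read_id)]
  mcols(pl)$x <- x
  mcols(pl)$weight <- 1 / x
  pl
}
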