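# Readers/writers for the external formats the pipeline touches. Internal
# coordinates are GRanges (1-based, closed) everywhere; BED's 0-based
# half-open and GTF's 1-based closed conventions are converted exactly once,
# at the parse/write boundary.

#' Read a FASTA file into a DNAStringSet
#'
#' Sequences are uppercased and header names truncated at the first
#' whitespace. Duplicate chromosome names and empty files are errors.
#'
#' @param path FASTA file.
#' @return [Biostrings::DNAStringSet] with per-chromosome sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  gen <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stopf("malformed FASTA %s: %s", path, conditionMessage(e)))
  if (length(gen) == 0L) stopf("empty FASTA: %s", path)
  names(gen) <- sub("\\s.*$", "", names(gen))
  if (anyDuplicated(names(gen)))
    stopf("duplicate chromosome name(s) in %s: %s", path,
          paste(unique(names(gen)[duplicated(names(gen))]), collapse = ", "))
  Biostrings::DNAStringSet(toupper(gen))
}

#' Write sequences to FASTA
#' @param seqs named character vector or DNAStringSet.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a BED6(+) file into a GRanges
#'
#' BED stores 0-based half-open intervals; the returned GRanges is 1-based
#' closed. The first six columns map to chrom/start/end/label/score/strand;
#' any further columns are kept in `mcols()$attrs` (tab-joined). Empty or
#' inverted intervals are an error naming the offending line.
#'
#' @param path BED file.
#' @return GRanges with mcols `label`, `score`, `attrs`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(empty_gr(label = character(), score = numeric(), attrs = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stopf("BED line %d has %d fields; BED6(+) required", lineno[which(nf < 6L)[1]],
          nf[nf < 6L][1])
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0) | start0 < 0L | start0 >= end0
  if (any(bad))
    stopf("BED line %d: invalid interval (start must satisfy 0 <= start < end)",
          lineno[which(bad)[1]])
  strand <- vapply(fields, `[[`, "", 6L)
  if (!all(strand %in% c("+", "-", ".")))
    stopf("BED line %d: strand must be +, - or .",
          lineno[which(!strand %in% c("+", "-", "."))[1]])
  attrs <- vapply(fields, function(f)
    if (length(f) > 6L) paste(f[-(1:6)], collapse = "\t") else "", "")
  GRanges(chrom, IRanges(start0 + 1L, end0),
          strand = ifelse(strand == ".", "*", strand),
          label = vapply(fields, `[[`, "", 4L),
          score = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L))),
          attrs = attrs)
}

#' Write a GRanges as BED6(+)
#'
#' Inverse of [read_bed()]: coordinates converted back to 0-based half-open.
#'
#' @param gr GRanges; mcols `label`, `score`, `attrs` used if present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  m <- mcols(gr)
  label <- if ("label" %in% names(m)) m$label else rep(".", length(gr))
  score <- if ("score" %in% names(m)) m$score else rep(0, length(gr))
  score[is.na(score)] <- 0
  str <- as.character(strand(gr))
  str[str == "*"] <- "."
  lines <- paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                 label, score, str, sep = "\t")
  if ("attrs" %in% names(m)) {
    has <- !is.na(m$attrs) & nzchar(m$attrs)
    lines[has] <- paste(lines[has], m$attrs[has], sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

# feature-kind normalization used by the GTF reader and the generator
.kind_map <- c(CDS = "CDS", exon = "exon",
               three_prime_utr = "3UTR", five_prime_utr = "5UTR")
.known_biotypes <- c("protein_coding", "lncRNA", "pseudogene")

#' Read transcript features from an Ensembl-dialect GTF
#'
#' Keeps CDS/exon/UTR features, normalizes feature kinds (three_prime_utr ->
#' "3UTR", five_prime_utr -> "5UTR") and buckets gene biotypes into
#' protein_coding / lncRNA / pseudogene / other ("*pseudogene*" biotypes all
#' map to pseudogene). Coordinates arrive 1-based closed and stay that way in
#' the GRanges.
#'
#' @param path GTF file.
#' @return GRanges with mcols `gene_id`, `kind`, `biotype`.
#' @export
read_gtf_features <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) %in% names(.kind_map)]
  if (length(gr) == 0L) {
    warnf("no CDS/exon/UTR features in %s", path)
  }
  gid <- gr$gene_id
  if (is.null(gid) || anyNA(gid) || any(!nzchar(gid)))
    stopf("GTF %s: feature(s) missing the gene_id attribute", path)
  bt <- gr$gene_biotype %||% rep(NA_character_, length(gr))
  bt[is.na(bt)] <- "other"
  bt[grepl("pseudogene", bt)] <- "pseudogene"
  bt[!bt %in% .known_biotypes] <- "other"
  out <- granges(gr)
  mcols(out) <- DataFrame(gene_id = gid,
                          kind = unname(.kind_map[as.character(gr$type)]),
                          biotype = bt)
  out
}

#' Write transcript features as Ensembl-dialect GTF
#'
#' Inverse of [read_gtf_features()] for the feature kinds it understands.
#'
#' @param gr GRanges with mcols `gene_id`, `kind`, `biotype`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gr, path) {
  rev_kind <- setNames(names(.kind_map), .kind_map)
  str <- as.character(strand(gr))
  str[str == "*"] <- "."
  lines <- paste(as.character(seqnames(gr)), "somapiR",
                 rev_kind[mcols(gr)$kind], start(gr), end(gr), ".", str, ".",
                 sprintf('gene_id "%s"; gene_biotype "%s";',
                         mcols(gr)$gene_id, mcols(gr)$biotype),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Container for aligned small-RNA reads
#'
#' Each read appears once, with all of its genome placements; `x` is the
#' number of reported placements and drives the 1/x fractional counting used
#' throughout the pipeline.
#'
#' @param reads data.frame with columns `read_id`, `seq`, `length`, `x`.
#' @param placements GRanges with mcols `read_id`, `mismatches`.
#' @return object of class `aligned_reads`.
#' @export
aligned_reads <- function(reads, placements) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "seq", "length", "x") %in% names(reads)),
            is(placements, "GRanges"),
            all(c("read_id", "mismatches") %in% names(mcols(placements))))
  if (anyDuplicated(reads$read_id)) stopf("duplicate read_id in reads table")
  if (!all(mcols(placements)$read_id %in% reads$read_id))
    stopf("placements reference unknown read_id(s)")
  structure(list(reads = reads, placements = placements),
            class = "aligned_reads")
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat(sprintf("<aligned_reads> %d reads, %d placements (max x = %s)\n",
              nrow(x$reads), length(x$placements),
              if (nrow(x$reads)) max(x$reads$x) else "NA"))
  invisible(x)
}

#' Read alignments from SAM/BAM into an `aligned_reads` object
#'
#' Multi-mapped reads must be separate records sharing a QNAME; they are
#' grouped into one read with a placement list and `x` = placement count.
#' Unmapped records are dropped. Plain-text SAM is converted via
#' [Rsamtools::asBam()] in a temporary directory.
#'
#' @param path SAM or BAM file.
#' @return `aligned_reads`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    hdr <- readLines(path, n = 1L)
    if (!startsWith(hdr, "@")) stopf("SAM %s has no header", path)
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "seq"),
    tag = "NM")
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- bitwAnd(rec$flag, 4L) == 0L & !is.na(rec$pos)
  if (!any(mapped)) {
    return(aligned_reads(
      data.frame(read_id = character(), seq = character(),
                 length = integer(), x = integer()),
      empty_gr(read_id = character(), mismatches = integer())))
  }
  qname <- rec$qname[mapped]
  seqs <- as.character(rec$seq)[mapped]
  str <- as.character(rec$strand)[mapped]
  # BAM stores the plus-strand sequence; recover the read as sequenced
  seqs[str == "-"] <- revcomp_chr(seqs[str == "-"])
  nm <- rec$tag$NM[mapped]
  if (is.null(nm)) nm <- rep(0L, sum(mapped))
  nm[is.na(nm)] <- 0L
  len <- nchar(seqs)
  pl <- GRanges(as.character(rec$rname)[mapped],
                IRanges(rec$pos[mapped], width = len),
                strand = str, read_id = qname, mismatches = nm)
  x <- table(qname)
  firsts <- !duplicated(qname)
  reads <- data.frame(read_id = qname[firsts], seq = seqs[firsts],
                      length = len[firsts],
                      x = as.integer(x[qname[firsts]]),
                      stringsAsFactors = FALSE)
  aligned_reads(reads, pl)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (set name, description, then gene ids; tab-separated).
#' @return named list of unique gene-id character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stopf("GMT line %d has an empty gene list", bad[1])
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stopf("duplicate gene-set name(s): %s",
          paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  sets
}

#' Read a sample sheet TSV
#'
#' @param path TSV with columns `sample`, `group`, `tissue`, `batch`
#'   (batch may be empty).
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  ss <- read_tsv_prologue(path)
  need <- c("sample", "group", "tissue")
  if (!all(need %in% names(ss)))
    stopf("sample sheet must have columns %s", paste(need, collapse = ", "))
  if (!"batch" %in% names(ss)) ss$batch <- ""
  if (anyDuplicated(ss$sample)) stopf("duplicate sample ids in sample sheet")
  if (length(unique(ss$group)) < 1L || nrow(ss) == 0L)
    stopf("sample sheet needs at least one sample and one group")
  ss
}

#' Write reads as FASTQ (constant quality)
#' @param reads data.frame with `read_id`, `seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$seq), function(n) strrep("I", n), "")
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", qual), path)
  invisible(path)
}

#' Read a FASTQ file (sequences only; qualities pass through unused)
#' @param path FASTQ file.
#' @return data.frame with `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("FASTQ file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stopf("truncated FASTQ: %s", path)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, length(lines), by = 4)]))
  data.frame(read_id = ids, seq = toupper(lines[seq(2, length(lines), by = 4)]),
             stringsAsFactors = FALSE)
}
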