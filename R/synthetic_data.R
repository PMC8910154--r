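# Synthetic small-RNA cohorts: a random genome with planted piRNA loci (in
# transposon, 3'UTR, pseudogene, lncRNA and intergenic contexts), decoy
# small-ncRNA loci, duplicated sequence for multi-mapping, and per-sample
# reads with log-normal library sizes, group-wise fold changes, and (for
# germline-like samples) ping-pong mate pairs with 1U/10A bias. Reads are
# exact genome substrings; mismatches are introduced only by the explicit
# `mutate_fraction` knob so the aligner's 1-mismatch tolerance can be tested
# in isolation.

#' Build a validated simulation configuration
#'
#' Defaults emulate a desk-scale two-group somatic brain cohort (14 control +
#' 14 disease samples, matching the amygdala cohort design) with 10% of
#' piRNA loci planted at a 4-fold change in the disease group. Germline-like
#' groups (set `germline = TRUE`) draw longer reads (24-32 nt), a 5'U start
#' bias, and ping-pong mate pairs with exactly 10 nt of 5'-overlap;
#' somatic-like groups draw 20-30 nt reads with no planted biases.
#'
#' @param seed integer RNG seed; identical configs give byte-identical
#'   cohorts.
#' @param n_chroms,chrom_len genome shape.
#' @param n_pirna_loci number of planted piRNA loci (length
#'   `pirna_locus_len`).
#' @param pirna_locus_len piRNA locus length in nt.
#' @param n_decoy_ncrna decoy tRNA/rRNA/miRNA/snoRNA loci that downstream
#'   analysis must exclude.
#' @param n_repeats named vector of repeat-locus counts per class
#'   (LINE/SINE/LTR/DNA/simple_repeat).
#' @param n_genes,n_lncrna,n_pseudogenes transcript loci; pseudogenes are
#'   sequence copies of genes (a natural multi-mapping source).
#' @param utr3_repeat_fraction share of protein-coding genes carrying a
#'   transposon fragment inside their 3'UTR.
#' @param pirna_context named fractions over
#'   LINE/SINE/LTR/DNA/three_utr/pseudogene/lncRNA/intergenic; where each
#'   piRNA locus is planted.
#' @param antisense_fraction probability a repeat-hosted piRNA locus is
#'   antisense to its host.
#' @param pirna_len_range_germline,pirna_len_range_somatic read-length ranges.
#' @param groups list of `list(name, n_samples, germline, de)`; groups with
#'   `de = TRUE` get `n_de_loci` loci at `fold_change`.
#' @param n_de_loci,fold_change planted differential expression.
#' @param pingpong `list(enabled, pair_fraction)`: fraction of germline locus
#'   draws emitted as a primary + 10-nt-5'-overlap mate pair.
#' @param bias `list(u1_fraction, a10_fraction)`: probability of a U/T 5'
#'   start for unpaired (u1) and paired (a10; the mate's 10th base is then A
#'   by complementarity) germline primaries.
#' @param libsize_lognormal `list(meanlog, sigma)` for per-sample read
#'   totals.
#' @param multimap_fraction share of intergenic piRNA loci duplicated to a
#'   second locus (reads map twice).
#' @param decoy_fraction share of each library drawn from decoy ncRNA loci.
#' @param abundance_sdlog log-sd of baseline locus abundances.
#' @param bio_sdlog per-sample log-normal biological noise on locus
#'   expression.
#' @param mutate_fraction share of reads given exactly one substitution.
#' @param adapter 3' adapter appended to every read ("" = none).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_len = 100000L,
                       n_pirna_loci = 200L, pirna_locus_len = 60L,
                       n_decoy_ncrna = 40L,
                       n_repeats = c(LINE = 12L, SINE = 12L, LTR = 8L,
                                     DNA = 8L, simple_repeat = 8L),
                       n_genes = 30L, n_lncrna = 10L, n_pseudogenes = 8L,
                       utr3_repeat_fraction = 0.25,
                       pirna_context = c(LINE = 0.08, SINE = 0.08, LTR = 0.04,
                                         DNA = 0.05, three_utr = 0.15,
                                         pseudogene = 0.10, lncRNA = 0.05,
                                         intergenic = 0.45),
                       antisense_fraction = 0.5,
                       pirna_len_range_germline = c(24L, 32L),
                       pirna_len_range_somatic = c(20L, 30L),
                       groups = list(
                         list(name = "control", n_samples = 14L,
                              germline = FALSE, de = FALSE),
                         list(name = "PD", n_samples = 14L,
                              germline = FALSE, de = TRUE)),
                       n_de_loci = 20L, fold_change = 4,
                       pingpong = list(enabled = TRUE, pair_fraction = 0.3),
                       bias = list(u1_fraction = 0.75, a10_fraction = 0.75),
                       libsize_lognormal = list(meanlog = log(20000), sigma = 0.25),
                       multimap_fraction = 0.1,
                       decoy_fraction = 0.25,
                       abundance_sdlog = 1.0,
                       bio_sdlog = 0.5,
                       mutate_fraction = 0,
                       adapter = "") {
  cfg <- as.list(environment())
  fr <- c(cfg$pirna_context, cfg$multimap_fraction, cfg$decoy_fraction,
          cfg$pingpong$pair_fraction, cfg$bias$u1_fraction,
          cfg$bias$a10_fraction, cfg$antisense_fraction, cfg$mutate_fraction,
          cfg$utr3_repeat_fraction)
  if (any(fr < 0 | fr > 1)) stopf("all fractions must lie in [0, 1]")
  if (abs(sum(cfg$pirna_context) - 1) > 1e-8)
    stopf("pirna_context fractions must sum to 1")
  if (cfg$fold_change <= 0) stopf("fold_change must be > 0")
  if (cfg$n_chroms < 1L || cfg$chrom_len < 2000L)
    stopf("need n_chroms >= 1 and chrom_len >= 2000")
  nm <- vapply(cfg$groups, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("group names must be unique")
  if (nzchar(cfg$adapter) && nchar(cfg$adapter) < 5L)
    stopf("adapter must be at least 5 nt")
  structure(cfg, class = "sim_config")
}

# occupancy-based non-overlapping placement of a locus of length len
.place_locus <- function(occ, len, margin = 100L, max_tries = 2000L) {
  chroms <- names(occ)
  for (i in seq_len(max_tries)) {
    ch <- sample(chroms, 1L)
    L <- length(occ[[ch]])
    lo <- margin + 1L
    hi <- L - margin - len
    if (hi <= lo) next
    s <- sample(lo:hi, 1L)
    if (!any(occ[[ch]][s:(s + len - 1L)])) {
      return(list(chrom = ch, start = s, end = s + len - 1L))
    }
  }
  stopf("could not place a %d-nt locus: requested loci do not fit the genome", len)
}

.random_chrom <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a genome and its annotation tracks
#'
#' Plants non-overlapping repeat, gene (with 5'UTR/CDS/3'UTR/exon features),
#' lncRNA, pseudogene (sequence copies of genes) and decoy-ncRNA loci, then
#' nests piRNA loci inside the configured contexts. A configurable share of
#' protein-coding genes carries a transposon fragment inside its 3'UTR, and a
#' share of intergenic piRNA loci is sequence-duplicated to create
#' multi-mapping reads.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (DNAStringSet), `tracks` (GRanges: `pirna`,
#'   `ncrna`, `repeats`, `transcripts`), `locus_info` (per-piRNA-locus truth:
#'   context class/orientation, duplication partner), `fold_changes`
#'   (locus x group matrix) and the `cfg`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(is(cfg, "sim_config"))
  set.seed(cfg$seed)
  chrom_names <- paste0("chr", seq_len(cfg$n_chroms))
  seqs <- setNames(lapply(chrom_names, function(x) .random_chrom(cfg$chrom_len)),
                   chrom_names)
  occ <- setNames(lapply(chrom_names, function(x) rep(FALSE, cfg$chrom_len)),
                  chrom_names)
  mark <- function(p) occ[[p$chrom]][p$start:p$end] <<- TRUE

  # --- repeats ------------------------------------------------------------
  rep_len <- c(LINE = 300L, SINE = 150L, LTR = 200L, DNA = 250L,
               simple_repeat = 60L)
  rep_rows <- list()
  for (cls in names(cfg$n_repeats)) {
    for (i in seq_len(cfg$n_repeats[[cls]])) {
      p <- .place_locus(occ, rep_len[[cls]])
      mark(p)
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(chrom = p$chrom, start = p$start, end = p$end,
                   strand = sample(c("+", "-"), 1L),
                   label = sprintf("%s_%d", cls, i), class = cls)
    }
  }
  repeats <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), label = character(), class = character())

  # --- protein-coding genes (5'UTR 100 / CDS 600 / 3'UTR 300, exon = span) --
  gene_rows <- list()
  for (i in seq_len(cfg$n_genes)) {
    p <- .place_locus(occ, 1000L)
    mark(p)
    st <- sample(c("+", "-"), 1L)
    g <- sprintf("gene%03d", i)
    if (st == "+") {
      seg <- data.frame(start = p$start + c(0L, 100L, 700L),
                        end = p$start + c(99L, 699L, 999L),
                        kind = c("5UTR", "CDS", "3UTR"))
    } else {
      seg <- data.frame(start = p$start + c(0L, 300L, 900L),
                        end = p$start + c(299L, 899L, 999L),
                        kind = c("3UTR", "CDS", "5UTR"))
    }
    seg <- rbind(seg, data.frame(start = p$start, end = p$end, kind = "exon"))
    seg$chrom <- p$chrom; seg$strand <- st
    seg$gene_id <- g; seg$biotype <- "protein_coding"
    gene_rows[[i]] <- seg
  }
  genes <- do.call(rbind, gene_rows)

  # --- lncRNAs (single exon) ----------------------------------------------
  lnc_rows <- list()
  for (i in seq_len(cfg$n_lncrna)) {
    p <- .place_locus(occ, 800L)
    mark(p)
    lnc_rows[[i]] <- data.frame(chrom = p$chrom, start = p$start, end = p$end,
                                strand = sample(c("+", "-"), 1L), kind = "exon",
                                gene_id = sprintf("lnc%03d", i),
                                biotype = "lncRNA")
  }
  lnc <- if (length(lnc_rows)) do.call(rbind, lnc_rows) else NULL

  # --- pseudogenes: sequence copies of whole genes ------------------------
  pg_rows <- list()
  pg_parents <- if (cfg$n_pseudogenes > 0L)
    sample(unique(genes$gene_id), cfg$n_pseudogenes, replace = cfg$n_pseudogenes > cfg$n_genes)
  else character()
  for (i in seq_along(pg_parents)) {
    p <- .place_locus(occ, 1000L)
    mark(p)
    par <- genes[genes$gene_id == pg_parents[i] & genes$kind == "exon", ]
    seqs[[p$chrom]] <- paste0(
      substr(seqs[[p$chrom]], 1L, p$start - 1L),
      substr(seqs[[par$chrom]], par$start, par$end),
      substr(seqs[[p$chrom]], p$end + 1L, nchar(seqs[[p$chrom]])))
    pg_rows[[i]] <- data.frame(chrom = p$chrom, start = p$start, end = p$end,
                               strand = par$strand, kind = "exon",
                               gene_id = sprintf("pg%03d_%s", i, pg_parents[i]),
                               biotype = "pseudogene")
  }
  pg <- if (length(pg_rows)) do.call(rbind, pg_rows) else NULL

  # --- transposon fragments inside some 3'UTRs ----------------------------
  utr3 <- genes[genes$kind == "3UTR", ]
  n_frag <- round(cfg$utr3_repeat_fraction * nrow(utr3))
  tp <- repeats[repeats$class %in% c("LINE", "SINE", "LTR", "DNA"), ]
  if (n_frag > 0L && nrow(tp) > 0L) {
    frag_genes <- sample(seq_len(nrow(utr3)), n_frag)
    for (gi in frag_genes) {
      src <- tp[sample(nrow(tp), 1L), ]
      fs <- src$start + sample.int(rep_len[[src$class]] - 80L, 1L) - 1L
      frag <- substr(seqs[[src$chrom]], fs, fs + 79L)
      dst <- utr3[gi, ]
      ds <- dst$start + 100L
      seqs[[dst$chrom]] <- paste0(
        substr(seqs[[dst$chrom]], 1L, ds - 1L), frag,
        substr(seqs[[dst$chrom]], ds + 80L, nchar(seqs[[dst$chrom]])))
    }
  }

  # --- decoy ncRNA loci ---------------------------------------------------
  decoy_classes <- rep(c("tRNA", "rRNA", "miRNA", "snoRNA"),
                       length.out = cfg$n_decoy_ncrna)
  dec_rows <- list()
  for (i in seq_len(cfg$n_decoy_ncrna)) {
    p <- .place_locus(occ, 70L)
    mark(p)
    dec_rows[[i]] <- data.frame(chrom = p$chrom, start = p$start, end = p$end,
                                strand = sample(c("+", "-"), 1L),
                                label = sprintf("%s_%d", decoy_classes[i], i),
                                class = decoy_classes[i])
  }
  decoys <- if (length(dec_rows)) do.call(rbind, dec_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), label = character(), class = character())

  # --- piRNA loci: nested in hosts or intergenic --------------------------
  ctx <- sample(names(cfg$pirna_context), cfg$n_pirna_loci, replace = TRUE,
                prob = cfg$pirna_context)
  pocc <- setNames(lapply(chrom_names, function(x) rep(FALSE, cfg$chrom_len)),
                   chrom_names)  # piRNA loci may overlap hosts but not each other
  L <- cfg$pirna_locus_len
  pick_inside <- function(host) {
    span <- host$end - host$start + 1L
    for (i in seq_len(200L)) {
      s <- host$start + sample.int(span - L + 1L, 1L) - 1L
      if (!any(pocc[[host$chrom]][s:(s + L - 1L)]))
        return(list(chrom = host$chrom, start = s, end = s + L - 1L))
    }
    NULL
  }
  info <- list()
  for (i in seq_len(cfg$n_pirna_loci)) {
    id <- sprintf("piR-syn-%06d", i)
    cls <- ctx[i]
    row <- NULL
    if (cls %in% c("LINE", "SINE", "LTR", "DNA")) {
      hosts <- repeats[repeats$class == cls, ]
      host <- hosts[sample(nrow(hosts), 1L), ]
      p <- pick_inside(host)
      if (!is.null(p)) {
        anti <- runif(1) < cfg$antisense_fraction
        st <- if (anti) setdiff(c("+", "-"), host$strand) else host$strand
        row <- data.frame(locus_id = id, chrom = p$chrom, start = p$start,
                          end = p$end, strand = st, context_class = cls,
                          context_orientation = if (anti) "antisense" else "sense",
                          host = host$label, duplicate_of = NA_character_)
      }
    } else if (cls == "three_utr") {
      host <- utr3[sample(nrow(utr3), 1L), ]
      p <- pick_inside(host)
      if (!is.null(p))
        row <- data.frame(locus_id = id, chrom = p$chrom, start = p$start,
                          end = p$end, strand = host$strand,
                          context_class = "three_utr",
                          context_orientation = "sense",
                          host = host$gene_id, duplicate_of = NA_character_)
    } else if (cls == "pseudogene" && !is.null(pg)) {
      host <- pg[sample(nrow(pg), 1L), ]
      p <- pick_inside(host)
      if (!is.null(p))
        row <- data.frame(locus_id = id, chrom = p$chrom, start = p$start,
                          end = p$end, strand = host$strand,
                          context_class = "pseudogene",
                          context_orientation = "sense",
                          host = host$gene_id, duplicate_of = NA_character_)
    } else if (cls == "lncRNA" && !is.null(lnc)) {
      host <- lnc[sample(nrow(lnc), 1L), ]
      p <- pick_inside(host)
      if (!is.null(p))
        row <- data.frame(locus_id = id, chrom = p$chrom, start = p$start,
                          end = p$end, strand = host$strand,
                          context_class = "lncRNA",
                          context_orientation = "sense",
                          host = host$gene_id, duplicate_of = NA_character_)
    }
    if (is.null(row)) {  # intergenic (or fallback when a host was full)
      p <- .place_locus(occ, L)
      mark(p)
      row <- data.frame(locus_id = id, chrom = p$chrom, start = p$start,
                        end = p$end, strand = sample(c("+", "-"), 1L),
                        context_class = "intergenic",
                        context_orientation = NA_character_,
                        host = NA_character_, duplicate_of = NA_character_)
    }
    pocc[[row$chrom]][row$start:row$end] <- TRUE
    info[[i]] <- row
  }
  info <- do.call(rbind, info)

  # --- duplicate a share of intergenic loci for multi-mapping -------------
  inter <- which(info$context_class == "intergenic")
  n_dup <- round(cfg$multimap_fraction * length(inter))
  if (n_dup > 0L) {
    dup_src <- sample(inter, n_dup)
    for (j in seq_along(dup_src)) {
      src <- info[dup_src[j], ]
      p <- .place_locus(occ, L)
      mark(p)
      seqs[[p$chrom]] <- paste0(
        substr(seqs[[p$chrom]], 1L, p$start - 1L),
        substr(seqs[[src$chrom]], src$start, src$end),
        substr(seqs[[p$chrom]], p$end + 1L, nchar(seqs[[p$chrom]])))
      info <- rbind(info, data.frame(
        locus_id = sprintf("piR-syn-%06d", nrow(info) + 1L),
        chrom = p$chrom, start = p$start, end = p$end, strand = src$strand,
        context_class = "intergenic", context_orientation = NA_character_,
        host = NA_character_, duplicate_of = src$locus_id))
      info$duplicate_of[info$locus_id == src$locus_id] <-
        info$locus_id[nrow(info)]
    }
  }
  rownames(info) <- NULL

  # --- fold changes -------------------------------------------------------
  gnames <- vapply(cfg$groups, `[[`, "", "name")
  fc <- matrix(1, nrow(info), length(gnames),
               dimnames = list(info$locus_id, gnames))
  de_idx <- sample(nrow(info), min(cfg$n_de_loci, nrow(info)))
  for (g in seq_along(cfg$groups)) {
    if (isTRUE(cfg$groups[[g]]$de)) fc[de_idx, g] <- cfg$fold_change
  }

  genome <- Biostrings::DNAStringSet(vapply(seqs, identity, ""))
  tx <- rbind(genes, if (!is.null(lnc)) lnc, if (!is.null(pg)) pg)
  tracks <- list(
    pirna = GRanges(info$chrom, IRanges(info$start, info$end),
                    strand = info$strand, label = info$locus_id,
                    score = rep(0, nrow(info)), attrs = rep("", nrow(info))),
    ncrna = GRanges(decoys$chrom, IRanges(decoys$start, decoys$end),
                    strand = decoys$strand, label = decoys$label,
                    score = rep(0, nrow(decoys)), attrs = decoys$class),
    repeats = GRanges(repeats$chrom, IRanges(repeats$start, repeats$end),
                      strand = repeats$strand, label = repeats$label,
                      score = rep(0, nrow(repeats)), attrs = repeats$class),
    transcripts = GRanges(tx$chrom, IRanges(tx$start, tx$end),
                          strand = tx$strand, gene_id = tx$gene_id,
                          kind = tx$kind, biotype = tx$biotype))
  list(genome = genome, tracks = tracks, locus_info = info,
       fold_changes = fc, cfg = cfg)
}

# vectorized draw of n offsets from `lo..hi`, each independently T-biased
# with probability `bias` (restricted to `t_offs`, the offsets whose 5' base
# is T on the read strand)
.draw_offsets <- function(n, lo, hi, t_offs, bias) {
  off <- lo + floor(runif(n) * (hi - lo + 1L))
  if (bias > 0 && length(t_offs) > 0L) {
    b <- runif(n) < bias
    if (any(b)) off[b] <- t_offs[ceiling(runif(sum(b)) * length(t_offs))]
  }
  as.integer(off)
}

.mutate_one <- function(seq) {
  i <- sample.int(nchar(seq), 1L)
  old <- substring(seq, i, i)
  substring(seq, i, i) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  seq
}

#' Simulate per-sample reads from a synthetic genome
#'
#' Draws per-sample library sizes (log-normal), splits each library between
#' decoy-ncRNA loci and piRNA loci, and samples locus counts from a
#' multinomial over baseline abundance x group fold change x per-sample
#' biological noise. Germline-like samples emit, for `pair_fraction` of
#' piRNA-locus draws, a primary read plus an opposite-strand mate whose 5'
#' end gives exactly 10 nt of 5'-overlap (so a 1U primary implies a 10A
#' mate). Reads are exact genome substrings unless `mutate_fraction` > 0.
#'
#' @param cfg a [sim_config()].
#' @param sim output of [simulate_genome()].
#' @return list with `samples` (named list of read data.frames: `read_id`,
#'   `seq`, `source_locus`, `source_class`, `is_mate`), `sample_sheet`,
#'   and `truth` (`reads` long table, `locus_means` with per-group expected
#'   count fractions and means, `pairs` per-sample planted mate-pair counts).
#' @export
simulate_reads <- function(cfg, sim) {
  stopifnot(is(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  info <- sim$locus_info
  seqs <- as.character(sim$genome)
  nloc <- nrow(info)
  baseline <- rlnorm(nloc, meanlog = 0, sdlog = cfg$abundance_sdlog)
  names(baseline) <- info$locus_id
  decoys <- as.data.frame(sim$tracks$ncrna)
  decoy_base <- rlnorm(nrow(decoys), 0, cfg$abundance_sdlog)

  gnames <- vapply(cfg$groups, `[[`, "", "name")
  exp_libsize <- exp(cfg$libsize_lognormal$meanlog +
                     cfg$libsize_lognormal$sigma^2 / 2)
  locus_means <- do.call(rbind, lapply(seq_along(gnames), function(g) {
    w <- baseline * sim$fold_changes[, g]
    data.frame(locus_id = info$locus_id, group = gnames[g],
               expected_fraction = w / sum(w),
               expected_count = w / sum(w) * (1 - cfg$decoy_fraction) * exp_libsize)
  }))

  span <- cfg$pirna_locus_len
  # 5' offsets are confined to 0..(span - maxlen) so offset and length can be
  # drawn independently; pair primaries start at >= 14 so the mate's 10-nt
  # 5'-overlap geometry keeps the mate >= 50% inside the locus
  t_offsets <- function(chrom_seq, anchor5, strand, lo, hi) {
    offs <- lo:hi
    pos5 <- if (strand == "+") anchor5 + offs else anchor5 - offs
    b <- substring(chrom_seq, pos5, pos5)
    offs[if (strand == "+") b == "T" else b == "A"]
  }

  samples <- list()
  sheet <- list()
  truth_rows <- list()
  pair_rows <- list()
  for (g in seq_along(cfg$groups)) {
    grp <- cfg$groups[[g]]
    lrange <- if (isTRUE(grp$germline)) cfg$pirna_len_range_germline
              else cfg$pirna_len_range_somatic
    maxlen <- lrange[2]
    off_hi <- span - maxlen
    if (off_hi < 14L)
      stopf("pirna_locus_len must be >= max read length + 14 for mate geometry")
    pair_frac <- if (isTRUE(grp$germline) && isTRUE(cfg$pingpong$enabled))
      cfg$pingpong$pair_fraction else 0
    u1 <- if (isTRUE(grp$germline)) cfg$bias$u1_fraction else 0
    a10 <- if (isTRUE(grp$germline)) cfg$bias$a10_fraction else 0
    for (s in seq_len(grp$n_samples)) {
      sid <- sprintf("%s_s%02d", grp$name, s)
      N <- max(100L, round(rlnorm(1, cfg$libsize_lognormal$meanlog,
                                  cfg$libsize_lognormal$sigma)))
      n_decoy <- rbinom(1L, N, cfg$decoy_fraction)
      w <- baseline * sim$fold_changes[, g] * rlnorm(nloc, 0, cfg$bio_sdlog)
      counts <- as.integer(rmultinom(1L, N - n_decoy, w))
      dcounts <- as.integer(rmultinom(1L, n_decoy, decoy_base))

      # per-event vectors, filled locus by locus
      ev <- list(chrom = list(), strand = list(), p5 = list(), len = list(),
                 src = list(), mate = list())
      push <- function(chrom, strand, p5, len, src, mate) {
        n <- length(p5)
        i <- length(ev$p5) + 1L
        ev$chrom[[i]] <<- rep(chrom, n); ev$strand[[i]] <<- rep(strand, n)
        ev$p5[[i]] <<- p5; ev$len[[i]] <<- len
        ev$src[[i]] <<- rep(src, n); ev$mate[[i]] <<- rep(mate, n)
      }
      npairs <- 0L
      for (li in which(counts > 0L)) {
        loc <- info[li, ]
        cs <- seqs[[loc$chrom]]
        anchor5 <- if (loc$strand == "+") loc$start else loc$end
        n <- counts[li]
        is_pair <- runif(n) < pair_frac
        n_p <- sum(is_pair); n_u <- n - n_p
        if (n_u > 0L) {
          toff <- t_offsets(cs, anchor5, loc$strand, 0L, off_hi)
          off <- .draw_offsets(n_u, 0L, off_hi, toff, u1)
          p5 <- if (loc$strand == "+") anchor5 + off else anchor5 - off
          len <- lrange[1] + floor(runif(n_u) * (lrange[2] - lrange[1] + 1L))
          push(loc$chrom, loc$strand, p5, as.integer(len), loc$locus_id, FALSE)
        }
        if (n_p > 0L) {
          toff <- t_offsets(cs, anchor5, loc$strand, 14L, off_hi)
          off <- .draw_offsets(n_p, 14L, off_hi, toff, a10)
          p5 <- if (loc$strand == "+") anchor5 + off else anchor5 - off
          plen <- lrange[1] + floor(runif(n_p) * (lrange[2] - lrange[1] + 1L))
          push(loc$chrom, loc$strand, p5, as.integer(plen), loc$locus_id, FALSE)
          mstrand <- if (loc$strand == "+") "-" else "+"
          m5 <- if (loc$strand == "+") p5 + 9L else p5 - 9L
          mmax <- pmin(lrange[2], off + 10L)
          mlen <- lrange[1] + floor(runif(n_p) * (mmax - lrange[1] + 1L))
          push(loc$chrom, mstrand, m5, as.integer(mlen), loc$locus_id, TRUE)
          npairs <- npairs + n_p
        }
      }
      for (di in which(dcounts > 0L)) {
        d <- decoys[di, ]
        n <- dcounts[di]
        st <- as.character(d$strand)
        len <- 20L + floor(runif(n) * 13)  # 20..32
        off <- floor(runif(n) * (d$end - d$start + 2L - len))
        p5 <- if (st == "+") d$start + off else d$end - off
        push(as.character(d$seqnames), st, as.integer(p5), as.integer(len),
             d$label, FALSE)
      }

      chrom <- unlist(ev$chrom); strand <- unlist(ev$strand)
      p5 <- unlist(ev$p5); len <- unlist(ev$len)
      src <- unlist(ev$src); mate <- unlist(ev$mate)
      plus <- strand == "+"
      rstart <- ifelse(plus, p5, p5 - len + 1L)
      rend <- rstart + len - 1L
      fseq <- substring(unlist(seqs[chrom], use.names = FALSE), rstart, rend)
      if (any(!plus)) fseq[!plus] <- revcomp_chr(fseq[!plus])
      k <- length(p5)
      if (cfg$mutate_fraction > 0 && k > 0L) {
        mut <- runif(k) < cfg$mutate_fraction
        fseq[mut] <- vapply(fseq[mut], .mutate_one, "")
      }
      if (nzchar(cfg$adapter)) fseq <- paste0(fseq, cfg$adapter)
      reads <- data.frame(
        read_id = sprintf("%s_r%06d", sid, seq_len(k)),
        seq = fseq, source_locus = src,
        source_class = ifelse(startsWith(src, "piR-"), "pirna", "decoy_ncrna"),
        is_mate = mate, stringsAsFactors = FALSE)
      samples[[sid]] <- reads
      sheet[[sid]] <- data.frame(
        sample = sid, group = grp$name,
        tissue = if (isTRUE(grp$germline)) "germline_like" else "somatic_like",
        batch = "")
      truth_rows[[sid]] <- cbind(sample = sid, reads[, c("read_id",
        "source_locus", "source_class", "is_mate")])
      pair_rows[[sid]] <- data.frame(sample = sid, n_pairs = npairs)
    }
  }
  list(samples = samples,
       sample_sheet = do.call(rbind, c(sheet, list(make.row.names = FALSE))),
       truth = list(reads = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
                    locus_means = locus_means,
                    pairs = do.call(rbind, c(pair_rows, list(make.row.names = FALSE)))))
}

#' Simulate a full cohort (genome + reads) in one call
#' @param cfg a [sim_config()].
#' @return list with elements of [simulate_genome()] plus `reads`
#'   (the [simulate_reads()] output).
#' @export
simulate_cohort <- function(cfg) {
  sim <- simulate_genome(cfg)
  sim$reads <- simulate_reads(cfg, sim)
  sim
}
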