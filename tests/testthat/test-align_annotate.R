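rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

test_that("size filter keeps the inclusive 20-32 window and trims adapters", {
  reads <- data.frame(read_id = c("a19", "a20", "a32", "a33"),
                      seq = vapply(c(19, 20, 32, 33), function(n)
                        strrep("A", n), ""))
  out <- trim_and_filter(reads)
  expect_setequal(out$reads$read_id, c("a20", "a32"))
  expect_equal(unname(out$report["kept"]), 2L)
  expect_equal(unname(out$report["input"]), 4L)

  # full adapter, partial adapter prefix (>= 5 nt), and sub-threshold suffix
  core <- strrep("ACGT", 6)  # 24 nt
  adapter <- "TGGAATTCTCGG"
  reads <- data.frame(
    read_id = c("full", "partial", "short_suffix", "none"),
    seq = c(paste0(core, adapter), paste0(core, substr(adapter, 1, 6)),
            paste0(core, substr(adapter, 1, 4)), core))
  out <- trim_and_filter(reads, adapter = adapter)
  expect_equal(out$reads$seq[out$reads$read_id == "full"], core)
  expect_equal(out$reads$seq[out$reads$read_id == "partial"], core)
  # a 4-nt match is below the 5-nt floor: read kept untrimmed
  expect_equal(out$reads$seq[out$reads$read_id == "short_suffix"],
               paste0(core, "TGGA"))
  expect_equal(unname(out$report["trimmed"]), 2L)

  expect_error(trim_and_filter(reads, adapter = "ACGT"), "at least 5")
  # no adapter: sequences pass through untouched (wide window keeps all)
  expect_equal(trim_and_filter(reads, max_len = 40L)$reads$seq, reads$seq)
})

test_that("mini_align reports exact, multi-mapped and 1-mismatch placements", {
  set.seed(42)
  motif <- rand_seq(26)
  spacer <- function() rand_seq(40)
  genome <- Biostrings::DNAStringSet(c(
    c1 = paste0(spacer(), motif, spacer()),
    c2 = paste0(spacer(), motif, spacer())))
  mut <- motif
  substr(mut, 13, 13) <- if (substr(mut, 13, 13) == "A") "C" else "A"
  reads <- data.frame(read_id = c("two_loci", "one_mm", "absent"),
                      seq = c(motif, mut, rand_seq(26)))
  al <- mini_align(reads, genome)
  expect_equal(al$reads$x[al$reads$read_id == "two_loci"], 2L)
  expect_equal(al$reads$x[al$reads$read_id == "one_mm"], 2L)
  mm <- mcols(al$placements)$mismatches[
    mcols(al$placements)$read_id == "one_mm"]
  expect_equal(sort(mm), c(1L, 1L))
  expect_false("absent" %in% al$reads$read_id)
  expect_equal(start(al$placements)[1], 41L)

  # reverse-strand placement
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  al2 <- mini_align(data.frame(read_id = "rev", seq = rc), genome,
                    max_mismatch = 0)
  expect_equal(as.character(strand(al2$placements)), c("-", "-"))
})

test_that("reads with more than max_positions placements are discarded", {
  set.seed(43)
  motif <- rand_seq(24)
  genome <- Biostrings::DNAStringSet(c(c1 = paste(
    vapply(1:51, function(i) paste0(motif, rand_seq(15)), ""), collapse = "")))
  al <- mini_align(data.frame(read_id = "r", seq = motif), genome)
  expect_equal(nrow(al$reads), 0L)
  al50 <- mini_align(data.frame(read_id = "r", seq = motif), genome,
                     max_positions = 51L)
  expect_equal(al50$reads$x, 51L)
})

test_that("seed aligner agrees exactly with the brute-force Hamming oracle", {
  set.seed(44)
  genome <- Biostrings::DNAStringSet(c(c1 = rand_seq(8000), c2 = rand_seq(6000)))
  gseq <- as.character(genome)
  reads <- lapply(1:300, function(i) {
    ch <- sample(1:2, 1)
    len <- sample(20:32, 1)
    s <- sample(nchar(gseq[ch]) - len, 1)
    r <- substr(gseq[ch], s, s + len - 1)
    if (i %% 3 == 0) {  # plant one substitution
      p <- sample(len, 1)
      substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(r, p, p)), 1)
    }
    if (i %% 7 == 0) r <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(r)))
    r
  })
  df <- data.frame(read_id = paste0("r", seq_along(reads)),
                   seq = unlist(reads))
  a <- mini_align(df, genome)
  b <- somapiR:::.brute_align(df, genome)
  key <- function(al) {
    p <- al$placements
    sort(paste(mcols(p)$read_id, seqnames(p), start(p), strand(p),
               mcols(p)$mismatches))
  }
  expect_identical(key(a), key(b))
  expect_identical(a$reads[order(a$reads$read_id), ],
                   b$reads[order(b$reads$read_id), ])
})

test_that("classification is exclusion-first and partitions all reads", {
  # 100-nt toy chromosome; tracks placed by hand
  set.seed(45)
  genome_seq <- rand_seq(400)
  reads <- data.frame(
    read_id = c("in_decoy_and_pirna", "in_pirna", "nowhere"),
    seq = c(substr(genome_seq, 41, 64),   # inside decoy AND piRNA locus
            substr(genome_seq, 141, 164), # inside piRNA locus only
            substr(genome_seq, 301, 324)))
  al <- mini_align(reads, Biostrings::DNAStringSet(c(c1 = genome_seq)))
  ncrna <- GRanges("c1", IRanges(31, 100), strand = "+", label = "tRNA_1")
  pirna <- GRanges("c1", IRanges(c(35, 135), c(70, 170)), strand = "+",
                   label = c("piR-1", "piR-2"))
  ann <- classify_reads(al, ncrna, pirna)
  cat_of <- function(id) ann$reads$category[ann$reads$read_id == id]
  expect_equal(cat_of("in_decoy_and_pirna"), "excluded_ncRNA")
  expect_equal(cat_of("in_pirna"), "piRNA")
  expect_equal(cat_of("nowhere"), "unannotated")
  expect_equal(unname(ann$summary["aligned"]),
               unname(sum(ann$summary[c("excluded_ncRNA", "piRNA",
                                        "unannotated")])))

  # 50%-of-read-length assignment rule: 12/24 in-locus passes, 11/24 fails
  r2 <- data.frame(read_id = c("half_in", "under_half"),
                   seq = c(substr(genome_seq, 159, 182),
                           substr(genome_seq, 160, 183)))
  ann2 <- classify_reads(mini_align(r2, Biostrings::DNAStringSet(c(c1 = genome_seq))),
                         GRanges(), pirna)
  expect_equal(ann2$reads$category[ann2$reads$read_id == "half_in"], "piRNA")
  expect_equal(ann2$reads$category[ann2$reads$read_id == "under_half"],
               "unannotated")

  expect_warning(classify_reads(al, ncrna, GRanges()), "empty piRNA track")
})

test_that("synthetic cohorts are recovered: decoys excluded, piRNAs annotated", {
  sim <- simulate_cohort(small_cfg(seed = 21))
  anns <- annotate_cohort(sim)
  truth <- sim$reads$truth$reads
  for (s in names(anns)) {
    ann <- anns[[s]]
    expect_equal(unname(ann$summary["aligned"]),
                 unname(sum(ann$summary[c("excluded_ncRNA", "piRNA",
                                          "unannotated")])))
    tr <- truth[truth$sample == s, ]
    m <- merge(ann$reads, tr, by = "read_id")
    expect_equal(mean(m$category[m$source_class == "decoy_ncrna"] ==
                        "excluded_ncRNA"), 1)
    expect_gte(mean(m$category[m$source_class == "pirna"] == "piRNA"), 0.99)
  }
})
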