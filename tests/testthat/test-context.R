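ctx_annotated <- function(specs, pirna) {
  reads <- unique(specs[, c("read_id", "len")])
  reads <- data.frame(read_id = reads$read_id, seq = strrep("A", reads$len),
                      length = reads$len,
                      x = as.integer(table(specs$read_id)[reads$read_id]))
  pl <- GRanges(specs$chrom, IRanges(specs$start, width = specs$len),
                strand = specs$strand, read_id = specs$read_id,
                mismatches = 0L)
  classify_reads(aligned_reads(reads, pl), GRanges(), pirna)
}

test_that("context ratios recover pure and mixed planted compositions", {
  pirna <- GRanges("c1", IRanges(c(1, 101), width = 60), strand = "+",
                   label = c("pL", "pS"))
  repeats <- GRanges("c1", IRanges(c(1, 101), width = 60),
                     strand = c("+", "+"),
                     label = c("LINE_1", "SINE_1"), score = 0,
                     attrs = c("LINE", "SINE"))
  # all 10 reads sense inside the LINE
  specs <- data.frame(read_id = paste0("r", 1:10), chrom = "c1",
                      start = 5, len = 24, strand = "+")
  prof <- profile_context(ctx_annotated(specs, pirna), repeats, GRanges())
  expect_equal(prof$ratio[prof$class == "LINE" & prof$orientation == "sense"], 1)
  expect_equal(sum(prof$ratio[prof$class != "LINE"]), 0)

  # 3 of 10 reads antisense to the SINE -> ratio exactly 0.3
  specs$start[1:3] <- 105
  specs$strand[1:3] <- "-"
  prof <- profile_context(ctx_annotated(specs, pirna), repeats, GRanges())
  expect_equal(prof$ratio[prof$class == "SINE" &
                          prof$orientation == "antisense"], 0.3)
  expect_equal(prof$ratio[prof$class == "LINE" &
                          prof$orientation == "sense"], 0.7)
  expect_equal(transposon_ratio(prof), 1)

  # no repeat track records -> all repeat ratios zero
  prof0 <- profile_context(ctx_annotated(specs, pirna), GRanges(), GRanges())
  expect_true(all(prof0$count[prof0$panel == "repeat"] == 0))
})

test_that("feature attribution uses 3UTR > 5UTR > CDS > exon priority", {
  pirna <- GRanges("c1", IRanges(1, 120), strand = "+", label = "p1")
  tx <- GRanges("c1", IRanges(c(1, 1, 61), c(120, 60, 120)), strand = "+",
                gene_id = "g1", kind = c("exon", "CDS", "3UTR"),
                biotype = "protein_coding")
  specs <- data.frame(read_id = c("in_utr", "in_cds"), chrom = "c1",
                      start = c(71, 11), len = 24, strand = "+")
  prof <- profile_context(ctx_annotated(specs, pirna), GRanges(), tx)
  feat <- prof[prof$panel == "feature" & prof$orientation == "sense", ]
  expect_equal(feat$count[feat$class == "3UTR"], 1)
  expect_equal(feat$count[feat$class == "CDS"], 1)
  expect_equal(feat$count[feat$class == "exon"], 0)
  # biotype panel counts each read once for the gene
  bio <- prof[prof$panel == "biotype" & prof$class == "protein_coding", ]
  expect_equal(sum(bio$count), 2)
})

test_that("piRNA-aligned-gene standards evaluate both branches strictly", {
  m4 <- rbind(no_reads = c(0, 0, 0, 0),
              half11 = c(11, 11, 0, 0),
              all3 = c(3, 3, 3, 3),
              all2 = c(2, 2, 2, 2))
  colnames(m4) <- paste0("s", 1:4)
  g <- pirna_aligned_genes(m4, "stringent")
  expect_setequal(g, c("half11", "all3"))  # 2 of 4 >= ceiling(4/2); >2 in all
  expect_equal(length(pirna_aligned_genes(m4, "relaxed")), 0L)  # needs n > 10

  m11 <- matrix(3, 2, 11, dimnames = list(c("gA", "gB"), paste0("s", 1:11)))
  m11["gB", ] <- 2
  expect_equal(pirna_aligned_genes(m11, "relaxed"), "gA")
  m10 <- m11[, 1:10]
  expect_equal(length(pirna_aligned_genes(m10, "relaxed")), 0L)
})

test_that("gene counts aggregate placements once per gene", {
  pirna <- GRanges("c1", IRanges(1, 200), strand = "+", label = "p1")
  tx <- GRanges("c1", IRanges(c(1, 50), c(100, 200)), strand = "+",
                gene_id = c("g1", "g1"), kind = c("exon", "3UTR"),
                biotype = "protein_coding")
  specs <- data.frame(read_id = "r1", chrom = "c1", start = 60, len = 24,
                      strand = "+")  # overlaps both features of g1
  gc <- gene_pirna_counts(list(s1 = ctx_annotated(specs, pirna)), tx)
  expect_equal(unname(gc["g1", "s1"]), 1)
})

test_that("context comparisons use the exact two-sided rank-sum law", {
  mk <- function(r) data.frame(panel = "repeat", class = "LINE",
                               orientation = "sense", count = NA, ratio = r)
  a <- lapply(c(0.1, 0.2, 0.3), mk)
  b <- lapply(c(0.4, 0.5, 0.6), mk)
  res <- compare_context(a, b, "LINE", "sense")
  expect_equal(res$p_value, 0.1)  # 2/20 labelings as extreme
  expect_equal(res$stars, "")
  # symmetry under label swap
  expect_equal(compare_context(b, a, "LINE", "sense")$p_value, 0.1)
  # identical groups: p = 1 within the exact-test resolution
  same <- compare_context(a, a, "LINE", "sense")
  expect_gte(same$p_value, 0.9)
  expect_error(compare_context(a[1], b, "LINE"), "at least 2")
})
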