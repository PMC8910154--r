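make_annotated <- function(read_specs, pirna, ncrna = GRanges()) {
  # read_specs: data.frame(read_id, chrom, start, len, strand, x per placement)
  reads <- unique(read_specs[, c("read_id", "len")])
  reads <- data.frame(read_id = reads$read_id,
                      seq = strrep("A", reads$len), length = reads$len,
                      x = as.integer(table(read_specs$read_id)[reads$read_id]))
  pl <- GRanges(read_specs$chrom,
                IRanges(read_specs$start, width = read_specs$len),
                strand = read_specs$strand, read_id = read_specs$read_id,
                mismatches = 0L)
  classify_reads(aligned_reads(reads, pl), ncrna, pirna)
}

test_that("fractional counting distributes 1/(x * loci) and conserves mass", {
  pirna <- GRanges("c1", IRanges(c(1, 101, 201, 301), width = 60),
                   strand = "+", label = paste0("p", 1:4))
  specs <- rbind(
    data.frame(read_id = "u", chrom = "c1", start = 10, len = 24, strand = "+"),
    data.frame(read_id = "m4", chrom = "c1", start = c(10, 110, 210, 310),
               len = 24, strand = "+"))
  ann <- make_annotated(specs, pirna)
  sheet <- data.frame(sample = "s1", group = "g", tissue = "t", batch = "")
  cm <- build_counts(list(s1 = ann), sheet)
  expect_equal(unname(cm$counts["p1", "s1"]), 1 + 0.25)  # x=1 read + x=4 read
  expect_equal(unname(cm$counts["p2", "s1"]), 0.25)
  expect_equal(sum(cm$counts), sum(ann$assignments$weight))
  expect_equal(sum(cm$counts), 2)  # both reads fully inside loci
  expect_equal(unname(cm$lib_size["s1"]), 2)

  expect_error(build_counts(list(s1 = ann),
                            data.frame(sample = "other", group = "g",
                                       tissue = "t", batch = "")),
               "sample sheet")
})

test_that("a placement overlapping two loci splits its weight", {
  pirna <- GRanges("c1", IRanges(c(1, 20), c(40, 80)), strand = "+",
                   label = c("pA", "pB"))
  specs <- data.frame(read_id = "r", chrom = "c1", start = 15, len = 24,
                      strand = "+")  # 15..38 inside both loci
  ann <- make_annotated(specs, pirna)
  expect_equal(nrow(ann$assignments), 2L)
  expect_equal(ann$assignments$weight, c(0.5, 0.5))
})

test_that("presence calling follows both branches with strict inequalities", {
  rule <- presence_rule(2, 10)
  cm <- manual_cm(rbind(p1 = c(3, 3, 3, 3), p2 = c(0, 11, 12, 13),
                        p3 = c(2, 2, 2, 2), p4 = c(0, 0, 11, 11)))
  present <- call_present(cm, rule)
  expect_true("p1" %in% present)   # all-samples branch
  expect_true("p2" %in% present)   # 50% branch: 3 of 4 > 10
  expect_false("p3" %in% present)  # strict >2 fails
  expect_true("p4" %in% present)   # exactly half (2 of 4) counts
  expect_error(presence_rule(10, 2), "min_all")
})

test_that("presence calling matches a per-piRNA brute-force oracle", {
  brute <- function(counts, rule) {
    n <- ncol(counts)
    hits <- vapply(seq_len(nrow(counts)), function(i) {
      a <- all(counts[i, ] > rule$min_all)
      b <- sum(counts[i, ] > rule$min_half) >= ceiling(n / 2)
      a || b
    }, TRUE)
    rownames(counts)[hits]
  }
  set.seed(77)
  for (i in 1:50) {
    n <- sample(3:9, 1)
    counts <- matrix(rpois(30 * n, lambda = 4), 30, n,
                     dimnames = list(paste0("p", 1:30), paste0("s", 1:n)))
    cm <- manual_cm(counts)
    for (rule in list(presence_rule(2, 10), presence_rule(2, 5))) {
      expect_identical(call_present(cm, rule), brute(counts, rule))
    }
  }
})

test_that("chromosome RPKM follows the formula and inverts to read mass", {
  pirna <- GRanges("c1", IRanges(seq(1, 991, by = 110), width = 60),
                   strand = "+", label = paste0("p", 1:10))
  specs <- data.frame(read_id = paste0("r", 1:10), chrom = "c1",
                      start = seq(5, 995, by = 110), len = 24, strand = "+")
  ann <- make_annotated(specs, pirna)
  lens <- c(c1 = 1e6, c2 = 5e5)
  present <- paste0("pp", 1:100)  # denominator: 100 present piRNAs
  rp <- chromosome_rpkm(ann, lens, present)
  expect_equal(rp$rpkm[rp$chrom == "c1"], 10 * 1e6 / (100 * 1e6))  # = 0.1
  expect_equal(rp$rpkm[rp$chrom == "c2"], 0)
  # formula inversion recovers total fraction-weighted reads
  expect_equal(sum(rp$rpkm * length(present) * lens / 1e6), 10,
               tolerance = 1e-9)
  expect_error(chromosome_rpkm(ann, lens, character()), "empty")

  # linearity: doubling the reads doubles every RPKM
  specs2 <- rbind(specs, transform(specs, read_id = paste0(read_id, "b")))
  rp2 <- chromosome_rpkm(make_annotated(specs2, pirna), lens, present)
  expect_equal(rp2$rpkm, 2 * rp$rpkm)
})

test_that("Venn partitions cover all regions and conserve the union", {
  out <- compare_sets(list(A = c("1", "2"), B = c("2", "3")))
  expect_equal(out$size[out$region == "A&B"], 1L)
  expect_equal(out$size[out$region == "A"], 1L)
  expect_equal(out$size[out$region == "B"], 1L)

  same <- compare_sets(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$size[same$region == "A&B"], 2L)
  expect_equal(sum(same$size[same$region != "A&B"]), 0L)

  set.seed(1)
  sets <- list(A = sample(letters, 12), B = sample(letters, 8),
               C = sample(letters, 15))
  out3 <- compare_sets(sets)
  expect_equal(nrow(out3), 7L)
  expect_equal(sum(out3$size), length(unique(unlist(sets))))
})
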