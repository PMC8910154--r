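sig_annotated <- function(seqs, chrom = "c1", starts = NULL, strands = NULL,
                          x = NULL) {
  n <- length(seqs)
  starts <- starts %||% seq(1, by = 100, length.out = n)
  strands <- strands %||% rep("+", n)
  x <- x %||% rep(1L, n)
  reads <- data.frame(read_id = paste0("r", 1:n), seq = seqs,
                      length = nchar(seqs), x = x)
  pl_rows <- rep(seq_len(n), x)
  pl <- GRanges(chrom, IRanges(starts[pl_rows] +
                                 1000 * (sequence(x) - 1),
                               width = nchar(seqs)[pl_rows]),
                strand = strands[pl_rows], read_id = reads$read_id[pl_rows],
                mismatches = 0L)
  pirna <- GRanges(chrom, IRanges(1, 1e6), strand = "+", label = "pAll")
  classify_reads(aligned_reads(reads, pl), GRanges(), pirna)
}

test_that("length/first-base histogram is a proper distribution", {
  ann <- sig_annotated(rep(paste0("T", strrep("A", 25)), 5))
  prof <- length_base_profile(ann)
  expect_equal(sum(prof$length_hist), 1, tolerance = 1e-9)
  expect_equal(unname(prof$length_hist["26", "T"]), 1)
  expect_equal(prof$u1_fraction, 1)

  # a multi-mapper still counts as one read
  ann2 <- sig_annotated(rep(paste0("T", strrep("A", 25)), 5), x = c(2L, 1L, 1L, 1L, 1L))
  expect_equal(length_base_profile(ann2)$length_hist, prof$length_hist)

  empty <- sig_annotated(paste0("T", strrep("A", 25)))
  empty$reads$category <- "unannotated"
  expect_error(length_base_profile(empty), "no annotated piRNA")
})

test_that("uniform first bases give u1 near 0.25", {
  set.seed(11)
  n <- 4000
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 26, replace = TRUE), collapse = ""), "")
  prof <- length_base_profile(sig_annotated(seqs))
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(prof$u1_fraction - 0.25), 3 * se)
  expect_lt(abs(prof$a10_fraction - 0.25), 3 * se)
})

test_that("bias tests give exact binomial tails", {
  ann <- sig_annotated(c(rep(paste0("T", strrep("A", 25)), 900),
                         rep(strrep("G", 26), 100)))
  bt <- bias_test(length_base_profile(ann))
  expect_equal(bt$p_value[bt$bias == "1U"],
               binom.test(900, 1000, 0.25, "greater")$p.value)
  expect_lt(bt$p_value[bt$bias == "1U"], 1e-6)
  # 10A here: first 900 reads have A at position 10
  expect_equal(bt$p_value[bt$bias == "10A"],
               binom.test(900, 1000, 0.25, "greater")$p.value)
})

test_that("ping-pong spectrum equals the all-pairs brute force", {
  set.seed(12)
  n <- 400
  strands <- sample(c("+", "-"), n, replace = TRUE)
  lens <- sample(20:30, n, replace = TRUE)
  starts <- sample(1:2000, n, replace = TRUE)
  xs <- sample(1:3, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  reads <- data.frame(read_id = paste0("r", 1:n),
                      seq = vapply(lens, function(l) strrep("A", l), ""),
                      length = lens, x = xs)
  pl_rows <- rep(seq_len(n), xs)
  pl <- GRanges("c1", IRanges(starts[pl_rows] + 3000 * (sequence(xs) - 1),
                              width = lens[pl_rows]),
                strand = strands[pl_rows], read_id = reads$read_id[pl_rows],
                mismatches = 0L)
  ann <- classify_reads(aligned_reads(reads, pl), GRanges(),
                        GRanges("c1", IRanges(1, 1e6), strand = "+",
                                label = "pAll"))
  pp <- pingpong_statistic(ann)

  # independent brute force: outer() over all plus/minus placement pairs
  w <- 1 / xs[pl_rows]
  plus <- as.character(strand(pl)) == "+"
  d <- outer(end(pl)[!plus], start(pl)[plus], "-") + 1
  wmat <- outer(w[!plus], w[plus])
  brute <- vapply(1:20, function(k) sum(wmat[d == k]), 0)
  expect_equal(unname(pp$spectrum), brute, tolerance = 1e-12)
})

test_that("germline-like samples show the k=10 signal; somatic-like do not", {
  sim <- simulate_cohort(signature_cfg(seed = 13, pair_fraction = 0.3))
  anns <- annotate_cohort(sim)
  germ <- pingpong_statistic(anns[["germ_s01"]])
  soma <- pingpong_statistic(anns[["soma_s01"]])
  expect_equal(germ$signal, "signal")
  expect_gte(germ$z, 1.645)
  expect_equal(soma$signal, "no signal")
  # germline biases present, somatic near-uniform
  pg <- length_base_profile(anns[["germ_s01"]])
  ps <- length_base_profile(anns[["soma_s01"]])
  expect_lt(bias_test(pg)$p_value[1], 0.001)
  expect_gt(bias_test(ps)$p_value[1], 0.01)
})

test_that("position shuffling destroys the k=10 excess", {
  sim <- simulate_cohort(signature_cfg(seed = 14, pair_fraction = 0.3))
  ann <- annotate_cohort(sim)[["germ_s01"]]
  set.seed(14)
  below <- 0L
  for (i in 1:20) {
    shuf <- ann
    pl <- shuf$placements
    new_start <- sample(1:25000, length(pl), replace = TRUE)
    shuf$placements <- GRanges(seqnames(pl),
                               IRanges(new_start, width = width(pl)),
                               strand = strand(pl),
                               read_id = mcols(pl)$read_id,
                               mismatches = mcols(pl)$mismatches)
    z <- pingpong_statistic(shuf)$z
    if (is.na(z) || z < 1.645) below <- below + 1L
  }
  expect_gte(below, 17L)
})

test_that("single-strand samples report no signal", {
  ann <- sig_annotated(rep(strrep("A", 24), 10))
  pp <- pingpong_statistic(ann)
  expect_true(all(pp$spectrum == 0))
  expect_true(is.na(pp$z))
  expect_equal(pp$signal, "no signal")
})
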