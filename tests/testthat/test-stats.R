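# independent two-sided exact rank-sum p by full enumeration of group
# assignments
enum_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  combos <- utils::combn(length(pooled), nA)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - nA * (nA + 1) / 2)
  mu <- nA * length(b) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu))
}

test_that("two-group Wilcoxon uses the exact law for small samples", {
  cm <- manual_cm(rbind(p1 = c(1, 2, 3, 4, 5, 6)),
                  groups = rep(c("A", "B"), each = 3))
  de <- diff_expression(cm, "A", "B")
  expect_equal(de$p_value, 0.1)  # {1,2,3} vs {4,5,6}: 2/20 assignments
  expect_equal(de$W, 0)
  expect_false(de$significant)

  cm2 <- manual_cm(rbind(p1 = rep(7, 6)), groups = rep(c("A", "B"), each = 3))
  expect_equal(diff_expression(cm2, "A", "B")$p_value, 1)

  expect_error(diff_expression(cm, "A", "missing"), "not in sample sheet")
  expect_error(diff_expression(manual_cm(rbind(p1 = 1:4),
                                         groups = rep(c("A", "B"), 2)),
                               "A", "B"), ">= 3")
})

test_that("normalization leaves the test invariant under library rescaling", {
  set.seed(21)
  counts <- matrix(rpois(8 * 20, 30), 20, 8)
  cm <- manual_cm(counts, groups = rep(c("A", "B"), each = 4),
                  lib_size = setNames(rep(1e5, 8), paste0("s0", 1:8)))
  cm2 <- cm
  cm2$counts <- cm$counts * 2
  cm2$lib_size <- cm$lib_size * 2
  expect_equal(diff_expression(cm, "A", "B")$p_value,
               diff_expression(cm2, "A", "B")$p_value)
})

test_that("exact branch matches enumeration for assorted small group sizes", {
  set.seed(22)
  for (sizes in list(c(3, 3), c(4, 3), c(4, 4), c(5, 3), c(6, 4), c(5, 5))) {
    a <- rnorm(sizes[1]); b <- rnorm(sizes[2]) + 0.8
    cm <- manual_cm(matrix(c(a, b), 1,
                           dimnames = list("p1", NULL)),
                    groups = rep(c("A", "B"), sizes))
    expect_equal(diff_expression(cm, "A", "B", normalize = FALSE)$p_value,
                 enum_wilcox_p(a, b), tolerance = 1e-12,
                 info = paste(sizes, collapse = "+"))
  }
})

test_that("Kruskal-Wallis flags staged trends the pooled test misses", {
  cm3 <- manual_cm(rbind(p1 = rep(5, 9)),
                   groups = rep(c("ctl", "pre", "mot"), each = 3))
  expect_equal(multi_group_de(cm3, c("ctl", "pre", "mot"))$p_value, 1)
  expect_error(multi_group_de(cm3, c("ctl", "pre")), ">= 3 groups")

  # planted monotone trend with equal pooled means
  set.seed(23)
  ctl <- rnorm(8, 10, 0.7); pre <- rnorm(8, 6, 0.7); mot <- rnorm(8, 14, 0.7)
  cm <- manual_cm(matrix(c(ctl, pre, mot), 1, dimnames = list("p1", NULL)),
                  groups = rep(c("ctl", "pre", "mot"), each = 8))
  res <- progression_specific(cm, "ctl", c("pre", "mot"))
  expect_equal(res$progression_specific, "p1")
  expect_true(res$stagewise$significant[1])
  expect_false(res$pooled$significant[1])
})

test_that("null p-values are near-uniform and hold the nominal level", {
  set.seed(24)
  n <- 600
  counts <- matrix(rlnorm(n * 24, 3, 0.6), n, 24)
  cm <- manual_cm(counts, groups = sample(rep(c("A", "B"), each = 12)))
  pv <- diff_expression(cm, "A", "B")$p_value
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif")$p.value), 0.001)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.03)
})

test_that("hypergeometric enrichment matches direct combinatorics", {
  # universe 10, set of 5, query of 2 fully inside: p = C(5,2)/C(10,2)
  universe <- paste0("g", 1:10)
  sets <- list(S = universe[1:5])
  res <- enrich(universe[1:2], sets, universe)
  expect_equal(res$p_value, choose(5, 2) / choose(10, 2))
  expect_equal(res$gene_ratio, 2 / 5)

  # query = universe forces k = K, p = 1
  res2 <- enrich(universe, sets, universe)
  expect_equal(res2$p_value, 1)
  # zero overlap -> p = 1
  res3 <- enrich(universe[6:7], list(S = universe[1:3]), universe)
  expect_equal(res3$p_value, 1)

  expect_error(enrich(character(), sets, universe), "empty query")
  expect_error(enrich("zz", sets, universe), "missing from universe")
  expect_warning(enrich(universe[1:2], list(S = universe[1:5], out = "qq"),
                        universe), "skipped")

  # exhaustive check of the upper tail for assorted (N, K, n)
  for (case in list(c(12, 4, 5), c(15, 6, 4), c(9, 3, 3))) {
    N <- case[1]; K <- case[2]; n <- case[3]
    univ <- paste0("u", seq_len(N))
    set <- univ[seq_len(K)]
    for (k in 0:min(n, K)) {
      query <- c(set[seq_len(k)], setdiff(univ, set)[seq_len(n - k)])
      p_pkg <- enrich(query, list(S = set), univ)$p_value
      p_enum <- sum(vapply(k:min(n, K), function(i)
        choose(K, i) * choose(N - K, n - i), 0)) / choose(N, n)
      expect_equal(p_pkg, p_enum, tolerance = 1e-12)
    }
  }
})

test_that("BH q-values dominate raw p-values and order is preserved", {
  set.seed(25)
  universe <- paste0("g", 1:50)
  sets <- lapply(1:6, function(i) sample(universe, 12))
  names(sets) <- paste0("S", 1:6)
  res <- enrich(sample(universe, 10), sets, universe)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_false(is.unsorted(res$p_value))
})
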