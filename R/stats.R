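# Differential expression (two-group Wilcoxon rank-sum on CPM-normalized
# counts; raw p < alpha is the significance rule, BH q-values reported
# alongside), multi-group Kruskal-Wallis with the progression-specific
# contrast, and self-contained hypergeometric gene-set enrichment with BH
# correction.

#' Two-group Wilcoxon differential expression
#'
#' Counts are normalized to counts per million library reads before testing.
#' The exact rank-sum distribution is used for combined n <= 20 without
#' ties; otherwise the normal approximation with tie and continuity
#' correction. Significance follows raw p < `alpha`; BH-adjusted q-values
#' are reported alongside.
#'
#' @param cm a `count_matrix`.
#' @param group_a,group_b group labels from the sample sheet (>= 3 samples
#'   each).
#' @param alpha raw-p significance level.
#' @param normalize set FALSE to test raw counts.
#' @return data.frame: `pirna_id`, `median_a`, `median_b` (CPM), `W`,
#'   `p_value`, `q_value`, `significant`.
#' @export
diff_expression <- function(cm, group_a, group_b, alpha = 0.05,
                            normalize = TRUE) {
  stopifnot(is(cm, "count_matrix"))
  ga <- cm$samples$sample[cm$samples$group == group_a]
  gb <- cm$samples$sample[cm$samples$group == group_b]
  if (length(ga) == 0L) stopf("group '%s' not in sample sheet", group_a)
  if (length(gb) == 0L) stopf("group '%s' not in sample sheet", group_b)
  if (length(ga) < 3L || length(gb) < 3L)
    stopf("need >= 3 samples per group")
  m <- if (normalize) cpm(cm) else cm$counts
  res <- t(vapply(seq_len(nrow(m)), function(i) {
    a <- m[i, ga]; b <- m[i, gb]
    if (length(unique(c(a, b))) == 1L)  # all tied: no evidence either way
      return(c(median(a), median(b), length(a) * length(b) / 2, 1))
    exact <- (length(a) + length(b)) <= 20L && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    c(median(a), median(b), unname(wt$statistic), wt$p.value)
  }, numeric(4)))
  out <- data.frame(pirna_id = rownames(m), median_a = res[, 1],
                    median_b = res[, 2], W = res[, 3], p_value = res[, 4],
                    stringsAsFactors = FALSE)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Multi-group (Kruskal-Wallis) differential expression
#'
#' @param cm a `count_matrix`.
#' @param groups labels (>= 3) to compare; each needs >= 3 samples.
#' @param alpha significance level.
#' @param normalize set FALSE to test raw counts.
#' @return data.frame: `pirna_id`, `H` (KW statistic), `p_value`,
#'   `q_value`, `significant`.
#' @export
multi_group_de <- function(cm, groups, alpha = 0.05, normalize = TRUE) {
  stopifnot(is(cm, "count_matrix"))
  if (length(groups) < 3L) stopf("need >= 3 groups (got %d)", length(groups))
  sel <- cm$samples$group %in% groups
  lab <- factor(cm$samples$group[sel], levels = groups)
  if (any(table(lab) < 3L)) stopf("each group needs >= 3 samples")
  m <- (if (normalize) cpm(cm) else cm$counts)[, cm$samples$sample[sel],
                                               drop = FALSE]
  res <- t(vapply(seq_len(nrow(m)), function(i) {
    kt <- suppressWarnings(kruskal.test(m[i, ], lab))
    c(unname(kt$statistic), kt$p.value)
  }, numeric(2)))
  out <- data.frame(pirna_id = rownames(m), H = res[, 1], p_value = res[, 2],
                    stringsAsFactors = FALSE)
  out$p_value[is.nan(out$p_value)] <- 1
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Progression-specific piRNAs: multi-group significant, pooled two-group not
#'
#' Reproduces the staged-disease contrast: features significant across >= 3
#' ordered groups (Kruskal-Wallis) but NOT between control and the pooled
#' case groups (Wilcoxon).
#'
#' @param cm a `count_matrix`.
#' @param control control group label.
#' @param stages case-stage labels (>= 2), pooled for the two-group test.
#' @param alpha significance level for both tests.
#' @return list: `stagewise` (KW table), `pooled` (Wilcoxon table),
#'   `progression_specific` (piRNA ids).
#' @export
progression_specific <- function(cm, control, stages, alpha = 0.05) {
  kw <- multi_group_de(cm, c(control, stages), alpha = alpha)
  pooled <- cm
  pooled$samples$group[pooled$samples$group %in% stages] <- "pooled_case"
  de <- diff_expression(pooled, control, "pooled_case", alpha = alpha)
  list(stagewise = kw, pooled = de,
       progression_specific = kw$pirna_id[kw$significant &
         !de$significant[match(kw$pirna_id, de$pirna_id)]])
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test P(X >= k) per gene set, BH-corrected
#' across sets; gene_ratio = overlap / set size (restricted to the
#' universe).
#'
#' @param query character vector of genes (must be a subset of `universe`).
#' @param gene_sets named list of gene vectors (e.g. [read_gmt()]).
#' @param universe background gene vector.
#' @param top_n optionally keep only the top-n sets by p-value.
#' @return data.frame: `set_name`, `overlap`, `query_size`, `set_size`,
#'   `universe_size`, `gene_ratio`, `p_value`, `q_value`.
#' @export
enrich <- function(query, gene_sets, universe, top_n = NULL) {
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0L) stopf("empty query gene list")
  if (!all(query %in% universe))
    stopf("query genes missing from universe: %s",
          paste(head(setdiff(query, universe), 5L), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    if (length(set) == 0L) {
      warnf("gene set '%s' does not intersect the universe; skipped", nm)
      return(NULL)
    }
    K <- length(set)
    k <- length(intersect(query, set))
    data.frame(set_name = nm, overlap = k, query_size = n, set_size = K,
               universe_size = N, gene_ratio = k / K,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no gene set intersects the universe")
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  if (!is.null(top_n)) out <- head(out, top_n)
  rownames(out) <- NULL
  out
}
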