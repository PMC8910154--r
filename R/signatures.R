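# Biogenesis signatures of annotated piRNA reads: length x first-base
# histogram, 5'U and 10A base biases, and the ping-pong 10-nt 5'-overlap
# statistic with a z-score against the neighboring-overlap background.

#' Length x first-base profile with 1U / 10A fractions
#'
#' Histogram over read length (20-32) and first base; each read counts once
#' (its 1/x placement weights sum to 1). `u1_fraction` is the share of reads
#' whose 5' base is T (U in the RNA), `a10_fraction` the share with A at
#' position 10 of the read's own sequence.
#'
#' @param annotated `annotated_reads` for one sample.
#' @param min_len,max_len histogram support.
#' @return list of class `signature_profile`: `length_hist` (length x base
#'   fractions summing to 1), `u1_fraction`, `a10_fraction`, `n_reads`.
#' @export
length_base_profile <- function(annotated, min_len = 20L, max_len = 32L) {
  r <- annotated$reads[annotated$reads$category == "piRNA", , drop = FALSE]
  if (nrow(r) == 0L) stopf("sample has no annotated piRNA reads")
  bases <- c("A", "C", "G", "T", "N")
  fb <- first_base(r$seq)
  fb[!fb %in% bases] <- "N"
  h <- table(factor(r$length, levels = min_len:max_len),
             factor(fb, levels = bases))
  h <- h / nrow(r)
  b10 <- substr(r$seq, 10L, 10L)
  structure(list(length_hist = unclass(h),
                 u1_fraction = mean(fb == "T"),
                 a10_fraction = mean(b10 == "A"),
                 n_reads = nrow(r)),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  cat(sprintf("<signature_profile> %d reads, 1U=%.3f, 10A=%.3f\n",
              x$n_reads, x$u1_fraction, x$a10_fraction))
  invisible(x)
}

#' Ping-pong 5'-overlap spectrum and z-score
#'
#' For every pair of opposite-strand piRNA-read placements on the same
#' chromosome, the 5'-overlap is k = 5'(minus) - 5'(plus) + 1 in plus-strand
#' coordinates; pairs with 1 <= k <= `kmax` are accumulated with weight
#' 1 / (x_plus * x_minus). The ping-pong z-score compares the k = 10 bin
#' against the mean and sd of the other bins (the local background);
#' z >= `z_threshold` (default 1.645, one-sided 5%) is called a signal.
#'
#' @param annotated `annotated_reads` for one sample.
#' @param kmax spectrum support (default 20).
#' @param z_threshold signal threshold on the z-score.
#' @return list of class `pingpong_result`: `spectrum` (named k = 1..kmax),
#'   `z`, `signal` ("signal" / "no signal"), `threshold`.
#' @export
pingpong_statistic <- function(annotated, kmax = 20L, z_threshold = 1.645) {
  pl <- .pirna_placements(annotated)
  spectrum <- setNames(rep(0, kmax), seq_len(kmax))
  pos_str <- as.character(strand(pl))
  plus <- pl[pos_str == "+"]
  minus <- pl[pos_str == "-"]
  if (length(plus) > 0L && length(minus) > 0L) {
    for (ch in unique(as.character(seqnames(pl)))) {
      p <- plus[as.character(seqnames(plus)) == ch]
      m <- minus[as.character(seqnames(minus)) == ch]
      if (length(p) == 0L || length(m) == 0L) next
      # aggregate weights by 5' position
      pw <- tapply(mcols(p)$weight, start(p), sum)
      mw <- tapply(mcols(m)$weight, end(m), sum)
      ppos <- as.integer(names(pw)); mpos <- as.integer(names(mw))
      for (k in seq_len(kmax)) {
        hit <- match(ppos + k - 1L, mpos)
        ok <- !is.na(hit)
        if (any(ok)) spectrum[k] <- spectrum[k] + sum(pw[ok] * mw[hit[ok]])
      }
    }
  }
  bg <- spectrum[-10L]
  z <- if (all(spectrum == 0) || sd(bg) == 0) NA_real_
       else (spectrum[10L] - mean(bg)) / sd(bg)
  structure(list(spectrum = spectrum, z = unname(z),
                 signal = if (!is.na(z) && z >= z_threshold) "signal"
                          else "no signal",
                 threshold = z_threshold),
            class = "pingpong_result")
}

#' @export
print.pingpong_result <- function(x, ...) {
  cat(sprintf("<pingpong_result> z = %s (%s)\n",
              format(x$z, digits = 4), x$signal))
  invisible(x)
}

#' One-sided binomial tests of the 5'U and 10A biases
#'
#' Tests `u1_fraction > 0.25` and `a10_fraction > 0.25` against the uniform
#' base-composition null.
#'
#' @param profile a [length_base_profile()] result.
#' @return data.frame with `bias`, `fraction`, `n`, `p_value`.
#' @export
bias_test <- function(profile) {
  stopifnot(is(profile, "signature_profile"))
  n <- profile$n_reads
  if (n == 0L) stopf("no reads in profile")
  p_u1 <- binom.test(round(profile$u1_fraction * n), n, p = 0.25,
                     alternative = "greater")$p.value
  p_a10 <- binom.test(round(profile$a10_fraction * n), n, p = 0.25,
                      alternative = "greater")$p.value
  data.frame(bias = c("1U", "10A"),
             fraction = c(profile$u1_fraction, profile$a10_fraction),
             n = n, p_value = c(p_u1, p_a10), stringsAsFactors = FALSE)
}
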