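`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a TSV with a "#"-comment prologue
#'
#' All pipeline outputs are plain TSV with a comment prologue recording the
#' package version and the parameters that produced them, so any table can be
#' traced back to its run.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list of parameters recorded in the prologue
#'   (serialized as `key=value`).
#' @return `path`, invisibly.
#' @export
write_tsv_prologue <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# somapiR %s", as.character(packageVersion("somapiR"))), con)
  for (nm in names(params)) {
    writeLines(sprintf("# %s=%s", nm,
                       paste(as.character(params[[nm]]), collapse = ",")), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_prologue()]
#'
#' @param path file path.
#' @return data.frame (prologue lines skipped).
#' @export
read_tsv_prologue <- function(path) {
  if (!file.exists(path)) stopf("TSV not found: %s", path)
  read.delim(path, comment.char = "#", sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

first_base <- function(seqs) substr(seqs, 1L, 1L)

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

empty_gr <- function(...) {
  g <- GRanges()
  mcols(g) <- DataFrame(...)
  g
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
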