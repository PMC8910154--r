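# Orchestration of the full workflow: simulate -> annotate -> quantify ->
# context -> signatures -> stats -> classify. Every stage writes plain TSV
# intermediates with a provenance prologue (package version, config hash,
# parameters); stages are individually re-runnable from the intermediates of
# the stages before them, and a manifest records outputs and checksums.

.pipeline_stages <- c("simulate", "annotate", "quantify", "context",
                      "signatures", "stats", "classify")

#' Build a validated run configuration
#'
#' @param sim a [sim_config()] describing the synthetic cohort (or NULL when
#'   `reads`/`tracks` paths point at existing inputs; the bundled default is
#'   the synthetic cohort).
#' @param presence list(min_all, min_half) presence thresholds (ovary-style
#'   designs use 2/5, other tissues 2/10).
#' @param max_mismatch,max_positions aligner constraints.
#' @param min_len,max_len size filter window (nt).
#' @param alpha significance level for differential tests.
#' @param z_threshold ping-pong signal threshold.
#' @param h_grid,keepX_grid classifier tuning grids.
#' @param de_groups character(2): the group labels compared in the stats and
#'   classify stages (default: first two groups of the cohort).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       presence = list(min_all = 2, min_half = 10),
                       max_mismatch = 1L, max_positions = 50L,
                       min_len = 20L, max_len = 32L,
                       alpha = 0.05, z_threshold = 1.645,
                       h_grid = 1:5,
                       keepX_grid = c(5L, 10L, 25L, 50L, Inf),
                       de_groups = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$de_groups) && !is.null(sim))
    cfg$de_groups <- vapply(sim$groups[1:2], `[[`, "", "name")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected; `sim` sub-keys are passed to [sim_config()].
#'
#' @param path YAML file.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  if (!is.null(raw$sim)) {
    sim_known <- names(formals(sim_config))
    bad <- setdiff(names(raw$sim), sim_known)
    if (length(bad)) stopf("unknown sim key(s): %s", paste(bad, collapse = ", "))
    raw$sim <- do.call(sim_config, raw$sim)
  }
  do.call(run_config, raw)
}

.cfg_hash <- function(cfg) rlang::hash(unclass(cfg))

.stage_params <- function(cfg, ...) {
  c(list(config_hash = .cfg_hash(cfg), seed = cfg$sim$seed), list(...))
}

# --- individual stages, each reading only earlier intermediates ------------

.stage_simulate <- function(cfg, dir) {
  sim <- simulate_cohort(cfg$sim)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_bed(sim$tracks$pirna, file.path(dir, "pirna.bed"))
  write_bed(sim$tracks$ncrna, file.path(dir, "ncrna.bed"))
  write_bed(sim$tracks$repeats, file.path(dir, "repeats.bed"))
  write_gtf(sim$tracks$transcripts, file.path(dir, "transcripts.gtf"))
  pars <- .stage_params(cfg)
  write_tsv_prologue(sim$reads$sample_sheet, file.path(dir, "samples.tsv"), pars)
  write_tsv_prologue(sim$reads$truth$reads, file.path(dir, "truth_reads.tsv"), pars)
  write_tsv_prologue(sim$reads$truth$locus_means,
                     file.path(dir, "truth_locus_means.tsv"), pars)
  write_tsv_prologue(sim$locus_info, file.path(dir, "locus_info.tsv"), pars)
  fq <- file.path(dir, "fastq")
  dir.create(fq, showWarnings = FALSE)
  for (s in names(sim$reads$samples))
    write_fastq(sim$reads$samples[[s]], file.path(fq, paste0(s, ".fastq")))
  # a small gene-set file: genes hosting 3'UTR piRNA loci + random fillers
  tx <- sim$tracks$transcripts
  genes <- unique(mcols(tx)$gene_id[mcols(tx)$biotype == "protein_coding"])
  hosts <- unique(stats::na.omit(
    sim$locus_info$host[sim$locus_info$context_class == "three_utr"]))
  sets <- list(UTR3_PIRNA_HOSTS = hosts)
  for (i in 1:3)
    sets[[sprintf("RANDOM_SET_%d", i)]] <-
      sample(genes, max(3L, length(genes) %/% 4L))
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), ""),
    file.path(dir, "genesets.gmt"))
  invisible(NULL)
}

.stage_annotate <- function(cfg, dir) {
  genome <- read_fasta(file.path(dir, "genome.fa"))
  ncrna <- read_bed(file.path(dir, "ncrna.bed"))
  pirna <- read_bed(file.path(dir, "pirna.bed"))
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  an_dir <- file.path(dir, "annotated")
  dir.create(an_dir, showWarnings = FALSE)
  summ <- list()
  for (s in sheet$sample) {
    reads <- read_fastq(file.path(dir, "fastq", paste0(s, ".fastq")))
    tf <- trim_and_filter(reads, adapter = cfg$sim$adapter %||% "",
                          min_len = cfg$min_len, max_len = cfg$max_len)
    al <- mini_align(tf$reads, genome, cfg$max_mismatch, cfg$max_positions)
    ann <- classify_reads(al, ncrna, pirna)
    df <- as.data.frame(ann$placements)[, c("seqnames", "start", "end",
                                            "strand", "read_id", "mismatches")]
    ri <- match(df$read_id, ann$reads$read_id)
    df$seq <- ann$reads$seq[ri]
    df$x <- ann$reads$x[ri]
    df$category <- ann$reads$category[ri]
    write_tsv_prologue(df, file.path(an_dir, paste0(s, ".placements.tsv")),
                       .stage_params(cfg, sample = s))
    summ[[s]] <- data.frame(sample = s, input = tf$report[["input"]],
                            kept = tf$report[["kept"]], t(ann$summary))
  }
  write_tsv_prologue(do.call(rbind, c(summ, list(make.row.names = FALSE))),
                     file.path(dir, "annotate_summary.tsv"), .stage_params(cfg))
  invisible(NULL)
}

# rebuild annotated_reads objects from the annotate-stage TSVs
.load_annotated <- function(cfg, dir) {
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  pirna <- read_bed(file.path(dir, "pirna.bed"))
  ncrna <- read_bed(file.path(dir, "ncrna.bed"))
  out <- list()
  for (s in sheet$sample) {
    df <- read_tsv_prologue(file.path(dir, "annotated",
                                      paste0(s, ".placements.tsv")))
    pl <- GRanges(df$seqnames, IRanges(df$start, df$end), strand = df$strand,
                  read_id = df$read_id, mismatches = df$mismatches)
    firsts <- !duplicated(df$read_id)
    reads <- data.frame(read_id = df$read_id[firsts], seq = df$seq[firsts],
                        length = nchar(df$seq[firsts]), x = df$x[firsts],
                        stringsAsFactors = FALSE)
    out[[s]] <- classify_reads(aligned_reads(reads, pl), ncrna, pirna)
  }
  list(samples = out, sheet = sheet)
}

.stage_quantify <- function(cfg, dir) {
  ld <- .load_annotated(cfg, dir)
  cm <- build_counts(ld$samples, ld$sheet)
  cdf <- data.frame(pirna_id = rownames(cm$counts),
                    round(cm$counts, 6), check.names = FALSE)
  write_tsv_prologue(cdf, file.path(dir, "counts.tsv"), .stage_params(cfg))
  write_tsv_prologue(data.frame(sample = names(cm$lib_size),
                                lib_size = unname(cm$lib_size)),
                     file.path(dir, "lib_sizes.tsv"), .stage_params(cfg))
  rule <- presence_rule(cfg$presence$min_all, cfg$presence$min_half)
  present <- call_present(cm, rule)
  write_tsv_prologue(data.frame(pirna_id = present),
                     file.path(dir, "presence.tsv"),
                     .stage_params(cfg, min_all = rule$min_all,
                                   min_half = rule$min_half))
  genome <- read_fasta(file.path(dir, "genome.fa"))
  lens <- setNames(Biostrings::width(genome), names(genome))
  rp <- do.call(rbind, lapply(ld$sheet$sample, function(s)
    cbind(sample = s,
          chromosome_rpkm(ld$samples[[s]], lens, present))))
  write_tsv_prologue(rp, file.path(dir, "rpkm.tsv"), .stage_params(cfg))
  # presence sets per tissue (>= 2 tissues) or per group
  by <- if (length(unique(ld$sheet$tissue)) >= 2L) "tissue" else "group"
  sets <- lapply(split(ld$sheet$sample, ld$sheet[[by]]), function(ss) {
    sub <- cm
    sub$counts <- cm$counts[, ss, drop = FALSE]
    call_present(sub, rule)
  })
  if (length(sets) >= 2L)
    write_tsv_prologue(compare_sets(sets), file.path(dir, "venn.tsv"),
                       .stage_params(cfg, by = by))
  invisible(NULL)
}

.stage_context <- function(cfg, dir) {
  ld <- .load_annotated(cfg, dir)
  repeats <- read_bed(file.path(dir, "repeats.bed"))
  tx <- read_gtf_features(file.path(dir, "transcripts.gtf"))
  profs <- lapply(ld$samples, profile_context, repeat_track = repeats,
                  transcript_track = tx)
  long <- do.call(rbind, lapply(names(profs), function(s)
    cbind(sample = s, profs[[s]])))
  write_tsv_prologue(long, file.path(dir, "context.tsv"), .stage_params(cfg))
  gc <- gene_pirna_counts(ld$samples, tx)
  write_tsv_prologue(data.frame(gene_id = rownames(gc), round(gc, 6),
                                check.names = FALSE),
                     file.path(dir, "gene_counts.tsv"), .stage_params(cfg))
  write_tsv_prologue(
    data.frame(gene_id = pirna_aligned_genes(gc, "stringent")),
    file.path(dir, "pirna_aligned_genes.tsv"),
    .stage_params(cfg, rule = "stringent"))
  grp <- split(ld$sheet$sample, ld$sheet$group)
  if (length(grp) >= 2L && all(lengths(grp[1:2]) >= 2L)) {
    gnames <- cfg$de_groups %||% names(grp)[1:2]
    cmpx <- do.call(rbind, lapply(
      c(.transposon_classes, "pseudogene", "protein_coding", "lncRNA"),
      function(cl) compare_context(profs[grp[[gnames[1]]]],
                                   profs[grp[[gnames[2]]]], cl)))
    write_tsv_prologue(cmpx, file.path(dir, "context_comparison.tsv"),
                       .stage_params(cfg, groups = gnames))
  }
  invisible(NULL)
}

.stage_signatures <- function(cfg, dir) {
  ld <- .load_annotated(cfg, dir)
  rows <- list(); spec <- list(); hist <- list()
  for (s in ld$sheet$sample) {
    prof <- length_base_profile(ld$samples[[s]])
    pp <- pingpong_statistic(ld$samples[[s]], z_threshold = cfg$z_threshold)
    bt <- bias_test(prof)
    rows[[s]] <- data.frame(sample = s, n_reads = prof$n_reads,
                            u1_fraction = prof$u1_fraction,
                            a10_fraction = prof$a10_fraction,
                            u1_p = bt$p_value[1], a10_p = bt$p_value[2],
                            pingpong_z = pp$z, verdict = pp$signal)
    spec[[s]] <- data.frame(sample = s, k = seq_along(pp$spectrum),
                            weighted_count = unname(pp$spectrum))
    h <- as.data.frame(as.table(prof$length_hist),
                       stringsAsFactors = FALSE)
    names(h) <- c("length", "first_base", "fraction")
    hist[[s]] <- cbind(sample = s, h)
  }
  pars <- .stage_params(cfg, z_threshold = cfg$z_threshold)
  write_tsv_prologue(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                     file.path(dir, "signatures.tsv"), pars)
  write_tsv_prologue(do.call(rbind, c(spec, list(make.row.names = FALSE))),
                     file.path(dir, "overlap_spectrum.tsv"), pars)
  write_tsv_prologue(do.call(rbind, c(hist, list(make.row.names = FALSE))),
                     file.path(dir, "length_hist.tsv"), pars)
  invisible(NULL)
}

.load_count_matrix <- function(dir) {
  cdf <- read_tsv_prologue(file.path(dir, "counts.tsv"))
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$pirna_id
  lib <- read_tsv_prologue(file.path(dir, "lib_sizes.tsv"))
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  structure(list(counts = counts,
                 lib_size = setNames(lib$lib_size, lib$sample)[colnames(counts)],
                 samples = sheet[match(colnames(counts), sheet$sample), ]),
            class = "count_matrix")
}

.stage_stats <- function(cfg, dir) {
  cm <- .load_count_matrix(dir)
  present <- read_tsv_prologue(file.path(dir, "presence.tsv"))$pirna_id
  cm$counts <- cm$counts[rownames(cm$counts) %in% present, , drop = FALSE]
  g <- cfg$de_groups
  de <- diff_expression(cm, g[1], g[2], alpha = cfg$alpha)
  write_tsv_prologue(de, file.path(dir, "de.tsv"),
                     .stage_params(cfg, groups = g, alpha = cfg$alpha))
  gmt <- read_gmt(file.path(dir, "genesets.gmt"))
  gc <- read_tsv_prologue(file.path(dir, "gene_counts.tsv"))
  universe <- gc$gene_id
  query <- read_tsv_prologue(file.path(dir, "pirna_aligned_genes.tsv"))$gene_id
  query <- intersect(query, universe)
  if (length(query) > 0L) {
    en <- suppressWarnings(enrich(query, gmt, universe))
    write_tsv_prologue(en, file.path(dir, "enrichment.tsv"), .stage_params(cfg))
  }
  invisible(NULL)
}

.stage_classify <- function(cfg, dir) {
  cm <- .load_count_matrix(dir)
  present <- read_tsv_prologue(file.path(dir, "presence.tsv"))$pirna_id
  cm$counts <- cm$counts[rownames(cm$counts) %in% present, , drop = FALSE]
  g <- cfg$de_groups
  sel <- cm$samples$group %in% g
  X <- t(cpm(cm)[, cm$samples$sample[sel], drop = FALSE])
  y <- cm$samples$group[sel]
  rep_cv <- tune_and_evaluate(X, y, h_grid = cfg$h_grid,
                              keepX_grid = cfg$keepX_grid,
                              seed = cfg$sim$seed %||% 1L)
  pars <- .stage_params(cfg, groups = g)
  write_tsv_prologue(
    data.frame(best_ncomp = rep_cv$best_ncomp,
               best_keepX = paste(rep_cv$best_keepX, collapse = ","),
               loo_accuracy = rep_cv$accuracy, auc = rep_cv$auc),
    file.path(dir, "cv_report.tsv"), pars)
  write_tsv_prologue(rep_cv$predictions, file.path(dir, "cv_predictions.tsv"),
                     pars)
  write_tsv_prologue(vip(rep_cv$model), file.path(dir, "vip.tsv"), pars)
  jsonlite::write_json(
    list(ncomp = rep_cv$best_ncomp, keepX = rep_cv$best_keepX,
         features = rep_cv$model$features, levels = rep_cv$model$levels,
         loadings = apply(rep_cv$model$W, 2L, function(w) as.list(
           setNames(w[w != 0], rep_cv$model$features[w != 0])),
           simplify = FALSE)),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Run the full pipeline (or a subset of stages)
#'
#' Stages run in order (simulate, annotate, quantify, context, signatures,
#' stats, classify), each writing TSV intermediates into `out_dir`; a
#' manifest records every stage's outputs with md5 checksums. A failing
#' stage halts the run with the stage named; earlier outputs are kept.
#' Re-running a suffix of the stage list reuses the intermediates on disk.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of stages to run, in pipeline order.
#' @return path to the manifest TSV, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir, stages = .pipeline_stages) {
  stopifnot(is(cfg, "run_config"))
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  funs <- list(simulate = .stage_simulate, annotate = .stage_annotate,
               quantify = .stage_quantify, context = .stage_context,
               signatures = .stage_signatures, stats = .stage_stats,
               classify = .stage_classify)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  rows <- list()
  for (st in .pipeline_stages[.pipeline_stages %in% stages]) {
    t_start <- Sys.time()
    t0 <- proc.time()[["elapsed"]]
    tryCatch(funs[[st]](cfg, out_dir),
             error = function(e) {
               stopf("pipeline stage '%s' failed: %s", st,
                     conditionMessage(e))
             })
    after <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    written <- after[file.info(after)$mtime >= t_start]
    outs <- sort(unique(sub(paste0("^", out_dir, "/?"), "", written)))
    rows[[st]] <- data.frame(
      stage = st,
      outputs = paste(outs, collapse = ","),
      checksums = paste(unname(tools::md5sum(file.path(out_dir, outs))),
                        collapse = ","),
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))
  }
  write_tsv_prologue(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                     manifest_path, .stage_params(cfg))
  invisible(manifest_path)
}
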