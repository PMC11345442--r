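#' Simulate a complete analysis bundle to disk
#'
#' Generates a genome, gene/exon and repeat annotations, per-sample eccDNA
#' catalogs, copy-number segments, an H/L cell expression matrix, a patient
#' expression matrix and a survival cohort whose hazard contrast aligns
#' with the planted expression classes, and writes everything (plus truth
#' tables) under `outdir`.
#'
#' @param config a [sim_config].
#' @param outdir output directory (created if missing).
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_bundle <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "ecc"), showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  genome <- generate_genome(config)
  annotation <- generate_annotation(genome, config)
  cat_out <- generate_eccdna_catalogs(genome, annotation, config)
  cn <- generate_cn_segments(config,
                             chrom_lengths = genome$chrom_lengths)
  expr <- generate_expression(config)
  # patient arm: planted expression classes drive the survival hazard
  n_pat <- config$surv_n
  labels_p <- rep(c("H", "L"), length.out = n_pat)
  expr_p <- generate_expression(config, labels_p, prefix = "P",
                                stream = "patient_expression")
  with_seed(derive_seed(config$seed, "patient_scores"), {
    scores_p <- as.numeric(labels_p == "H") + rnorm(n_pat, 0, 0.1)
  })
  cohort <- generate_survival_cohort(config, scores = scores_p)
  cohort$id <- colnames(expr_p$matrix)

  p <- function(...) file.path(outdir, ...)
  write_genome_fasta(genome, p("genome.fa"))
  gf <- annotation$genes$features
  write_annotation(annotation_track(gf[gf$feature_class == "gene", ]),
                   p("genes.bed"))
  write_annotation(annotation_track(gf[gf$feature_class == "exon", ]),
                   p("exons.bed"))
  write_annotation(annotation$repeats, p("repeats.bed"))
  for (ct in cat_out$catalogs) {
    write_eccdna_catalog(ct, p("ecc", paste0(ct$sample_id, ".bed")))
  }
  samples <- cat_out$truth$samples[, c("sample_id", "mapped_read_total")]
  write.table(samples, p("samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_cn_segments(cn, p("cn_segments.tsv"))
  write_expression_matrix(expr$matrix, p("expression.tsv"))
  write.table(data.frame(sample = names(expr$groups), group = expr$groups),
              p("expr_groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_expression_matrix(expr_p$matrix, p("expression_patients.tsv"))
  write_survival_table(cohort[, c("id", "time", "event", "score")],
                       p("survival.tsv"))
  write.table(cat_out$truth$samples, p("truth", "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cat_out$truth$windows, p("truth", "windows.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(expr$truth[expr$truth$direction != "none", ],
              p("truth", "de_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort[, c("id", "truth_stratum")],
              p("truth", "survival_strata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(genome = genome, annotation = annotation,
                 catalogs = cat_out$catalogs, truth = cat_out$truth,
                 cn = cn, expression = expr, expression_patients = expr_p,
                 cohort = cohort, outdir = outdir))
}
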