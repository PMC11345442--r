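#' Pipeline run configuration
#'
#' Validates all input paths of a bundle directory (layout of
#' [simulate_bundle()]) and fixes every tunable of the downstream stages.
#' One master seed governs all stochastic stages through labelled derived
#' streams, so two runs under the same configuration are byte-identical.
#'
#' @param bundle_dir directory holding genome.fa, genes.bed, exons.bed,
#'   repeats.bed, ecc/*.bed, samples.tsv, cn_segments.tsv, expression.tsv,
#'   expr_groups.tsv, expression_patients.tsv, survival.tsv.
#' @param out_dir report output directory.
#' @param seed master seed.
#' @param window density-correlation window (bp, >= 10 kb).
#' @param gc_n_random background stretches per record in the GC stage.
#' @param gc_max_records per-sample record cap for the GC stage (records
#'   subsampled deterministically beyond it).
#' @param nmf_restarts NMF restarts.
#' @param fc_threshold,de_alpha differential-expression gates.
#' @param panel_size gene-panel size.
#' @param min_group_frac minimum group fraction for the optimal cutoff.
#' @param n_perm permutations for the cutoff-adjusted p-value.
#' @return an object of class `run_config`.
#' @export
run_config <- function(bundle_dir, out_dir, seed = 1L, window = 1e4,
                       gc_n_random = 100L, gc_max_records = 300L,
                       nmf_restarts = 20L, fc_threshold = 1.2,
                       de_alpha = 0.05, panel_size = 100L,
                       min_group_frac = 0.2, n_perm = 200L) {
  need <- c("genome.fa", "genes.bed", "exons.bed", "repeats.bed",
            "samples.tsv", "cn_segments.tsv", "expression.tsv",
            "expr_groups.tsv", "expression_patients.tsv", "survival.tsv")
  for (f in need) {
    assert_that(file.exists(file.path(bundle_dir, f)),
                sprintf("missing input: %s", file.path(bundle_dir, f)))
  }
  beds <- list.files(file.path(bundle_dir, "ecc"), pattern = "\\.bed$",
                     full.names = TRUE)
  assert_that(length(beds) >= 2, "need at least two catalogs under ecc/")
  cfg <- as.list(environment())
  cfg$catalog_paths <- beds
  class(cfg) <- "run_config"
  cfg
}

stage_params <- function(config, stage, extra = list()) {
  c(list(stage = stage, seed = config$seed), extra)
}

#' Run the full characterization and outcome pipeline
#'
#' Executes characterize, gc-profile, elements, group and survival in
#' order, writing eight TSV reports (each with a metadata preamble) under
#' `config$out_dir`: abundance, sizes, gene_derivation, density_corr, gc,
#' elements, groups and survival_report. Any stage error aborts the run
#' with the failing stage named.
#'
#' @param config a [run_config].
#' @return invisibly, a named list of report paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "load"
  out <- tryCatch({
    bp <- function(f) file.path(config$bundle_dir, f)
    op <- function(f) file.path(config$out_dir, f)
    genome <- read_genome_fasta(bp("genome.fa"))
    genes <- read_annotation(bp("genes.bed"), "gene_bed")
    exons <- read_annotation(bp("exons.bed"), "exon_bed")
    repeats <- read_annotation(bp("repeats.bed"), "repeat_bed")
    samples <- read.delim(bp("samples.tsv"), stringsAsFactors = FALSE)
    catalogs <- lapply(config$catalog_paths, function(pth) {
      sid <- sub("\\.bed$", "", basename(pth))
      mrt <- samples$mapped_read_total[match(sid, samples$sample_id)]
      read_eccdna_catalog(pth, "circlemap_bed", mapped_read_total = mrt,
                          sample_id = sid)
    })
    names(catalogs) <- vapply(catalogs, `[[`, "", "sample_id")
    lens <- genome$chrom_lengths
    reports <- list()

    stage <- "characterize"
    ab <- lapply(catalogs, compute_abundance, chrom_lengths = lens)
    ab_df <- do.call(rbind, lapply(ab, function(a) {
      data.frame(sample_id = a$sample_id, n_records = a$n_records,
                 epm = a$epm, t(a$chrom_share), check.names = FALSE)
    }))
    pooled_cnt <- Reduce(`+`, lapply(catalogs, function(ct)
      table(factor(ct$records$chrom, levels = names(lens)))))
    pooled_dens <- as.numeric(pooled_cnt) / (lens / 1e6)
    pooled <- data.frame(sample_id = "pooled",
                         n_records = sum(ab_df$n_records),
                         epm = NA_real_,
                         t(pooled_dens / sum(pooled_dens) * 100),
                         check.names = FALSE)
    names(pooled)[-(1:3)] <- names(lens)
    reports$abundance <- write_report_tsv(rbind(ab_df, pooled),
      op("abundance.tsv"), stage_params(config, "characterize"))

    pooled_rec <- do.call(rbind, lapply(catalogs, function(ct)
      ct$records[, c("chrom", "start", "end")]))
    sd_ <- size_distribution(pooled_rec, bin_width = 100)
    reports$sizes <- write_report_tsv(sd_$histogram, op("sizes.tsv"),
      stage_params(config, "characterize",
                   list(modal_bin_start = sd_$modal_bin[["start"]],
                        modal_bin_end = sd_$modal_bin[["end"]])))

    gd <- gene_derivation(catalogs, genes)
    spanned <- table(factor(pmin(gd$per_species$n_genes, 10L), levels = 0:10))
    reports$gene_derivation <- write_report_tsv(gd$per_gene,
      op("gene_derivation.tsv"),
      stage_params(config, "characterize",
                   list(n_species = gd$n_species,
                        spanned_gene_histogram_0_to_10plus =
                          paste(as.numeric(spanned), collapse = ","))))

    dc_gene <- density_correlation(catalogs, lens, genes,
                                   window = config$window)
    dc_alu <- density_correlation(catalogs, lens, repeats,
                                  window = config$window,
                                  covariate_classes = "Alu")
    reports$density_corr <- write_report_tsv(
      data.frame(covariate = c("gene", "Alu"),
                 window = config$window,
                 n_windows = c(dc_gene$n_windows, dc_alu$n_windows),
                 r = c(dc_gene$r, dc_alu$r),
                 p_value = c(dc_gene$p_value, dc_alu$p_value)),
      op("density_corr.tsv"),
      stage_params(config, "characterize", list(window = config$window)))

    stage <- "gc-profile"
    gc_rows <- lapply(catalogs, function(ct) {
      r <- ct$records[ct$records$chrom %in% genome$chrom_names, ,
                      drop = FALSE]
      if (nrow(r) > config$gc_max_records) {
        keep <- with_seed(derive_seed(config$seed,
                                      paste0("gcsub_", ct$sample_id)),
                          sort(sample.int(nrow(r), config$gc_max_records)))
        r <- r[keep, , drop = FALSE]
      }
      sub <- eccdna_catalog(ct$sample_id, r, ct$mapped_read_total)
      fp <- flank_profile(sub, genome)
      en <- gc_enrichment_test(sub, genome, n_random = config$gc_n_random,
                               seed = derive_seed(config$seed,
                                                  paste0("gc_", ct$sample_id)))
      data.frame(sample_id = ct$sample_id, n_records = en$n_records,
                 mean_locus_gc = en$mean_locus_gc,
                 mean_upstream_gc = mean(fp$upstream_gc, na.rm = TRUE),
                 mean_downstream_gc = mean(fp$downstream_gc, na.rm = TRUE),
                 mean_background_gc = en$mean_background_gc,
                 genome_gc = en$genome_gc,
                 statistic = en$statistic, p_value = en$p_value,
                 direction = en$direction)
    })
    reports$gc <- write_report_tsv(do.call(rbind, gc_rows), op("gc.tsv"),
      stage_params(config, "gc-profile",
                   list(n_random = config$gc_n_random,
                        max_records = config$gc_max_records)))

    stage <- "elements"
    gene_exon <- annotation_track(rbind(genes$features, exons$features))
    part <- build_region_partition(gene_exon, lens)
    cls <- classify_records(pooled_rec, part)
    region_df <- data.frame(kind = "region_frequency",
                            class = names(cls$counts),
                            count = as.numeric(cls$counts),
                            value = as.numeric(cls$frequencies),
                            ci_lo = NA_real_, ci_hi = NA_real_)
    nmr <- normalized_mapping_ratio(pooled_rec, repeats, lens,
                                    n_boot = 100L,
                                    seed = derive_seed(config$seed, "nmr"))
    ratio_df <- data.frame(kind = "element_ratio", class = nmr$class,
                           count = nmr$n_overlapping, value = nmr$ratio,
                           ci_lo = nmr$ci_lo, ci_hi = nmr$ci_hi)
    reports$elements <- write_report_tsv(rbind(region_df, ratio_df),
      op("elements.tsv"), stage_params(config, "elements"))

    stage <- "group"
    fm <- abundance_feature_matrix(catalogs, lens)
    epm <- setNames(vapply(ab, `[[`, 0, "epm"),
                    vapply(ab, `[[`, "", "sample_id"))
    grp <- nmf_group(fm, epm, n_restarts = config$nmf_restarts,
                     seed = derive_seed(config$seed, "nmf"))
    cn_sets <- read_cn_segments(bp("cn_segments.tsv"), lens)
    wg <- lapply(cn_sets, compute_wgii, chrom_lengths = lens)
    assoc <- instability_association(wg, epm, labels = grp$labels)
    wg_v <- setNames(vapply(wg, `[[`, 0, "wgii"),
                     vapply(wg, `[[`, "", "sample_id"))
    groups_df <- data.frame(sample_id = names(grp$labels),
                            nmf_label = unname(grp$labels),
                            epm = unname(epm[names(grp$labels)]),
                            wgii = unname(wg_v[names(grp$labels)]))
    reports$groups <- write_report_tsv(groups_df, op("groups.tsv"),
      stage_params(config, "group",
                   list(nmf_restarts = config$nmf_restarts,
                        wgii_epm_pearson_r = assoc$pearson_r,
                        wgii_epm_pearson_p = assoc$pearson_p,
                        wgii_HL_contrast_p =
                          assoc$group_contrast$p_value %||% NA_real_)))

    stage <- "survival"
    expr <- read_expression_matrix(bp("expression.tsv"))
    eg <- read.delim(bp("expr_groups.tsv"), stringsAsFactors = FALSE)
    egroups <- setNames(eg$group, eg$sample)
    de <- differential_expression(expr, egroups,
                                  fc_threshold = config$fc_threshold,
                                  alpha = config$de_alpha)
    panel <- build_panel(de, n = config$panel_size)
    expr_p <- read_expression_matrix(bp("expression_patients.tsv"))
    scores <- ssgsea_score(expr_p, panel)
    cohort <- read_survival_table(bp("survival.tsv"))
    oc <- optimal_cutoff(scores, cohort,
                         min_group_frac = config$min_group_frac,
                         n_perm = config$n_perm,
                         seed = derive_seed(config$seed, "cutoff"))
    markers <- head(panel[panel %in% rownames(expr_p)], 2)
    aucs <- vapply(markers, function(g) {
      roc_auc(expr_p[g, cohort$id],
              as.integer(oc$labels[cohort$id] == "high"))$auc
    }, 0)
    surv_df <- data.frame(
      cutoff = oc$cutoff,
      n_high = as.numeric(oc$group_sizes[["high"]]),
      n_low = as.numeric(oc$group_sizes[["low"]]),
      logrank_chisq = oc$chisq,
      p_naive = oc$p_naive,
      p_adjusted = oc$p_adjusted,
      hazard_ratio = oc$km$hazard_ratio,
      n_up_genes = sum(de$call == "up"),
      n_down_genes = sum(de$call == "down"),
      panel_size = length(panel),
      marker1 = markers[1] %||% NA_character_,
      marker1_auc = if (length(aucs) >= 1) aucs[1] else NA_real_,
      marker2 = if (length(markers) >= 2) markers[2] else NA_character_,
      marker2_auc = if (length(aucs) >= 2) aucs[2] else NA_real_)
    reports$survival <- write_report_tsv(surv_df, op("survival_report.tsv"),
      stage_params(config, "survival",
                   list(fc_threshold = config$fc_threshold,
                        panel_size = config$panel_size,
                        min_group_frac = config$min_group_frac,
                        n_perm = config$n_perm)))
    reports
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(out)
}
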