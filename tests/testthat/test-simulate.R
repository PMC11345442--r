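quick_cfg <- function(...) {
  sim_config(seed = 1, n_chrom = 1, chrom_length = 1e5, n_samples = 2,
             abundance_split = c(H = 500, L = 100), ...)
}

test_that("generated genomes realize the target GC landscape", {
  cfg <- quick_cfg(gc_landscape = 0.5)
  g <- generate_genome(cfg)
  expect_gt(genome_gc_total(g), 0.47)
  expect_lt(genome_gc_total(g), 0.53)
  # per 10-kb window within 0.03 of target
  ws <- (0:9) * 1e4
  wgc <- genome_gc(g, rep("chr1", 10), ws, ws + 1e4)
  expect_true(all(abs(wgc - 0.5) < 0.03))

  g1 <- generate_genome(quick_cfg(gc_landscape = 1))
  expect_equal(genome_gc_total(g1), 1)

  expect_identical(as.character(generate_genome(cfg)$seq),
                   as.character(generate_genome(cfg)$seq))
  tiny <- sim_config(seed = 1, n_chrom = 1, chrom_length = 100)
  expect_error(generate_genome(tiny), "window")
})

test_that("annotation hits the repeat coverage target and the gene gradient", {
  cfg <- sim_config(seed = 2, n_chrom = 1, chrom_length = 1e6, n_samples = 2,
                    repeat_fraction = 0.525)
  g <- generate_genome(cfg)
  ann <- generate_annotation(g, cfg)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    ann$repeats$features$chrom,
    IRanges::IRanges(ann$repeats$features$start + 1,
                     ann$repeats$features$end)))
  cov <- sum(as.numeric(GenomicRanges::width(gr)))
  expect_gte(cov, 505000)
  expect_lte(cov, 545000)

  ann0 <- generate_annotation(g, sim_config(seed = 2, n_chrom = 1,
                                            chrom_length = 1e6,
                                            repeat_fraction = 0))
  expect_equal(nrow(ann0$repeats$features), 0L)

  # gradient: per-window gene counts increase along the chromosome
  counts <- 0
  for (s in 1:6) {
    cfg2 <- sim_config(seed = s, n_chrom = 1, chrom_length = 1e6,
                       gene_density_gradient = c(5, 120),
                       repeat_fraction = 0)
    ann2 <- generate_annotation(generate_genome(cfg2), cfg2)
    gf <- ann2$genes$features
    gf <- gf[gf$feature_class == "gene", ]
    mid <- (gf$start + gf$end) %/% 2
    counts <- counts + tabulate(mid %/% 1e5 + 1, nbins = 10)
  }
  rho <- cor(counts, 1:10, method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("catalog placement is unbiased without planted structure", {
  cfg <- sim_config(seed = 3, n_chrom = 1, chrom_length = 1e6, n_samples = 2,
                    abundance_split = c(H = 10000, L = 100),
                    gene_density_gradient = c(10, 10))
  g <- generate_genome(cfg)
  ann <- generate_annotation(g, cfg)
  cc <- generate_eccdna_catalogs(g, ann, cfg)
  r <- cc$catalogs[[1]]$records
  locus_gc <- genome_gc(g, r$chrom, r$start, r$end)
  expect_lt(abs(mean(locus_gc) - genome_gc_total(g)), 0.01)
})

test_that("H catalogs dominate L catalogs under the abundance split", {
  for (s in 1:3) {
    cfg <- sim_config(seed = s, n_chrom = 2, chrom_length = 2e5,
                      n_samples = 8, abundance_split = c(H = 4000, L = 400))
    g <- generate_genome(cfg)
    ann <- generate_annotation(g, cfg)
    cc <- generate_eccdna_catalogs(g, ann, cfg)
    n <- vapply(cc$catalogs, function(ct) nrow(ct$records), 0)
    lab <- vapply(cc$catalogs, `[[`, "", "group_label")
    expect_gt(min(n[lab == "H"]), max(n[lab == "L"]))
  }
})

test_that("catalog generation is deterministic and truth-recomputable", {
  cfg <- quick_cfg(gc_bias = 2, density_coupling = c(a = 0.5, b = 0.3),
                   gene_density_gradient = c(20, 80))
  g <- generate_genome(cfg)
  ann <- generate_annotation(g, cfg)
  c1 <- generate_eccdna_catalogs(g, ann, cfg)
  c2 <- generate_eccdna_catalogs(g, ann, cfg)
  expect_identical(c1$catalogs[[1]]$records, c2$catalogs[[1]]$records)

  # placement weight recomputable from the emitted truth table
  w <- c1$truth$windows
  gn <- if (max(w$gene_density) > 0) w$gene_density / max(w$gene_density) else 0
  an <- if (max(w$alu_density) > 0) w$alu_density / max(w$alu_density) else 0
  re <- exp(cfg$gc_bias * w$gc) * pmax(0, 1 + 0.5 * gn + 0.3 * an)
  expect_lt(max(abs(re - w$weight)), 1e-9)
})

test_that("eccDNA lengths have the planted sub-100-bp mode", {
  cfg <- sim_config(seed = 4, n_chrom = 1, chrom_length = 5e5, n_samples = 2,
                    abundance_split = c(H = 10000, L = 100))
  g <- generate_genome(cfg)
  ann <- generate_annotation(g, cfg)
  cc <- generate_eccdna_catalogs(g, ann, cfg)
  sd_ <- size_distribution(cc$catalogs[[1]], bin_width = 100)
  expect_lt(sd_$modal_bin[["end"]], 101)
})

test_that("cn segments tile chromosomes and separate group wGII", {
  lens <- c(chr1 = 1e5, chr2 = 8e4)
  cfg <- sim_config(seed = 5, n_samples = 18)
  sets <- generate_cn_segments(cfg, chrom_lengths = lens)
  for (s in sets) {
    for (ch in names(lens)) {
      seg <- s$segments[s$segments$chrom == ch, ]
      expect_equal(sum(seg$end - seg$start), unname(lens[[ch]]))
    }
  }
  wg <- vapply(sets, function(s) compute_wgii(s, lens)$wgii, 0)
  lab <- sim_group_labels(cfg)
  expect_gt(mean(wg[lab == "H"]) - mean(wg[lab == "L"]), 0.3)

  cfg0 <- sim_config(seed = 5, n_samples = 4, wgii_targets = c(H = 0, L = 0),
                     wgii_noise_sd = 0)
  sets0 <- generate_cn_segments(cfg0, chrom_lengths = lens)
  wg0 <- vapply(sets0, function(s) compute_wgii(s, lens)$wgii, 0)
  expect_true(all(wg0 < 0.1))
})

test_that("expression matrices plant recoverable fold changes", {
  cfg <- sim_config(seed = 6, n_genes = 500, n_de = 200, fold_change = 2,
                    expr_sigma = 0.5, expr_n_per_group = 200)
  e1 <- generate_expression(cfg)
  e2 <- generate_expression(cfg)
  expect_identical(e1$matrix, e2$matrix)
  de <- differential_expression(e1$matrix, e1$groups, fc_threshold = 1.2)
  truth_up <- e1$truth$gene[e1$truth$direction == "up"]
  recovered <- sum(de$gene[de$call == "up"] %in% truth_up)
  expect_gte(recovered, 95)

  # no planted DE: adjusted calls stay near zero
  cfg0 <- sim_config(seed = 7, n_genes = 500, n_de = 0,
                     expr_n_per_group = 50)
  e0 <- generate_expression(cfg0)
  de0 <- differential_expression(e0$matrix, e0$groups, fc_threshold = 1.2)
  expect_lte(sum(de0$call != "none"), 0.05 * 500)
})

test_that("survival cohorts realize the planted hazard contrast", {
  cfg <- sim_config(seed = 8, surv_n = 300, survival_hr = 2,
                    censoring_rate = 0.2)
  worse <- 0
  for (r in 1:10) {
    co <- generate_survival_cohort(cfg, stream = paste0("s", r))
    med_hi <- median(co$time[co$truth_stratum == "high"])
    med_lo <- median(co$time[co$truth_stratum == "low"])
    worse <- worse + (med_hi < med_lo)
  }
  expect_gte(worse, 9)

  cfg1 <- sim_config(seed = 8, surv_n = 100, censoring_rate = 1)
  co1 <- generate_survival_cohort(cfg1)
  expect_true(all(co1$event == 0))
})
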