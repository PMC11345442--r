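test_that("EPM and per-chromosome shares follow their definitions", {
  lens <- c(chr1 = 1e6, chr2 = 2e6)
  rec <- recs(rep(c("chr1", "chr2"), c(10, 10)),
              seq(0, by = 1000, length.out = 20), 0)
  rec$end <- rec$start + 100
  ct <- eccdna_catalog("s", rec, mapped_read_total = 1e7)
  ab <- compute_abundance(ct, lens)
  expect_equal(ab$epm, 2)                      # 20 / 1e7 * 1e6
  # densities 10/Mb and 5/Mb -> shares 2/3, 1/3
  expect_equal(unname(ab$chrom_share["chr1"]), 200 / 3, tolerance = 1e-9)
  expect_equal(unname(ab$chrom_share["chr2"]), 100 / 3, tolerance = 1e-9)
  expect_equal(sum(ab$chrom_share), 100, tolerance = 1e-9)

  ct500 <- eccdna_catalog("s2", recs(rep("chr1", 500), 0:499 * 10, 0:499 * 10 + 5),
                          mapped_read_total = 1e7)
  expect_equal(compute_abundance(ct500, lens)$epm, 50)

  empty <- eccdna_catalog("e", recs(character(), integer(), integer()), 1e7)
  abe <- compute_abundance(empty, lens)
  expect_equal(abe$epm, 0)
  expect_true(all(abe$chrom_share == 0))
  ct$mapped_read_total <- NA_real_
  expect_error(compute_abundance(ct, lens), "mapped_read_total")
})

test_that("shares are invariant under uniform scaling of mapped totals", {
  lens <- c(chr1 = 1e6, chr2 = 2e6)
  rec <- recs(sample(c("chr1", "chr2"), 50, TRUE), 0:49 * 100, 0:49 * 100 + 80)
  a1 <- compute_abundance(eccdna_catalog("s", rec, 1e7), lens)
  a2 <- compute_abundance(eccdna_catalog("s", rec, 3e7), lens)
  expect_equal(a1$chrom_share, a2$chrom_share)
})

test_that("size histograms bin lengths with a deterministic modal tie-break", {
  ct <- recs("chr1", c(0, 0, 0), c(50, 60, 150))
  sd_ <- size_distribution(ct, bin_width = 100)
  expect_equal(sd_$histogram$count, c(2, 1))
  expect_equal(unname(sd_$modal_bin), c(0, 100))
  expect_equal(sum(sd_$histogram$count), 3)

  same <- recs("chr1", rep(0, 5), rep(77, 5))
  expect_equal(nrow(size_distribution(same, 100)$histogram), 1L)

  tie <- recs("chr1", c(0, 0), c(50, 150))   # one in each bin
  expect_equal(unname(size_distribution(tie, 100)$modal_bin), c(0, 100))
})

test_that("gene derivation deduplicates species and matches brute force", {
  genes <- annotation_track(data.frame(
    chrom = "chr1", start = c(0, 150, 260), end = c(100, 250, 400),
    feature_class = "gene", gene_id = c("g1", "g2", "g3")))
  one <- eccdna_catalog("a", recs("chr1", 50, 300), 1e6)
  gd <- gene_derivation(one, genes)
  expect_equal(gd$per_species$n_genes, 3L)
  expect_equal(sum(gd$per_gene$n_species), 3L)

  dup1 <- eccdna_catalog("a", recs("chr1", 10, 60), 1e6)
  dup2 <- eccdna_catalog("b", recs("chr1", 10, 60), 1e6)
  gd2 <- gene_derivation(list(dup1, dup2), genes)
  expect_equal(gd2$n_species, 1L)

  # pooling a catalog with itself changes nothing
  gd3 <- gene_derivation(list(dup1, dup1), genes)
  expect_equal(gd3$per_gene, gene_derivation(dup1, genes)$per_gene)

  set.seed(31)
  n <- 200; m <- 20
  sp <- recs("chr1", sample.int(5000, n), 0); sp$end <- sp$start + sample.int(400, n)
  sp <- unique(sp)
  gn <- data.frame(chrom = "chr1", start = sample.int(5000, m), end = 0,
                   feature_class = "gene", gene_id = sprintf("g%02d", 1:m))
  gn$end <- gn$start + sample.int(600, m)
  ct <- eccdna_catalog("r", sp, 1e6)
  gd4 <- gene_derivation(ct, annotation_track(gn))
  oracle <- brute_overlap(ct$records, gn)
  got <- setNames(rep(0L, m), gn$gene_id)
  got[gd4$per_gene$gene_id] <- gd4$per_gene$n_species
  expect_equal(unname(got[gn$gene_id]), unname(oracle$per_gene[gn$gene_id]))
  sp_sorted <- ct$records
  expect_equal(gd4$per_species$n_genes,
               brute_overlap(sp_sorted, gn)$per_species)
})

test_that("density correlation recovers exact and degenerate cases", {
  lens <- c(chr1 = 1e6)
  # construct window counts identical for eccDNA and genes
  k <- rep(1:10, each = 10)
  win_of <- rep(0:99, k[1:100] * 0 + 1)   # windows 0..99
  ecc <- NULL; gen <- NULL
  for (w in 0:99) {
    cnt <- (w %% 10) + 1
    mid <- w * 1e4 + 5000
    ecc <- rbind(ecc, recs("chr1", rep(mid, cnt), rep(mid + 50, cnt)))
    gen <- rbind(gen, data.frame(chrom = "chr1", start = rep(mid, cnt),
                                 end = rep(mid + 100, cnt),
                                 feature_class = "gene",
                                 gene_id = sprintf("g%d_%d", w, 1:cnt)))
  }
  ct <- eccdna_catalog("s", ecc, 1e6)
  dc <- density_correlation(ct, lens, annotation_track(gen), window = 1e4)
  expect_equal(dc$r, 1, tolerance = 1e-12)
  expect_equal(dc$n_windows, 100L)
  expect_error(density_correlation(ct, lens, annotation_track(gen),
                                   window = 5000), ">= 10 kb")
  # constant (all-zero) covariate -> undefined correlation with warning
  expect_warning(
    dc0 <- density_correlation(ct, lens, annotation_track(gen), window = 1e4,
                               covariate_classes = "Alu"),
    "degenerate")
  expect_true(is.na(dc0$r))
})

test_that("drug screen flags exact negative relations and skips sparse drugs", {
  ab <- setNames(c(1, 2, 3, 4, 5, 6), paste0("S", 1:6))
  ic50 <- rbind(drugA = 10 - 1.5 * ab,
                drugB = c(5, 5.1, 4.9, 5.2, 5.05, 4.95),
                drugC = c(2, 3, NA, NA, NA, NA))
  colnames(ic50) <- names(ab)
  expect_warning(res <- drug_sensitivity_correlation(ab, ic50), "drugC")
  expect_false("drugC" %in% res$drug)
  a <- res[res$drug == "drugA", ]
  expect_equal(a$r, -1, tolerance = 1e-12)
  expect_true(a$flagged)
  expect_true(all(c("p_adj", "direction") %in% names(res)))
  expect_false(res$flagged[res$drug == "drugB"])
})
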