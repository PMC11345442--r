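test_that("wGII reproduces hand-computed values", {
  lens <- c(chr1 = 100, chr2 = 100)
  dip <- cn_segment_set("a", data.frame(chrom = c("chr1", "chr2"),
                                        start = 0, end = 100, cn = 2L), lens)
  expect_equal(compute_wgii(dip, lens)$wgii, 0)

  mixed <- cn_segment_set("b", data.frame(chrom = c("chr1", "chr2"),
                                          start = 0, end = 100,
                                          cn = c(3L, 2L)), lens)
  w <- compute_wgii(mixed, lens)
  expect_equal(w$ploidy, 2L)   # length-weighted modal CN over 200 bp
  expect_equal(unname(w$per_chrom), c(1, 0))
  expect_equal(w$wgii, 0.5)

  # every bp at CN 3 against a known diploid baseline -> wGII 1
  tri <- cn_segment_set("c", data.frame(chrom = c("chr1", "chr2"),
                                        start = 0, end = 100, cn = 3L), lens)
  expect_equal(compute_wgii(tri, lens, ploidy = 2L)$wgii, 1)
  # with inferred ploidy the same profile is the baseline itself
  expect_equal(compute_wgii(tri, lens)$wgii, 0)

  lens3 <- c(chr1 = 300, chr2 = 100)
  ab3 <- cn_segment_set("d", data.frame(chrom = c("chr1", "chr2"),
                                        start = 0, end = c(300, 100),
                                        cn = c(2L, 5L)), lens3)
  w3 <- compute_wgii(ab3, lens3)
  expect_equal(w3$ploidy, 2L)
  expect_equal(w3$wgii, 0.5)
})

test_that("wGII agrees with a brute-force per-bp scan on random toys", {
  set.seed(61)
  for (rep in 1:8) {
    lens <- c(chr1 = 5000, chr2 = 3000, chr3 = 2000)
    segs <- NULL
    for (ch in names(lens)) {
      cuts <- sort(sample(seq(100, lens[[ch]] - 100, by = 100),
                          sample(1:4, 1)))
      bounds <- c(0, cuts, lens[[ch]])
      segs <- rbind(segs, data.frame(
        chrom = ch, start = bounds[-length(bounds)], end = bounds[-1],
        cn = sample(0:4, length(bounds) - 1, TRUE)))
    }
    s <- cn_segment_set("t", segs, lens)
    expect_equal(compute_wgii(s, lens)$wgii, brute_wgii(segs, lens),
                 tolerance = 1e-12)
  }
})

test_that("wGII is invariant under splitting segments of equal CN", {
  lens <- c(chr1 = 1000)
  a <- cn_segment_set("a", data.frame(chrom = "chr1", start = c(0, 600),
                                      end = c(600, 1000), cn = c(2L, 3L)),
                      lens)
  b <- cn_segment_set("a", data.frame(chrom = "chr1",
                                      start = c(0, 300, 600, 800),
                                      end = c(300, 600, 800, 1000),
                                      cn = c(2L, 2L, 3L, 3L)), lens)
  expect_equal(compute_wgii(a, lens)$wgii, compute_wgii(b, lens)$wgii)
})

test_that("sex-chromosome exclusion drops chromosomes from the mean", {
  lens <- c(chr1 = 100, chrX = 100)
  s <- cn_segment_set("a", data.frame(chrom = c("chr1", "chrX"), start = 0,
                                      end = 100, cn = c(2L, 4L)), lens)
  expect_equal(compute_wgii(s, lens)$wgii, 0.5)
  expect_equal(compute_wgii(s, lens, exclude = "chrX")$wgii, 0)
})

test_that("NMF recovers block structure and is duplication-consistent", {
  set.seed(62)
  blockA <- matrix(rep(c(5, 5, 0, 0), each = 5), 5, 4) + runif(20, 0, 0.01)
  blockB <- matrix(rep(c(0, 0, 5, 5), each = 5), 5, 4) + runif(20, 0, 0.01)
  m <- rbind(blockA, blockB)
  rownames(m) <- paste0("S", 1:10)
  ab <- setNames(c(rep(10, 5), rep(1, 5)), rownames(m))
  g <- nmf_group(m, ab, n_restarts = 10, seed = 1)
  expect_true(all(g$labels[1:5] == "H") && all(g$labels[6:10] == "L"))
  expect_true(all(diff(g$trace) <= 1e-8 * max(g$trace[1], 1)))

  dup <- rbind(m, m[1, , drop = FALSE])
  rownames(dup) <- c(rownames(m), "S1b")
  ab2 <- c(ab, S1b = 10)
  g2 <- nmf_group(dup, ab2, n_restarts = 10, seed = 1)
  expect_equal(unname(g2$labels["S1"]), unname(g2$labels["S1b"]))

  neg <- m; neg[1, 1] <- -1
  expect_error(nmf_group(neg, ab), "non-negative")
  expect_error(nmf_group(m[1:3, ], ab[1:3]), "4 samples")
})

test_that("feature matrix augmentation mirrors columns at the cohort max", {
  ct1 <- eccdna_catalog("A", recs("chr1", c(0, 10), c(5, 20)), 1e6)
  ct2 <- eccdna_catalog("B", recs("chr1", 0, 5), 2e6)
  lens <- c(chr1 = 1000)
  fm <- abundance_feature_matrix(list(ct1, ct2), lens)
  expect_equal(dim(fm), c(2L, 2L))
  expect_equal(unname(fm[, "chr1_mirror"]),
               unname(max(fm[, "chr1"]) - fm[, "chr1"]))
  plain <- abundance_feature_matrix(list(ct1, ct2), lens, augment = FALSE)
  expect_equal(colnames(plain), "chr1")
  expect_equal(unname(plain["A", 1]), 2 / 1e6 * 1e6)
})

test_that("instability association reports correlations and group contrast", {
  set.seed(63)
  wg <- lapply(1:12, function(i) {
    list(sample_id = paste0("S", i), wgii = c(rep(0.6, 6), rep(0.1, 6))[i] +
           runif(1, 0, 0.05))
  })
  ab <- setNames(c(rnorm(6, 100, 5), rnorm(6, 10, 2)), paste0("S", 1:12))
  lab <- setNames(rep(c("H", "L"), each = 6), paste0("S", 1:12))
  ia <- instability_association(wg, ab, labels = lab)
  expect_gt(ia$pearson_r, 0.8)
  expect_lt(ia$group_contrast$p_value, 0.01)
  expect_gt(ia$group_contrast$mean_H, ia$group_contrast$mean_L)

  wg0 <- lapply(wg, function(x) { x$wgii <- 0.5; x })
  expect_warning(ia0 <- instability_association(wg0, ab), "degenerate")
  expect_true(is.na(ia0$pearson_r))
})
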