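test_that("circlemap dialect maps columns and rejects bad rows", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t250\t4\t7\t33.2", f)
  ct <- read_eccdna_catalog(f, "circlemap_bed", mapped_read_total = 1e6)
  expect_equal(nrow(ct$records), 1L)
  expect_equal(ct$records$start, 100)
  expect_equal(ct$records$end, 250)
  expect_equal(ct$records$split_reads, 7)
  expect_equal(ct$records$discordant_reads, 4)
  expect_equal(ct$records$score, 33.2)

  writeLines("chr1\t250\t250\t4\t7\t33.2", f)
  expect_error(read_eccdna_catalog(f, "circlemap_bed"),
               "zero-length interval, line 1")
  writeLines("chr1\tXX\t250\t4\t7\t33.2", f)
  expect_error(read_eccdna_catalog(f, "circlemap_bed"),
               "malformed coordinate, line 1")
  writeLines("chr1\t100\t250", f)
  expect_error(read_eccdna_catalog(f, "circlemap_bed"), "columns")
})

test_that("plain_bed defaults read supports to zero and counts rows", {
  f <- withr::local_tempfile(fileext = ".bed")
  set.seed(5)
  n <- 10L
  s <- sort(sample.int(1000, n))
  writeLines(sprintf("chr%d\t%d\t%d", rep(1:2, 5), s, s + 50), f)
  expect_equal(length(readLines(f)), n)   # independent line count
  ct <- read_eccdna_catalog(f, "plain_bed")
  expect_equal(nrow(ct$records), n)
  expect_true(all(ct$records$split_reads == 0))
})

test_that("catalog write/read round-trips coordinates and counts exactly", {
  set.seed(11)
  n <- 40
  st <- sample.int(5000, n)
  rec <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                    start = st, end = st + sample.int(300, n),
                    split_reads = rpois(n, 3), discordant_reads = rpois(n, 2),
                    score = round(runif(n, 0, 100), 2))
  ct <- eccdna_catalog("s1", rec, 1e6)
  f <- withr::local_tempfile(fileext = ".bed")
  write_eccdna_catalog(ct, f)
  ct2 <- read_eccdna_catalog(f, "circlemap_bed", mapped_read_total = 1e6,
                             sample_id = "s1")
  expect_equal(ct2$records, ct$records)
})

test_that("min_split filter drops weakly supported calls", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\t1\t1\t5", "chr1\t200\t300\t1\t4\t5"), f)
  ct <- read_eccdna_catalog(f, "circlemap_bed", min_split = 2)
  expect_equal(nrow(ct$records), 1L)
  expect_equal(ct$records$start, 200)
})

test_that("FASTA reading uppercases, sums wrapped lines, rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrA", "acgt"), f)
  g <- read_genome_fasta(f)
  expect_equal(unname(g$chrom_lengths["chrA"]), 4L)
  expect_equal(as.character(g$seq[["chrA"]]), "ACGT")

  seq120 <- paste(rep("ACGTA", 24), collapse = "")
  writeLines(c(">chrB", substr(seq120, 1, 60), substr(seq120, 61, 120)), f)
  g2 <- read_genome_fasta(f)
  expect_equal(unname(g2$chrom_lengths["chrB"]), 120L)

  writeLines(c(">chrA", "ACGT", ">chrA", "GGGG"), f)
  expect_error(read_genome_fasta(f), "duplicate")
})

test_that("genome FASTA round-trips through write and read", {
  g <- toy_genome(chr1 = "ACGTACGTACGTNNACGT", chr2 = "GGGCCC")
  f <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, f, width = 7)
  g2 <- read_genome_fasta(f)
  expect_equal(as.character(g2$seq), as.character(g$seq))
})

test_that("repeat class labels normalize to the closed vocabulary", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t300\tSINE/Alu",
               "chr1\t400\t700\tSimple_repeat",
               "chr1\t800\t900\tLINE/L1",
               "chr1\t950\t990\tSINE/MIR"), f)
  tr <- read_annotation(f, "repeat_bed")
  expect_equal(tr$features$feature_class,
               c("Alu", "simple_repeat", "LINE", "SINE"))
  writeLines("chr1\t0\t300\tWeirdRepeatXYZ", f)
  expect_warning(tr2 <- read_annotation(f, "repeat_bed"), "other_repeat")
  expect_equal(tr2$features$feature_class, "other_repeat")
})

test_that("gene BED rows become gene features carrying gene_id", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t%d\t%d\tG%d", (0:4) * 1000, (0:4) * 1000 + 500, 1:5), f)
  tr <- read_annotation(f, "gene_bed")
  expect_equal(nrow(tr$features), 5L)
  expect_true(all(tr$features$feature_class == "gene"))
  expect_setequal(tr$features$gene_id, paste0("G", 1:5))
  writeLines("chr1\t0\t300", f)
  expect_error(read_annotation(f, "repeat_bed"), "class")
})

test_that("cn segment sets enforce tiling and survive a TSV round trip", {
  seg <- data.frame(chrom = "chr1", start = c(0, 400), end = c(400, 1000),
                    cn = c(2L, 3L))
  s <- cn_segment_set("a", seg, c(chr1 = 1000))
  expect_s3_class(s, "cn_segment_set")
  expect_error(cn_segment_set("a", seg[2, , drop = FALSE], c(chr1 = 1000)),
               "gap")
  bad <- seg; bad$start[2] <- 500
  expect_error(cn_segment_set("a", bad), "gap|overlap")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cn_segments(list(s), f)
  back <- read_cn_segments(f, c(chr1 = 1000))
  expect_equal(back[["a"]]$segments$cn, seg$cn)
})

test_that("0-based half-open conversion preserves widths and overlaps", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 30
    a <- recs("chr1", sample.int(500, n), 0)
    a$end <- a$start + sample.int(80, n)
    b <- recs("chr1", sample.int(500, n), 0)
    b$end <- b$start + sample.int(80, n)
    ga <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1, a$end))
    gb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1, b$end))
    expect_equal(GenomicRanges::width(ga), a$end - a$start)
    hits <- GenomicRanges::findOverlaps(ga, gb)
    got <- sort(paste(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits)))
    want <- character(0)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        want <- c(want, paste(i, j))
      }
    }
    expect_equal(got, sort(want))
  }
})

test_that("report TSVs carry a metadata preamble and read back", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(x = 1:3, y = c("a", "b", "c"))
  write_report_tsv(df, f, params = list(seed = 7, window = 1e4))
  lines <- readLines(f)
  expect_true(any(grepl("^# seed: 7", lines)))
  expect_equal(read_report_tsv(f), df)
})

test_that("off-genome records are kept in counts but flagged", {
  g <- toy_genome(chr1 = strrep("ACGT", 100))
  ct <- eccdna_catalog("s", recs(c("chr1", "chrUn"), c(0, 5), c(50, 60)), 1e6)
  expect_message(v <- validate_catalog_genome(ct, g), "absent")
  expect_equal(sum(v$records$on_genome), 1L)
  expect_equal(nrow(v$records), 2L)
})
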