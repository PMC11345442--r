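#' Construct an eccDNA catalog
#'
#' One catalog holds the circular-DNA interval calls of a single sample,
#' sorted by (chrom, start, end), together with the mapped-read total used to
#' normalize abundance and an optional H/L group label.
#'
#' @param sample_id sample identifier.
#' @param records data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `split_reads`, `discordant_reads`, `score`.
#' @param mapped_read_total total mapped reads of the sample (`NA` allowed
#'   until normalized abundance is requested).
#' @param group_label optional `"H"` or `"L"`.
#' @return an object of class `eccdna_catalog`.
#' @export
eccdna_catalog <- function(sample_id, records, mapped_read_total = NA_real_,
                           group_label = NA_character_) {
  stopifnot(is.data.frame(records))
  for (col in c("chrom", "start", "end")) {
    assert_that(col %in% names(records), sprintf("records lack column %s", col))
  }
  if (is.null(records$split_reads)) records$split_reads <- rep(0L, nrow(records))
  if (is.null(records$discordant_reads)) {
    records$discordant_reads <- rep(0L, nrow(records))
  }
  if (is.null(records$score)) records$score <- rep(0, nrow(records))
  records$chrom <- as.character(records$chrom)
  if (nrow(records)) {
    assert_that(all(records$start >= 0) && all(records$start < records$end),
                "records must satisfy 0 <= start < end")
    assert_that(all(records$split_reads >= 0) && all(records$discordant_reads >= 0),
                "read supports must be non-negative")
  }
  records <- records[order(records$chrom, records$start, records$end),
                     c("chrom", "start", "end", "split_reads",
                       "discordant_reads", "score"), drop = FALSE]
  rownames(records) <- NULL
  if (!is.na(mapped_read_total)) {
    assert_that(mapped_read_total > 0, "mapped_read_total must be > 0")
  }
  structure(list(sample_id = as.character(sample_id), records = records,
                 mapped_read_total = as.numeric(mapped_read_total),
                 group_label = group_label),
            class = "eccdna_catalog")
}

#' @export
print.eccdna_catalog <- function(x, ...) {
  cat(sprintf("eccdna_catalog '%s': %d records%s%s\n", x$sample_id,
              nrow(x$records),
              if (!is.na(x$mapped_read_total))
                sprintf(", %.3g mapped reads", x$mapped_read_total) else "",
              if (!is.na(x$group_label))
                sprintf(", group %s", x$group_label) else ""))
  invisible(x)
}

#' Read an eccDNA catalog from a BED-dialect file
#'
#' Two tab-separated dialects are supported. `circlemap_bed` is the circular
#' BED output of Circle-Map-style callers with columns (chrom, start, end,
#' discordant_reads, split_reads, score); extra columns are ignored.
#' `plain_bed` needs only (chrom, start, end); read supports default to 0.
#' Zero- or negative-length intervals and non-numeric coordinates are parse
#' errors naming the offending line.
#'
#' @param path file path.
#' @param dialect `"circlemap_bed"` (default) or `"plain_bed"`.
#' @param mapped_read_total mapped-read total for abundance normalization.
#' @param sample_id defaults to the file name without extension.
#' @param min_split optional minimum split-read support filter (records with
#'   fewer split reads are dropped); 0 keeps every call.
#' @return an [eccdna_catalog].
#' @export
read_eccdna_catalog <- function(path,
                                dialect = c("circlemap_bed", "plain_bed"),
                                mapped_read_total = NA_real_,
                                sample_id = NULL, min_split = 0L) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (!length(lines)) {
    return(eccdna_catalog(sample_id, data.frame(chrom = character(),
                                                start = integer(),
                                                end = integer()),
                          mapped_read_total))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (dialect == "circlemap_bed") 6L else 3L
  short <- which(lengths(fields) < need)
  if (length(short)) {
    stop(sprintf("parse error: expected >= %d columns, line %d", need, short[1]),
         call. = FALSE)
  }
  getcol <- function(k) vapply(fields, `[`, "", k)
  start <- suppressWarnings(as.numeric(getcol(2L)))
  end <- suppressWarnings(as.numeric(getcol(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("parse error: malformed coordinate, line %d", bad[1]),
         call. = FALSE)
  }
  zl <- which(start >= end)
  if (length(zl)) {
    stop(sprintf("zero-length interval, line %s",
                 paste(zl, collapse = ", ")), call. = FALSE)
  }
  rec <- data.frame(chrom = getcol(1L), start = start, end = end)
  if (dialect == "circlemap_bed") {
    rec$discordant_reads <- suppressWarnings(as.numeric(getcol(4L)))
    rec$split_reads <- suppressWarnings(as.numeric(getcol(5L)))
    rec$score <- suppressWarnings(as.numeric(getcol(6L)))
    badn <- which(is.na(rec$discordant_reads) | is.na(rec$split_reads))
    if (length(badn)) {
      stop(sprintf("parse error: malformed read count, line %d", badn[1]),
           call. = FALSE)
    }
  }
  if (min_split > 0 && !is.null(rec$split_reads)) {
    rec <- rec[rec$split_reads >= min_split, , drop = FALSE]
  }
  eccdna_catalog(sample_id, rec, mapped_read_total)
}

#' Write an eccDNA catalog as a BED-dialect file
#' @param catalog an [eccdna_catalog].
#' @param path output path.
#' @param dialect column layout, as in [read_eccdna_catalog()].
#' @export
write_eccdna_catalog <- function(catalog, path,
                                 dialect = c("circlemap_bed", "plain_bed")) {
  dialect <- match.arg(dialect)
  r <- catalog$records
  out <- if (dialect == "circlemap_bed") {
    data.frame(r$chrom, r$start, r$end, r$discordant_reads, r$split_reads,
               r$score)
  } else {
    data.frame(r$chrom, r$start, r$end)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Check a catalog against a genome
#'
#' Records on chromosomes absent from the genome are kept for counting but
#' excluded from sequence-dependent analyses; records exceeding chromosome
#' bounds are an error.
#'
#' @param catalog an [eccdna_catalog].
#' @param genome a [genome_model].
#' @return the catalog with a logical `on_genome` column added to records; a
#'   message reports the tally of off-genome records.
#' @export
validate_catalog_genome <- function(catalog, genome) {
  r <- catalog$records
  on <- r$chrom %in% genome$chrom_names
  if (any(on)) {
    lens <- genome$chrom_lengths[r$chrom[on]]
    assert_that(all(r$end[on] <= lens),
                "record extends beyond chromosome length")
  }
  if (any(!on)) {
    message(sprintf("catalog '%s': %d record(s) on chromosomes absent from the genome (kept in counts, excluded from sequence analyses)",
                    catalog$sample_id, sum(!on)))
  }
  catalog$records$on_genome <- on
  catalog
}

# records of a catalog as a GRanges (1-based closed, for overlap machinery)
catalog_granges <- function(catalog, genome = NULL) {
  r <- if (is.data.frame(catalog)) catalog else catalog$records
  gr <- GenomicRanges::GRanges(r$chrom,
                               IRanges::IRanges(r$start + 1L, r$end))
  if (!is.null(genome)) {
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% genome$chrom_names]
  }
  gr
}
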