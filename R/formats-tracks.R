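#' Closed vocabulary of annotation feature classes
#' @export
FEATURE_CLASSES <- c("gene", "exon", "CDS", "UTR5", "UTR3", "intron",
                     "intergenic", "SINE", "Alu", "LINE", "LTR",
                     "simple_repeat", "low_complexity", "DNA_transposon",
                     "satellite", "other_repeat")

#' Repeat classes within the closed vocabulary
#' @export
REPEAT_CLASSES <- c("SINE", "Alu", "LINE", "LTR", "simple_repeat",
                    "low_complexity", "DNA_transposon", "satellite",
                    "other_repeat")

#' Map a RepeatMasker class/family string to the closed vocabulary
#'
#' `SINE/Alu` maps to `Alu`; other `SINE/*` to `SINE`; `LINE/*`, `LTR/*`,
#' `DNA/*`, `Simple_repeat`, `Low_complexity`, `Satellite/*` to their
#' respective classes. Unknown labels map to `other_repeat` with a warning.
#'
#' @param label character vector of RepeatMasker-style labels.
#' @return character vector of vocabulary classes.
#' @export
map_repeat_class <- function(label) {
  fam <- sub("/.*$", "", label)
  out <- rep("other_repeat", length(label))
  out[grepl("^SINE", label, ignore.case = TRUE)] <- "SINE"
  out[grepl("^SINE/Alu", label, ignore.case = TRUE) |
        label %in% c("Alu", "alu")] <- "Alu"
  out[grepl("^LINE", fam, ignore.case = TRUE)] <- "LINE"
  out[grepl("^LTR", fam, ignore.case = TRUE)] <- "LTR"
  out[grepl("^Simple_repeat$", fam, ignore.case = TRUE)] <- "simple_repeat"
  out[grepl("^Low_complexity$", fam, ignore.case = TRUE)] <- "low_complexity"
  out[grepl("^DNA", fam, ignore.case = TRUE)] <- "DNA_transposon"
  out[grepl("^Satellite", fam, ignore.case = TRUE)] <- "satellite"
  out[label %in% REPEAT_CLASSES] <- label[label %in% REPEAT_CLASSES]
  unknown <- out == "other_repeat" & !(label %in% "other_repeat")
  if (any(unknown)) {
    warning(sprintf("%d repeat label(s) outside the vocabulary mapped to other_repeat (e.g. '%s')",
                    sum(unknown), label[unknown][1]), call. = FALSE)
  }
  out
}

#' Construct an annotation track
#'
#' @param features data frame with `chrom`, `start`, `end` (0-based
#'   half-open), `feature_class` (one of [FEATURE_CLASSES]) and optional
#'   `gene_id` (required on `gene` features).
#' @return an object of class `annotation_track`.
#' @export
annotation_track <- function(features) {
  stopifnot(is.data.frame(features))
  for (col in c("chrom", "start", "end", "feature_class")) {
    assert_that(col %in% names(features), sprintf("features lack column %s", col))
  }
  if (is.null(features$gene_id)) {
    features$gene_id <- rep(NA_character_, nrow(features))
  }
  features$chrom <- as.character(features$chrom)
  if (nrow(features)) {
    assert_that(all(features$start >= 0 & features$start < features$end),
                "features must satisfy 0 <= start < end")
    assert_that(all(features$feature_class %in% FEATURE_CLASSES),
                "feature_class outside the closed vocabulary")
    g <- features$feature_class == "gene"
    assert_that(all(!is.na(features$gene_id[g])), "gene features need gene_id")
  }
  features <- features[order(features$chrom, features$start, features$end),
                       c("chrom", "start", "end", "feature_class", "gene_id"),
                       drop = FALSE]
  rownames(features) <- NULL
  structure(list(features = features), class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  tab <- table(x$features$feature_class)
  cat(sprintf("annotation_track: %d features (%s)\n", nrow(x$features),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read a BED-like annotation file
#'
#' @param path file path (tab-separated, no header).
#' @param kind `"gene_bed"` (column 4 = gene id; all features class `gene`)
#'   or `"repeat_bed"` (column 4 = RepeatMasker-style class string). An
#'   `"exon_bed"` kind reads exon features carrying the parent gene id.
#' @return an [annotation_track].
#' @export
read_annotation <- function(path, kind = c("gene_bed", "repeat_bed", "exon_bed")) {
  kind <- match.arg(kind)
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(annotation_track(data.frame(chrom = character(), start = integer(),
                                       end = integer(),
                                       feature_class = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop(sprintf("missing class/id column, line %d",
                 which(lengths(fields) < 4L)[1]), call. = FALSE)
  }
  getcol <- function(k) vapply(fields, `[`, "", k)
  df <- data.frame(chrom = getcol(1L),
                   start = as.numeric(getcol(2L)),
                   end = as.numeric(getcol(3L)))
  lab <- getcol(4L)
  if (kind == "gene_bed") {
    df$feature_class <- "gene"; df$gene_id <- lab
  } else if (kind == "exon_bed") {
    df$feature_class <- "exon"; df$gene_id <- lab
  } else {
    df$feature_class <- map_repeat_class(lab); df$gene_id <- NA_character_
  }
  annotation_track(df)
}

#' Write an annotation track as BED4
#' @param track an [annotation_track].
#' @param path output path.
#' @export
write_annotation <- function(track, path) {
  f <- track$features
  lab <- ifelse(f$feature_class %in% c("gene", "exon") & !is.na(f$gene_id),
                f$gene_id, f$feature_class)
  write.table(data.frame(f$chrom, f$start, f$end, lab), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

track_granges <- function(track, classes = NULL) {
  f <- if (is.data.frame(track)) track else track$features
  if (!is.null(classes)) f <- f[f$feature_class %in% classes, , drop = FALSE]
  gr <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start + 1L, f$end))
  S4Vectors::mcols(gr)$feature_class <- f$feature_class
  S4Vectors::mcols(gr)$gene_id <- f$gene_id
  gr
}

#' Construct a copy-number segment set
#'
#' Segments must tile every chromosome they mention: non-overlapping and
#' gap-free. Copy numbers are non-negative integers.
#'
#' @param sample_id sample identifier.
#' @param segments data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `cn`.
#' @param chrom_lengths optional named lengths; when given, coverage of each
#'   chromosome is enforced.
#' @return an object of class `cn_segment_set`.
#' @export
cn_segment_set <- function(sample_id, segments, chrom_lengths = NULL) {
  stopifnot(is.data.frame(segments))
  for (col in c("chrom", "start", "end", "cn")) {
    assert_that(col %in% names(segments), sprintf("segments lack column %s", col))
  }
  segments$chrom <- as.character(segments$chrom)
  assert_that(all(segments$start >= 0 & segments$start < segments$end),
              "segments must satisfy 0 <= start < end")
  assert_that(all(segments$cn >= 0 & segments$cn == round(segments$cn)),
              "cn must be non-negative integers")
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    if (any(s$start[-1] != s$end[-nrow(s)])) {
      stop(sprintf("coverage gap or overlap on chromosome %s", ch),
           call. = FALSE)
    }
    if (s$start[1] != 0) stop(sprintf("coverage gap on chromosome %s", ch),
                              call. = FALSE)
    if (!is.null(chrom_lengths)) {
      assert_that(s$end[nrow(s)] == chrom_lengths[[ch]],
                  sprintf("coverage gap on chromosome %s", ch))
    }
  }
  structure(list(sample_id = as.character(sample_id), segments = segments),
            class = "cn_segment_set")
}

#' Read copy-number segments for all samples from a TSV
#'
#' Expected columns: `sample`, `chrom`, `start`, `end`, `cn` (header line
#' required, `#` preamble lines ignored).
#'
#' @param path file path.
#' @param chrom_lengths optional named lengths for coverage validation.
#' @return named list of [cn_segment_set], one per sample.
#' @export
read_cn_segments <- function(path, chrom_lengths = NULL) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "cn")
  assert_that(all(need %in% names(df)),
              paste("CN table needs columns:", paste(need, collapse = ", ")))
  lapply(split(df, df$sample), function(s) {
    cn_segment_set(s$sample[1], s[, c("chrom", "start", "end", "cn")],
                   chrom_lengths)
  })
}

#' Write copy-number segments for a list of samples
#' @param sets list of [cn_segment_set].
#' @param path output path.
#' @export
write_cn_segments <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s) {
    cbind(sample = s$sample_id, s$segments)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' First column = gene id, remaining columns = samples. Duplicate gene ids
#' are an error; values must be non-negative.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  assert_that(ncol(df) >= 2, "expression table needs gene id + sample columns")
  ids <- as.character(df[[1]])
  assert_that(!anyDuplicated(ids), "duplicate gene ids")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  assert_that(all(m >= 0), "expression values must be >= 0")
  m
}

#' Write an expression matrix as TSV
#' @param mat genes-by-samples matrix with dimnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table
#'
#' Expected columns: `id`, `time` (days, > 0), `event` (1 = death observed,
#' 0 = censored) and optionally one or more score columns.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_survival_table <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "time", "event")
  assert_that(all(need %in% names(df)),
              paste("survival table needs columns:", paste(need, collapse = ", ")))
  assert_that(all(df$time > 0), "survival times must be positive")
  assert_that(all(df$event %in% c(0, 1)), "event must be 0/1")
  df
}

#' Write a survival table
#' @param cohort data frame with id/time/event (+ scores).
#' @param path output path.
#' @export
write_survival_table <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
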