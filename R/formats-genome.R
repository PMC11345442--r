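#' Genome model
#'
#' A genome is a set of named chromosome sequences held as an uppercase
#' [Biostrings::DNAStringSet] together with a per-chromosome cumulative
#' G+C / N index that makes the GC fraction of any interval an O(1) lookup.
#' All coordinates in this package are 0-based half-open (BED convention).
#'
#' @param sequences a named character vector or `DNAStringSet` of chromosome
#'   sequences over `A/C/G/T/N` (lowercase permitted, stored uppercase).
#' @return an object of class `genome_model` with elements `seq`
#'   (`DNAStringSet`), `chrom_names` and `chrom_lengths`.
#' @export
genome_model <- function(sequences) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  assert_that(methods::is(sequences, "DNAStringSet"),
              "sequences must be a character vector or DNAStringSet")
  nm <- names(sequences)
  assert_that(!is.null(nm) && all(nzchar(nm)), "every chromosome needs a name")
  assert_that(!anyDuplicated(nm), "duplicate chromosome names")
  assert_that(all(Biostrings::width(sequences) > 0L), "empty chromosome sequence")
  sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  names(sequences) <- nm
  g <- list(seq = sequences,
            chrom_names = nm,
            chrom_lengths = setNames(Biostrings::width(sequences), nm),
            .cache = new.env(parent = emptyenv()))
  class(g) <- "genome_model"
  g
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %s bp total\n",
              length(x$chrom_names),
              format(sum(as.numeric(x$chrom_lengths)), big.mark = ",")))
  invisible(x)
}

#' Read a genome FASTA file
#'
#' @param path path to a FASTA file; lowercase bases are permitted and are
#'   uppercased on read. Duplicate headers or empty records are errors.
#' @return a [genome_model].
#' @export
read_genome_fasta <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  seqs <- Biostrings::readDNAStringSet(path)
  assert_that(length(seqs) > 0L, "FASTA contains no records")
  # headers may carry descriptions after whitespace; the id is the first token
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate FASTA header: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("empty FASTA record: ",
         paste(names(seqs)[Biostrings::width(seqs) == 0L], collapse = ", "),
         call. = FALSE)
  }
  genome_model(seqs)
}

#' Write a genome FASTA file
#' @param genome a [genome_model].
#' @param path output path.
#' @param width line wrap width in bp.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(genome$seq, path, width = width)
  invisible(path)
}

# cumulative (G|C) and N counts per chromosome; cached on first use
gc_index <- function(genome, chrom) {
  key <- paste0("gc_", chrom)
  if (!is.null(genome$.cache[[key]])) return(genome$.cache[[key]])
  assert_that(chrom %in% genome$chrom_names, sprintf("unknown chromosome %s", chrom))
  r <- charToRaw(as.character(genome$seq[[chrom]]))
  idx <- list(gc = cumsum(r == as.raw(71L) | r == as.raw(67L)),
              n  = cumsum(r == as.raw(78L)))
  genome$.cache[[key]] <- idx
  idx
}

#' Extract genome sequence for 0-based half-open intervals
#'
#' @param genome a [genome_model].
#' @param chrom,start,end parallel vectors of 0-based half-open coordinates.
#' @return a character vector of sequences.
#' @export
genome_sequence <- function(genome, chrom, start, end) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n)
  len <- genome$chrom_lengths[chrom]
  assert_that(all(start >= 0 & start < end & end <= len),
              "interval outside chromosome bounds")
  out <- character(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    out[i] <- as.character(Biostrings::extractAt(
      genome$seq[[ch]], IRanges::IRanges(start[i] + 1L, end[i])))
  }
  out
}

#' GC fraction of genome intervals (N bases excluded from the denominator)
#'
#' @inheritParams genome_sequence
#' @return numeric vector of GC fractions; `NA` where the interval is all N.
#' @export
genome_gc <- function(genome, chrom, start, end) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n)
  out <- numeric(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    idx <- gc_index(genome, ch)
    L <- genome$chrom_lengths[[ch]]
    s <- start[i]; e <- end[i]
    assert_that(all(s >= 0 & s < e & e <= L), "interval outside chromosome bounds")
    gc0 <- c(0L, idx$gc); n0 <- c(0L, idx$n)
    gc <- gc0[e + 1L] - gc0[s + 1L]
    nn <- n0[e + 1L] - n0[s + 1L]
    denom <- (e - s) - nn
    out[i] <- ifelse(denom > 0, gc / denom, NA_real_)
  }
  out
}

#' Genome-wide GC fraction
#' @param genome a [genome_model].
#' @return single GC fraction over all chromosomes, N excluded.
#' @export
genome_gc_total <- function(genome) {
  gc <- 0; atcg <- 0
  for (ch in genome$chrom_names) {
    idx <- gc_index(genome, ch)
    L <- genome$chrom_lengths[[ch]]
    gc <- gc + idx$gc[L]
    atcg <- atcg + L - idx$n[L]
  }
  gc / atcg
}

#' GC fraction of a plain sequence string
#'
#' Computes (G+C)/(A+C+G+T); N bases are excluded from the denominator and an
#' all-N sequence yields `NA`.
#'
#' @param sequence character vector of sequences over `A/C/G/T/N` (any case).
#' @return numeric vector of fractions in `[0, 1]` (or `NA`).
#' @export
gc_content <- function(sequence) {
  assert_that(is.character(sequence) && all(nzchar(sequence)),
              "sequence must be non-empty character")
  ss <- Biostrings::DNAStringSet(toupper(sequence))
  fr <- Biostrings::letterFrequency(ss, letters = c("A", "C", "G", "T", "N"))
  denom <- rowSums(fr[, c("A", "C", "G", "T"), drop = FALSE])
  out <- (fr[, "C"] + fr[, "G"]) / denom
  out[denom == 0] <- NA_real_
  unname(out)
}
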