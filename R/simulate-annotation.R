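# repeat class mix: bp share of the planted repeat complement and the
# length range (bp) elements of each class are drawn from
.repeat_mix <- data.frame(
  class = c("Alu", "SINE", "LINE", "LTR", "simple_repeat",
            "low_complexity", "DNA_transposon"),
  weight = c(0.24, 0.095, 0.22, 0.15, 0.12, 0.0875, 0.0875),
  min_len = c(250, 150, 500, 300, 50, 50, 200),
  max_len = c(350, 350, 3000, 1000, 500, 300, 1000),
  stringsAsFactors = FALSE
)

#' Generate a synthetic annotation: genes with exons, plus a repeat track
#'
#' Gene density follows a linear per-Mb gradient along every chromosome
#' (`gene_density_gradient`), planting the covariate behind the
#' gene-density / eccDNA-frequency correlation. Repeat elements of seven
#' RepeatMasker-style classes are placed uniformly until their union covers
#' `repeat_fraction` of the genome (within one element length).
#'
#' @param genome a [genome_model].
#' @param config a [sim_config].
#' @return list with `genes` and `repeats`, both [annotation_track]s; the
#'   genes track carries `gene` and `exon` features.
#' @export
generate_annotation <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "annotation"), {
    genes <- .gen_genes(genome, config)
    reps <- .gen_repeats(genome, config)
  })
  list(genes = annotation_track(genes), repeats = annotation_track(reps))
}

.gen_genes <- function(genome, config) {
  g1 <- config$gene_density_gradient[1]
  g2 <- config$gene_density_gradient[2]
  out <- vector("list", length(genome$chrom_names))
  for (ci in seq_along(genome$chrom_names)) {
    ch <- genome$chrom_names[ci]
    L <- genome$chrom_lengths[[ch]]
    w <- config$density_window
    n_win <- floor(L / w)
    assert_that(n_win >= 1, "chromosome shorter than the density window")
    frac <- if (n_win == 1) 0.5 else (seq_len(n_win) - 1) / (n_win - 1)
    dens <- g1 + (g2 - g1) * frac            # genes per Mb per window
    lambda <- dens * w / 1e6
    counts <- rpois(n_win, lambda)
    rows <- list(); k <- 0L
    for (j in seq_len(n_win)) {
      if (counts[j] == 0) next
      for (r in seq_len(counts[j])) {
        glen <- round(runif(1, 1000, 5000))
        glen <- min(glen, w - 2L)
        if (glen < 200) next
        gstart <- (j - 1) * w + floor(runif(1, 0, w - glen))
        k <- k + 1L
        gid <- sprintf("%s_g%04d", ch, k)
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = ch, start = gstart, end = gstart + glen,
                     feature_class = "gene", gene_id = gid)
        # exons: split the gene into chunks, ~40% exonic bp
        n_ex <- max(1L, round(glen / 1200))
        chunk <- glen / n_ex
        for (e in seq_len(n_ex)) {
          elen <- max(30L, round(0.4 * chunk))
          off <- floor(runif(1, 0, max(1, chunk - elen)))
          es <- gstart + round((e - 1) * chunk) + off
          ee <- min(es + elen, gstart + glen)
          if (ee > es) {
            rows[[length(rows) + 1L]] <-
              data.frame(chrom = ch, start = es, end = ee,
                         feature_class = "exon", gene_id = gid)
          }
        }
      }
    }
    out[[ci]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(), start = integer(), end = integer(),
                      feature_class = character(), gene_id = character())
  }
  res
}

.gen_repeats <- function(genome, config) {
  if (config$repeat_fraction == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), feature_class = character(),
                      gene_id = character()))
  }
  # weights are bp shares of the repeat complement; classes are filled from
  # longest to shortest element type so non-overlap rejection does not crowd
  # the long classes out of an increasingly occupied genome
  mix <- .repeat_mix[order(-(.repeat_mix$min_len + .repeat_mix$max_len)), ]
  rows <- vector("list", 0L)
  for (ch in genome$chrom_names) {
    L <- genome$chrom_lengths[[ch]]
    covered <- raw(L)       # per-bp occupancy bitmap (raw, 1 byte each)
    cls <- character(0); st <- integer(0); en <- integer(0)
    for (ci in seq_len(nrow(mix))) {
      target <- config$repeat_fraction * L * mix$weight[ci]
      tot <- 0; iter <- 0L
      while (tot < target) {
        iter <- iter + 1L
        if (iter > 5e5) stop("infeasible repeat density", call. = FALSE)
        len <- round(runif(1, mix$min_len[ci], mix$max_len[ci]))
        if (len >= L) len <- L - 1L
        s <- floor(runif(1, 0, L - len))
        span <- (s + 1L):(s + len)
        # repeats are kept mutually non-overlapping (RepeatMasker-like)
        if (any(covered[span] != as.raw(0L))) next
        covered[span] <- as.raw(1L)
        tot <- tot + len
        cls <- c(cls, mix$class[ci]); st <- c(st, s); en <- c(en, s + len)
      }
    }
    rows[[ch]] <- data.frame(chrom = ch, start = st, end = en,
                             feature_class = cls, gene_id = NA_character_)
  }
  do.call(rbind, rows)
}
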