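# Placement intensity is defined on 1-kb windows:
#   weight(w) = exp(gc_bias * GC(w)) * (1 + a * geneDensity(w) + b * AluDensity(w))
# with densities measured per `density_window` and scaled to [0,1] genome-wide.
# Records are drawn by inverse-CDF over window weights, then uniformly within
# the window, which makes every record's planted intensity recomputable from
# the emitted truth table.

PLACEMENT_WINDOW <- 1000L

# per-1-kb-window placement weights + covariate densities for a genome
placement_weights <- function(genome, annotation, config) {
  genes <- annotation$genes$features
  genes <- genes[genes$feature_class == "gene", , drop = FALSE]
  alus <- annotation$repeats$features
  alus <- alus[alus$feature_class == "Alu", , drop = FALSE]
  a <- unname(config$density_coupling["a"])
  b <- unname(config$density_coupling["b"])
  cw <- config$density_window
  tabs <- lapply(genome$chrom_names, function(ch) {
    L <- genome$chrom_lengths[[ch]]
    n_win <- floor(L / PLACEMENT_WINDOW)
    ws <- (seq_len(n_win) - 1L) * PLACEMENT_WINDOW
    we <- ws + PLACEMENT_WINDOW
    gc <- genome_gc(genome, rep(ch, n_win), ws, we)
    gc[is.na(gc)] <- 0
    coarse_of <- ws %/% cw
    dens <- function(f) {
      if (!nrow(f)) return(numeric(n_win))
      mid <- (f$start[f$chrom == ch] + f$end[f$chrom == ch]) %/% 2
      cnt <- tabulate(mid %/% cw + 1L, nbins = max(coarse_of) + 1L)
      (cnt / (cw / 1e6))[coarse_of + 1L]
    }
    data.frame(chrom = ch, start = ws, end = we, gc = gc,
               gene_density = dens(genes), alu_density = dens(alus))
  })
  tab <- do.call(rbind, tabs)
  gmax <- max(tab$gene_density); amax <- max(tab$alu_density)
  gn <- if (gmax > 0) tab$gene_density / gmax else tab$gene_density * 0
  an <- if (amax > 0) tab$alu_density / amax else tab$alu_density * 0
  tab$weight <- exp(config$gc_bias * tab$gc) * pmax(0, 1 + a * gn + b * an)
  tab
}

# per-chromosome sorted disjoint intervals and multiplier per weighted class;
# returns a function giving the placement multiplier of a midpoint position
element_multiplier_fun <- function(annotation, config) {
  ew <- config$element_weights
  if (is.null(ew) || !length(ew)) return(NULL)
  feats <- annotation$repeats$features
  tabs <- list()
  for (cls in names(ew)) {
    f <- feats[feats$feature_class == cls, , drop = FALSE]
    if (!nrow(f)) next
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      f$chrom, IRanges::IRanges(f$start + 1L, f$end)))
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr))
    tabs[[cls]] <- split(df, df$chrom)
  }
  if (!length(tabs)) return(NULL)
  function(chrom, pos) {
    m <- rep(1, length(pos))
    for (cls in names(tabs)) {
      for (ch in unique(chrom)) {
        iv <- tabs[[cls]][[ch]]
        if (is.null(iv)) next
        i <- which(chrom == ch)
        j <- findInterval(pos[i], iv$start)
        inside <- j >= 1 & pos[i] < iv$end[pmax(j, 1)]
        m[i][inside] <- m[i][inside] * ew[[cls]]
      }
    }
    m
  }
}

#' Generate per-sample eccDNA catalogs with planted placement structure
#'
#' Catalog sizes are Poisson around the group mean (`abundance_split`),
#' locus placement follows the configured GC and gene/Alu density coupling
#' (with optional per-element-class multipliers applied to the record
#' midpoint by rejection sampling), and lengths are log-normal with the
#' configured mode (default 80 bp, truncated to `[30 bp, 1 Mb]`).
#'
#' @param genome a [genome_model].
#' @param annotation list with `genes` and `repeats` tracks, as produced by
#'   [generate_annotation()].
#' @param config a [sim_config].
#' @return list with `catalogs` (list of [eccdna_catalog]) and `truth`
#'   (list with per-sample table and the per-window placement-weight table).
#' @export
generate_eccdna_catalogs <- function(genome, annotation, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  assert_that(all(config$abundance_split > 0), "abundance means must be > 0")
  labels <- sim_group_labels(config)
  wtab <- placement_weights(genome, annotation, config)
  prob <- wtab$weight / sum(wtab$weight)
  emult <- element_multiplier_fun(annotation, config)
  emax <- if (is.null(emult)) 1 else prod(pmax(config$element_weights, 1))
  mu <- log(config$size_mode) + config$size_sigma^2   # log-normal mode
  catalogs <- vector("list", config$n_samples)
  strows <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    sid <- sprintf("S%02d", i)
    with_seed(derive_seed(config$seed, paste0("catalog_", i)), {
      n <- rpois(1L, config$abundance_split[[labels[i]]])
      draw_loci <- function(k) {
        widx <- sample.int(nrow(wtab), k, replace = TRUE, prob = prob)
        len <- round(rlnorm(k, mu, config$size_sigma))
        len <- pmin(pmax(len, 30L), 1e6)
        ch <- wtab$chrom[widx]
        L <- genome$chrom_lengths[ch]
        len <- pmin(len, L)
        start <- wtab$start[widx] + floor(runif(k, 0, PLACEMENT_WINDOW))
        start <- pmin(start, L - len)
        data.frame(chrom = ch, start = start, len = len)
      }
      d <- draw_loci(n)
      if (!is.null(emult) && n > 0) {
        # rejection step: accept with prob multiplier(midpoint) / max
        kept <- list()
        pending <- d
        while (nrow(pending)) {
          m <- emult(pending$chrom, pending$start + pending$len %/% 2)
          acc <- runif(nrow(pending)) < m / emax
          kept[[length(kept) + 1L]] <- pending[acc, , drop = FALSE]
          k <- sum(!acc)
          pending <- if (k) draw_loci(k) else pending[0, ]
        }
        d <- do.call(rbind, kept)
      }
      ch <- d$chrom; start <- d$start; len <- d$len
      rec <- data.frame(chrom = ch, start = start, end = start + len,
                        split_reads = rpois(n, 1.5) + 1L,
                        discordant_reads = rpois(n, 2),
                        score = round(runif(n, 1, 100), 1))
      mrt <- round(runif(1, config$mapped_reads_range[1],
                         config$mapped_reads_range[2]))
    })
    catalogs[[i]] <- eccdna_catalog(sid, rec, mapped_read_total = mrt,
                                    group_label = labels[i])
    strows[[i]] <- data.frame(sample_id = sid, group = labels[i],
                              mean_records = config$abundance_split[[labels[i]]],
                              n_records = nrow(rec), mapped_read_total = mrt)
  }
  names(catalogs) <- vapply(catalogs, `[[`, "", "sample_id")
  list(catalogs = catalogs,
       truth = list(samples = do.call(rbind, strows), windows = wtab))
}
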