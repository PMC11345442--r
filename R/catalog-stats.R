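#' Per-sample eccDNA abundance summary
#'
#' Normalized abundance is reported as EPM (eccDNAs per million mapped
#' reads): `n_records / mapped_read_total * 1e6`. Per-chromosome shares are
#' the per-Mb record densities normalized to percentages.
#'
#' @param catalog an [eccdna_catalog] with `mapped_read_total` set.
#' @param chrom_lengths named chromosome lengths in bp.
#' @return list with `sample_id`, `n_records`, `epm` and `chrom_share`
#'   (named percentages summing to 100, or all zero for an empty catalog).
#' @export
compute_abundance <- function(catalog, chrom_lengths) {
  assert_that(!is.na(catalog$mapped_read_total) && catalog$mapped_read_total > 0,
              "mapped_read_total must be > 0")
  n <- nrow(catalog$records)
  epm <- n / catalog$mapped_read_total * 1e6
  cnt <- table(factor(catalog$records$chrom, levels = names(chrom_lengths)))
  dens <- as.numeric(cnt) / (chrom_lengths / 1e6)
  share <- if (sum(dens) > 0) dens / sum(dens) * 100 else dens * 0
  list(sample_id = catalog$sample_id, n_records = n, epm = epm,
       chrom_share = setNames(share, names(chrom_lengths)))
}

#' Size distribution of eccDNA lengths
#'
#' Bins are `[0, w), [w, 2w), ...`; the modal bin is the fullest, with ties
#' broken toward the smallest bin start.
#'
#' @param catalog an [eccdna_catalog] (or data frame of records).
#' @param bin_width bin width in bp.
#' @return list with `histogram` (data frame bin_start/bin_end/count) and
#'   `modal_bin` (c(start, end) of the modal bin).
#' @export
size_distribution <- function(catalog, bin_width = 100) {
  r <- if (is.data.frame(catalog)) catalog else catalog$records
  len <- r$end - r$start
  assert_that(length(len) > 0, "empty catalog")
  idx <- len %/% bin_width           # 0-based bin index
  counts <- table(idx)
  bs <- as.numeric(names(counts)) * bin_width
  hist <- data.frame(bin_start = bs, bin_end = bs + bin_width,
                     count = as.numeric(counts))
  hist <- hist[order(hist$bin_start), , drop = FALSE]
  rownames(hist) <- NULL
  mode_row <- which(hist$count == max(hist$count))[1]
  list(histogram = hist,
       modal_bin = c(start = hist$bin_start[mode_row],
                     end = hist$bin_end[mode_row]))
}

# pooled unique species across catalogs: unique (chrom, start, end)
pool_species <- function(catalogs) {
  if (inherits(catalogs, "eccdna_catalog")) catalogs <- list(catalogs)
  recs <- do.call(rbind, lapply(catalogs, function(ct)
    ct$records[, c("chrom", "start", "end")]))
  sp <- unique(recs)
  sp <- sp[order(sp$chrom, sp$start, sp$end), , drop = FALSE]
  rownames(sp) <- NULL
  sp
}

#' Gene derivation of eccDNA species
#'
#' A species is a unique (chrom, start, end) interval after pooling the
#' given catalogs. A species counts toward a gene when it overlaps the gene
#' by at least 1 bp; its spanned-gene count is the number of distinct
#' overlapped gene ids.
#'
#' @param catalogs an [eccdna_catalog] or list of catalogs (pooled).
#' @param genes an [annotation_track]; only `gene` features are used.
#' @return list with `per_gene` (gene_id, n_species), `per_species`
#'   (chrom/start/end, n_genes) and `n_species`.
#' @export
gene_derivation <- function(catalogs, genes) {
  sp <- pool_species(catalogs)
  gf <- genes$features[genes$features$feature_class == "gene", , drop = FALSE]
  sp_gr <- GenomicRanges::GRanges(sp$chrom, IRanges::IRanges(sp$start + 1L, sp$end))
  g_gr <- GenomicRanges::GRanges(gf$chrom, IRanges::IRanges(gf$start + 1L, gf$end))
  hits <- GenomicRanges::findOverlaps(sp_gr, g_gr, minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits)
  gh <- gf$gene_id[S4Vectors::subjectHits(hits)]
  pairs <- unique(data.frame(species = qh, gene = gh))
  per_gene <- as.data.frame(table(pairs$gene), stringsAsFactors = FALSE)
  names(per_gene) <- c("gene_id", "n_species")
  per_sp <- sp
  per_sp$n_genes <- 0L
  if (nrow(pairs)) {
    tab <- table(pairs$species)
    per_sp$n_genes[as.integer(names(tab))] <- as.integer(tab)
  }
  list(per_gene = per_gene[order(-per_gene$n_species, per_gene$gene_id), ],
       per_species = per_sp, n_species = nrow(sp))
}

# tile the genome into fixed windows (0-based half-open, last partial window
# dropped so windows have equal length)
genome_windows <- function(chrom_lengths, window) {
  out <- lapply(names(chrom_lengths), function(ch) {
    n <- floor(chrom_lengths[[ch]] / window)
    if (n < 1) return(NULL)
    data.frame(chrom = ch, start = (seq_len(n) - 1) * window,
               end = seq_len(n) * window)
  })
  do.call(rbind, out)
}

# count interval midpoints per window (records partition across windows)
midpoint_window_counts <- function(df, windows, window) {
  if (!nrow(df)) return(numeric(nrow(windows)))
  mid <- (df$start + df$end) %/% 2
  key <- paste(df$chrom, mid %/% window)
  wkey <- paste(windows$chrom, windows$start %/% window)
  cnt <- table(key)
  out <- numeric(nrow(windows))
  m <- match(names(cnt), wkey)
  ok <- !is.na(m)
  out[m[ok]] <- as.numeric(cnt)[ok]
  out
}

#' Correlation of per-window eccDNA frequency with a covariate density
#'
#' The genome is tiled into fixed windows; eccDNA records and covariate
#' features are each counted by the window holding their midpoint and
#' expressed per Mb; the two per-window densities are correlated.
#'
#' @param catalogs an [eccdna_catalog] or list (records pooled, not
#'   deduplicated).
#' @param chrom_lengths named chromosome lengths.
#' @param covariate_track an [annotation_track] (e.g. genes, or the Alu
#'   subset of a repeat track).
#' @param window window size in bp (>= 10 kb).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param covariate_classes optional feature classes to keep from the track.
#' @return list with `windows` (per-window densities), `r`, `p_value`,
#'   `method` and `n_windows`.
#' @export
density_correlation <- function(catalogs, chrom_lengths, covariate_track,
                                window = 1e4,
                                method = c("pearson", "spearman"),
                                covariate_classes = NULL) {
  method <- match.arg(method)
  assert_that(window >= 1e4, "window must be >= 10 kb")
  if (inherits(catalogs, "eccdna_catalog")) catalogs <- list(catalogs)
  recs <- do.call(rbind, lapply(catalogs, function(ct)
    ct$records[, c("chrom", "start", "end")]))
  feats <- covariate_track$features
  if (!is.null(covariate_classes)) {
    feats <- feats[feats$feature_class %in% covariate_classes, , drop = FALSE]
  }
  win <- genome_windows(chrom_lengths, window)
  assert_that(!is.null(win) && nrow(win) >= 3, "too few windows")
  mb <- window / 1e6
  win$ecc_per_mb <- midpoint_window_counts(recs, win, window) / mb
  win$cov_per_mb <- midpoint_window_counts(feats, win, window) / mb
  if (sd(win$ecc_per_mb) == 0 || sd(win$cov_per_mb) == 0) {
    warning("degenerate densities: correlation undefined", call. = FALSE)
    return(list(windows = win, r = NA_real_, p_value = NA_real_,
                method = method, n_windows = nrow(win)))
  }
  ct <- cor.test(win$ecc_per_mb, win$cov_per_mb, method = method, exact = FALSE)
  list(windows = win, r = unname(ct$estimate), p_value = ct$p.value,
       method = method, n_windows = nrow(win))
}

#' Correlate drug IC50 values with normalized eccDNA abundance
#'
#' One row per drug with at least `min_pairs` non-missing paired samples;
#' drugs are flagged significant-negative when r < 0 and the raw p < alpha
#' (mirroring volcano-style screens); Benjamini-Hochberg adjusted p-values
#' are reported alongside.
#'
#' @param abundance named numeric vector of per-sample EPM values (or list
#'   of [compute_abundance()] results).
#' @param ic50 drugs-by-samples numeric matrix of IC50 values (NA = missing).
#' @param min_pairs minimum paired observations per drug (default 5).
#' @param alpha flagging threshold on the raw p-value.
#' @param method correlation method.
#' @return data frame: drug, n, r, p_value, p_adj, direction, flagged.
#' @export
drug_sensitivity_correlation <- function(abundance, ic50, min_pairs = 5L,
                                         alpha = 0.05,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.list(abundance) && !is.numeric(abundance)) {
    abundance <- setNames(vapply(abundance, `[[`, 0, "epm"),
                          vapply(abundance, `[[`, "", "sample_id"))
  }
  stopifnot(is.matrix(ic50))
  common <- intersect(names(abundance), colnames(ic50))
  assert_that(length(common) >= min_pairs, "too few shared samples")
  ab <- abundance[common]
  rows <- lapply(rownames(ic50), function(d) {
    y <- ic50[d, common]
    ok <- !is.na(y) & !is.na(ab)
    if (sum(ok) < min_pairs) {
      warning(sprintf("drug %s skipped: %d paired observation(s)", d, sum(ok)),
              call. = FALSE)
      return(NULL)
    }
    if (sd(y[ok]) == 0 || sd(ab[ok]) == 0) {
      warning(sprintf("drug %s skipped: constant values", d), call. = FALSE)
      return(NULL)
    }
    ct <- cor.test(ab[ok], y[ok], method = method, exact = FALSE)
    data.frame(drug = d, n = sum(ok), r = unname(ct$estimate),
               p_value = ct$p.value)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res$p_adj <- p.adjust(res$p_value, "BH")
  res$direction <- ifelse(res$r < 0, "negative", "positive")
  res$flagged <- res$r < 0 & res$p_value < alpha
  rownames(res) <- NULL
  res[order(res$p_value), ]
}
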