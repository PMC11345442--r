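# Region-class partition and genome-composition-normalized element mapping.

REGION_PRECEDENCE <- c("exon", "CDS", "UTR5", "UTR3", "intron", "intergenic")

reduce_class <- function(features, class, chrom_lengths) {
  f <- features[features$feature_class %in% class, , drop = FALSE]
  if (!nrow(f)) return(GenomicRanges::GRanges())
  assert_that(all(f$chrom %in% names(chrom_lengths)) &&
                all(f$end <= chrom_lengths[f$chrom]),
              "features off the genome")
  GenomicRanges::reduce(GenomicRanges::GRanges(
    f$chrom, IRanges::IRanges(f$start + 1L, f$end)))
}

granges_to_df <- function(gr, class) {
  if (!length(gr)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), region_class = character()))
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             region_class = class)
}

#' Build an exclusive genomic-region partition
#'
#' Every bp of the genome is assigned exactly one region class. Overlaps are
#' resolved by precedence (exon > UTR > intron), introns are gene bp not
#' covered by any exonic class, and the remainder is intergenic.
#'
#' @param genes an [annotation_track] carrying `gene` features and any of
#'   `exon`, `CDS`, `UTR5`, `UTR3`.
#' @param chrom_lengths named chromosome lengths in bp.
#' @return data frame chrom/start/end/region_class (0-based half-open) whose
#'   intervals tile the genome.
#' @export
build_region_partition <- function(genes, chrom_lengths) {
  feats <- genes$features
  genome_gr <- GenomicRanges::GRanges(
    names(chrom_lengths), IRanges::IRanges(1L, unname(chrom_lengths)))
  assigned <- GenomicRanges::GRanges()
  pieces <- list()
  for (cls in c("exon", "CDS", "UTR5", "UTR3")) {
    gr <- reduce_class(feats, cls, chrom_lengths)
    gr <- GenomicRanges::setdiff(gr, assigned)
    assigned <- GenomicRanges::reduce(c(assigned, gr))
    pieces[[cls]] <- granges_to_df(gr, cls)
  }
  gene_gr <- reduce_class(feats, "gene", chrom_lengths)
  intron <- GenomicRanges::setdiff(gene_gr, assigned)
  assigned <- GenomicRanges::reduce(c(assigned, intron))
  pieces[["intron"]] <- granges_to_df(intron, "intron")
  intergenic <- GenomicRanges::setdiff(genome_gr, assigned)
  pieces[["intergenic"]] <- granges_to_df(intergenic, "intergenic")
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify records into exclusive region classes
#'
#' Each record is assigned to the class holding the majority of its bp;
#' ties go to the higher-precedence class (exon > UTR > intron >
#' intergenic). Per-class bp is also accumulated fractionally.
#'
#' @param catalog an [eccdna_catalog] (or records data frame).
#' @param partition output of [build_region_partition()].
#' @return list with `per_record` (assigned class per record), `counts`
#'   (records per class), `frequencies` (shares summing to 1) and `bp`
#'   (fractional bp per class).
#' @export
classify_records <- function(catalog, partition) {
  r <- if (is.data.frame(catalog)) catalog else catalog$records
  assert_that(nrow(r) > 0, "empty catalog")
  classes <- REGION_PRECEDENCE[REGION_PRECEDENCE %in%
                                 unique(partition$region_class)]
  rec_gr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start + 1L, r$end))
  part_gr <- GenomicRanges::GRanges(partition$chrom,
                                    IRanges::IRanges(partition$start + 1L,
                                                     partition$end))
  hits <- GenomicRanges::findOverlaps(rec_gr, part_gr)
  ov <- GenomicRanges::pintersect(rec_gr[S4Vectors::queryHits(hits)],
                                  part_gr[S4Vectors::subjectHits(hits)])
  w <- GenomicRanges::width(ov)
  cls <- partition$region_class[S4Vectors::subjectHits(hits)]
  qi <- S4Vectors::queryHits(hits)
  # bp per (record, class)
  agg <- rowsum(w, group = paste(qi, cls, sep = "\r"))
  keys <- strsplit(rownames(agg), "\r", fixed = TRUE)
  agg_rec <- as.integer(vapply(keys, `[`, "", 1L))
  agg_cls <- vapply(keys, `[`, "", 2L)
  bp_by_class <- tapply(agg[, 1], factor(agg_cls, levels = classes), sum)
  bp_by_class[is.na(bp_by_class)] <- 0
  prec_rank <- match(agg_cls, REGION_PRECEDENCE)
  ord <- order(agg_rec, -agg[, 1], prec_rank)   # majority bp, ties by precedence
  first <- !duplicated(agg_rec[ord])
  assigned <- setNames(agg_cls[ord][first], agg_rec[ord][first])
  per_record <- assigned[as.character(seq_len(nrow(r)))]
  counts <- table(factor(per_record, levels = classes))
  list(per_record = unname(per_record),
       counts = setNames(as.numeric(counts), classes),
       frequencies = setNames(as.numeric(counts) / nrow(r), classes),
       bp = setNames(as.numeric(bp_by_class), classes))
}

#' Genome-composition-normalized element mapping ratio
#'
#' Element classes (repeat annotations) may overlap each other; a record
#' contributes to every class it touches. The primary observed share of a
#' class is the fraction of records whose midpoint lies in the class (the
#' same midpoint convention the per-window density statistics use), and
#' the ratio is that share divided by the class's share of the genome, so
#' uniform placement gives 1 for every class. A binary any-overlap share
#' would inflate short-element classes by roughly record length / element
#' length even under uniform placement; it is reported as `n_overlapping`
#' alongside, and the mean fraction of record bp in the class (slightly
#' attenuated for planted effects because records straddle element edges)
#' as `ratio_bp`. A percentile bootstrap over records yields the CI; a
#' copy-number-normalized ratio (share of elements rather than bp) is
#' reported as `ratio_by_count`.
#'
#' @param catalog an [eccdna_catalog] (or records data frame).
#' @param elements an [annotation_track] of repeat features.
#' @param chrom_lengths named chromosome lengths.
#' @param n_boot bootstrap replicates (default 200); 0 disables the CI.
#' @param seed seed for the bootstrap.
#' @param min_overlap minimum overlap in bp to count a record as
#'   overlapping (for `n_overlapping`).
#' @return data frame: class, n_overlapping, observed_fraction, genome_bp,
#'   genome_fraction, ratio, ci_lo, ci_hi, ratio_by_count.
#' @export
normalized_mapping_ratio <- function(catalog, elements, chrom_lengths,
                                     n_boot = 200L, seed = 1L,
                                     min_overlap = 1L) {
  r <- if (is.data.frame(catalog)) catalog else catalog$records
  assert_that(nrow(r) > 0, "empty catalog")
  feats <- elements$features
  classes <- REPEAT_CLASSES[REPEAT_CLASSES %in% unique(feats$feature_class)]
  assert_that(length(classes) > 0, "no repeat classes in the element track")
  genome_bp_total <- sum(as.numeric(chrom_lengths))
  rec_gr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start + 1L, r$end))
  mid <- (r$start + r$end) %/% 2
  mid_gr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  rec_w <- r$end - r$start
  n <- nrow(r)
  inmid <- matrix(FALSE, n, length(classes), dimnames = list(NULL, classes))
  frac <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  n_over <- setNames(numeric(length(classes)), classes)
  genome_bp <- setNames(numeric(length(classes)), classes)
  n_elements <- setNames(numeric(length(classes)), classes)
  for (cls in classes) {
    gr <- reduce_class(feats, cls, chrom_lengths)
    genome_bp[cls] <- sum(as.numeric(GenomicRanges::width(gr)))
    n_elements[cls] <- sum(feats$feature_class == cls)
    if (!length(gr)) next
    inmid[, cls] <- IRanges::overlapsAny(mid_gr, gr)
    hits <- GenomicRanges::findOverlaps(rec_gr, gr)
    if (length(hits)) {
      ovw <- GenomicRanges::width(GenomicRanges::pintersect(
        rec_gr[S4Vectors::queryHits(hits)], gr[S4Vectors::subjectHits(hits)]))
      tot <- rowsum(ovw, S4Vectors::queryHits(hits))
      qi <- as.integer(rownames(tot))
      frac[qi, cls] <- tot[, 1] / rec_w[qi]
      n_over[cls] <- sum(tot[, 1] >= min_overlap)
    }
  }
  gfrac <- genome_bp / genome_bp_total
  efrac <- if (sum(n_elements) > 0) n_elements / sum(n_elements) else n_elements
  obs <- colMeans(inmid)
  obs_bp <- colMeans(frac)
  ratio <- ifelse(gfrac > 0, obs / gfrac, NA_real_)
  ratio_bp <- ifelse(gfrac > 0, obs_bp / gfrac, NA_real_)
  ratio_count <- ifelse(efrac > 0, obs / efrac, NA_real_)
  ci <- matrix(NA_real_, length(classes), 2)
  if (n_boot > 0) {
    with_seed(derive_seed(seed, "ratio_boot"), {
      boots <- matrix(NA_real_, n_boot, length(classes))
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        boots[b, ] <- colMeans(inmid[idx, , drop = FALSE]) /
          ifelse(gfrac > 0, gfrac, NA_real_)
      }
    })
    ci <- t(apply(boots, 2, quantile, c(0.025, 0.975), na.rm = TRUE))
  }
  data.frame(class = classes,
             n_overlapping = n_over,
             observed_fraction = obs,
             genome_bp = genome_bp,
             genome_fraction = gfrac,
             ratio = ratio,
             ci_lo = ci[, 1], ci_hi = ci[, 2],
             ratio_bp = ratio_bp,
             ratio_by_count = ratio_count,
             row.names = NULL)
}
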