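# GC profiling of eccDNA loci against their immediate flanks and a
# length-matched random-genome background (the resampling null).

# N fraction of intervals, via the cached cumulative index
genome_n_fraction <- function(genome, chrom, start, end) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    idx <- gc_index(genome, ch)
    n0 <- c(0L, idx$n)
    s <- start[i]; e <- end[i]
    out[i] <- (n0[e + 1L] - n0[s + 1L]) / (e - s)
  }
  out
}

#' Locus and flank GC profile of catalog records
#'
#' For each record the locus GC and the GC of the 1-kb windows immediately
#' upstream (`[start - flank, start)`) and downstream (`[end, end + flank)`)
#' are computed. Windows extending past chromosome bounds are clipped and
#' flagged; an empty clipped window yields `NA`.
#'
#' @param catalog an [eccdna_catalog] (or records data frame).
#' @param genome a [genome_model]; records on chromosomes absent from the
#'   genome are dropped.
#' @param flank flank width in bp (default 1000).
#' @return data frame with chrom/start/end, `locus_gc`, `upstream_gc`,
#'   `downstream_gc` and clipping flags.
#' @export
flank_profile <- function(catalog, genome, flank = 1000L) {
  r <- if (is.data.frame(catalog)) catalog else catalog$records
  r <- r[r$chrom %in% genome$chrom_names, , drop = FALSE]
  assert_that(nrow(r) > 0, "no records on genome chromosomes")
  L <- genome$chrom_lengths[r$chrom]
  us <- pmax(r$start - flank, 0)
  de <- pmin(r$end + flank, L)
  out <- data.frame(chrom = r$chrom, start = r$start, end = r$end)
  out$locus_gc <- genome_gc(genome, r$chrom, r$start, r$end)
  out$upstream_gc <- NA_real_
  ok <- us < r$start
  out$upstream_gc[ok] <- genome_gc(genome, r$chrom[ok], us[ok], r$start[ok])
  out$downstream_gc <- NA_real_
  ok2 <- de > r$end
  out$downstream_gc[ok2] <- genome_gc(genome, r$chrom[ok2], r$end[ok2], de[ok2])
  out$upstream_clipped <- r$start - flank < 0
  out$downstream_clipped <- r$end + flank > L
  rownames(out) <- NULL
  out
}

# cumulative valid-start positions for stretches of length len
.valid_positions <- function(genome, len) {
  v <- pmax(genome$chrom_lengths - len + 1, 0)
  v[genome$chrom_lengths < len] <- 0
  v
}

#' Length-matched random-genome background GC for one record
#'
#' Draws `n` stretches of exactly the record's length, with the start
#' uniform over all valid genome positions (chromosome chosen with
#' probability proportional to its number of valid starts), so stretches
#' are never truncated at chromosome ends. Stretches that are more than
#' half N are rejected and redrawn (at most 100 extra rounds). Draws are
#' fully determined by `(seed, record_index)`, so reordering records never
#' changes a record's background.
#'
#' @param record one-row data frame (or list) with `chrom`, `start`, `end`.
#' @param genome a [genome_model].
#' @param n number of stretches (default 1000).
#' @param seed integer seed.
#' @param record_index index of the record within its catalog (default 1).
#' @return numeric vector of `n` GC fractions.
#' @export
random_background <- function(record, genome, n = 1000L, seed = 1L,
                              record_index = 1L) {
  ctx <- .bg_ctx(genome)
  with_seed(.bg_stream(seed, record_index), {
    .bg_gc(record$end - record$start, ctx, n)
  })
}

# per-record background stream: fully determined by (seed, record index)
.bg_stream <- function(seed, record_index) {
  as.integer((derive_seed(seed, "bg") + record_index * 2654435) %% 2147483647)
}

# precomputed genome context for the background sampler
.bg_ctx <- function(genome) {
  idx <- lapply(genome$chrom_names, function(ch) {
    i <- gc_index(genome, ch)
    list(gc0 = c(0L, i$gc), n0 = c(0L, i$n))
  })
  has_n <- any(vapply(idx, function(i) tail(i$n0, 1) > 0, TRUE))
  list(idx = idx, lens = unname(genome$chrom_lengths), has_n = has_n)
}

# GC of n length-matched stretches; draws from the current RNG state
.bg_gc <- function(len, ctx, n) {
  valid <- pmax(ctx$lens - len + 1, 0)
  keep <- which(valid > 0)
  tot <- sum(as.numeric(valid[keep]))
  assert_that(tot > 0, "no valid position for a stretch of this length")
  cum <- cumsum(as.numeric(valid[keep]))
  cum0 <- c(0, cum)
  draw_gc <- function(k) {
    u <- runif(k) * tot
    ci <- findInterval(u, cum, left.open = TRUE) + 1L
    off <- pmin(pmax(floor(u - cum0[ci]), 0), valid[keep][ci] - 1)
    gc <- numeric(k); nfrac <- numeric(k)
    for (j in seq_along(keep)) {
      i <- which(ci == j)
      if (!length(i)) next
      cidx <- ctx$idx[[keep[j]]]
      s <- off[i]
      g <- cidx$gc0[s + len + 1L] - cidx$gc0[s + 1L]
      if (ctx$has_n) {
        nn <- cidx$n0[s + len + 1L] - cidx$n0[s + 1L]
        denom <- len - nn
        gc[i] <- ifelse(denom > 0, g / denom, NA_real_)
        nfrac[i] <- nn / len
      } else {
        gc[i] <- g / len
      }
    }
    list(gc = gc, nfrac = nfrac)
  }
  d <- draw_gc(n)
  gc <- d$gc
  bad <- which(d$nfrac > 0.5 | is.na(gc))
  tries <- 0L
  while (length(bad) && tries < 100L) {
    tries <- tries + 1L
    d2 <- draw_gc(length(bad))
    ok <- d2$nfrac <= 0.5 & !is.na(d2$gc)
    gc[bad[ok]] <- d2$gc[ok]
    bad <- bad[!ok]
  }
  gc
}

#' GC enrichment of eccDNA loci against the length-matched background
#'
#' The statistic is the mean locus GC minus the mean of the pooled
#' random-background GC; significance is a two-sided Mann-Whitney test of
#' the per-record locus GC values against the pooled background draws.
#' Under uniform placement each locus and each background stretch is an
#' identically distributed length-matched stretch, so the two samples are
#' exchangeable and the rank test holds its nominal level (comparing loci
#' to per-record background *means* instead would mix unequal variances
#' and over-reject). GC fractions are bounded and skewed, hence a rank
#' test rather than a t-test.
#'
#' @param catalog an [eccdna_catalog].
#' @param genome a [genome_model].
#' @param n_random background stretches per record (default 1000).
#' @param seed integer seed governing all background draws.
#' @param min_records minimum catalog size (default 30).
#' @return list with `statistic`, `p_value`, `direction`, `mean_locus_gc`,
#'   `mean_background_gc`, `genome_gc` (whole-genome baseline, reported as
#'   the secondary reference), `n_records` and the per-record table.
#' @export
gc_enrichment_test <- function(catalog, genome, n_random = 1000L, seed = 1L,
                               min_records = 30L) {
  r <- catalog$records[catalog$records$chrom %in% genome$chrom_names, ,
                       drop = FALSE]
  assert_that(nrow(r) >= min_records,
              sprintf("need >= %d records on the genome", min_records))
  locus <- genome_gc(genome, r$chrom, r$start, r$end)
  lens <- r$end - r$start
  ctx <- .bg_ctx(genome)
  bg <- with_seed(0L, lapply(seq_len(nrow(r)), function(i) {
    set.seed(.bg_stream(seed, i))
    .bg_gc(lens[i], ctx, n_random)
  }))
  bg_mean <- vapply(bg, mean, 0, na.rm = TRUE)
  bg_pool <- unlist(bg)
  bg_pool <- bg_pool[!is.na(bg_pool)]
  ok <- !is.na(locus) & !is.na(bg_mean)
  stat <- mean(locus[ok]) - mean(bg_pool)
  wt <- suppressWarnings(wilcox.test(locus[ok], bg_pool))
  list(statistic = stat,
       p_value = wt$p.value,
       direction = if (stat >= 0) "enriched" else "depleted",
       mean_locus_gc = mean(locus[ok]),
       mean_background_gc = mean(bg_pool),
       genome_gc = genome_gc_total(genome),
       n_records = sum(ok),
       per_record = data.frame(r[, c("chrom", "start", "end")],
                               locus_gc = locus, background_gc = bg_mean))
}
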