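# Independent brute-force oracles and tiny fixture builders used across the
# suite. Each oracle is written from the definition, independently of the
# package's implementation path.

# all-pairs overlap scan: distinct species per gene and genes per species
brute_overlap <- function(species, genes) {
  per_gene <- setNames(integer(nrow(genes)), genes$gene_id)
  per_species <- integer(nrow(species))
  for (i in seq_len(nrow(species))) {
    for (j in seq_len(nrow(genes))) {
      if (species$chrom[i] == genes$chrom[j] &&
          species$start[i] < genes$end[j] &&
          genes$start[j] < species$end[i]) {
        per_gene[genes$gene_id[j]] <- per_gene[genes$gene_id[j]] + 1L
        per_species[i] <- per_species[i] + 1L
      }
    }
  }
  list(per_gene = per_gene, per_species = per_species)
}

# running-sum ssGSEA score, coded from the definition
brute_ssgsea <- function(x, in_set, alpha = 0.25) {
  n <- length(x)
  rnk <- rank(x, ties.method = "average")
  ord <- order(-x)
  num <- 0; den_in <- sum(rnk[ord][in_set[ord]]^alpha)
  n_out <- sum(!in_set)
  run_in <- 0; run_out <- 0; total <- 0
  for (k in seq_len(n)) {
    g <- ord[k]
    if (in_set[g]) run_in <- run_in + rnk[g]^alpha / den_in
    else run_out <- run_out + 1 / n_out
    total <- total + (run_in - run_out)
  }
  unname(total)
}

# two-group log-rank chi-square from 2x2 tables at each event time
hand_logrank <- function(time, event, group) {
  g1 <- unique(group)[1]
  ut <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Mann-Whitney AUC by explicit all-pairs counting with midrank ties
allpairs_auc <- function(marker, labels) {
  pos <- marker[labels == 1]
  neg <- marker[labels == 0]
  u <- 0
  for (p in pos) for (q in neg) {
    u <- u + (p > q) + 0.5 * (p == q)
  }
  u / (length(pos) * length(neg))
}

# per-bp scan wGII (ploidy = length-weighted modal CN)
brute_wgii <- function(seg, chrom_lengths) {
  cn_by_bp <- integer(0)
  per_chrom <- c()
  for (ch in names(chrom_lengths)) {
    v <- integer(chrom_lengths[[ch]])
    s <- seg[seg$chrom == ch, ]
    for (i in seq_len(nrow(s))) v[(s$start[i] + 1):s$end[i]] <- s$cn[i]
    cn_by_bp <- c(cn_by_bp, v)
  }
  ploidy <- as.integer(names(which.max(table(cn_by_bp))))
  for (ch in names(chrom_lengths)) {
    v <- integer(chrom_lengths[[ch]])
    s <- seg[seg$chrom == ch, ]
    for (i in seq_len(nrow(s))) v[(s$start[i] + 1):s$end[i]] <- s$cn[i]
    per_chrom <- c(per_chrom, mean(v != ploidy))
  }
  mean(per_chrom)
}

# deterministic toy genome from explicit sequences
toy_genome <- function(...) {
  genome_model(c(...))
}

# small record data frame constructor
recs <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end)
}

# adjusted Rand index for two labelings (two-cluster case)
label_agreement <- function(a, b) {
  max(mean(a == b), mean(a != b))
}
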