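#' Generate copy-number segment sets whose wGII tracks the H/L groups
#'
#' Each sample gets a target wGII drawn around its group's
#' `wgii_targets` value; every chromosome receives one aberrant segment
#' (copy number 1, 3 or 4 against a diploid background) whose length equals
#' the chromosome's aberrant fraction, so segments tile each chromosome
#' exactly and the realized wGII is the mean of the per-chromosome
#' fractions.
#'
#' @param config a [sim_config].
#' @param group_labels `"H"`/`"L"` per sample (default [sim_group_labels()]).
#' @param chrom_lengths named chromosome lengths; default from the config.
#' @return named list of [cn_segment_set].
#' @export
generate_cn_segments <- function(config, group_labels = sim_group_labels(config),
                                 chrom_lengths = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- setNames(rep_len(config$chrom_length, config$n_chrom),
                              paste0("chr", seq_len(config$n_chrom)))
  }
  sets <- vector("list", length(group_labels))
  for (i in seq_along(group_labels)) {
    sid <- sprintf("S%02d", i)
    with_seed(derive_seed(config$seed, paste0("cn_", i)), {
      target <- config$wgii_targets[[group_labels[i]]] +
        rnorm(1, 0, config$wgii_noise_sd)
      target <- min(max(target, 0), 0.95)
      segs <- lapply(names(chrom_lengths), function(ch) {
        L <- chrom_lengths[[ch]]
        f <- min(max(target + rnorm(1, 0, 0.03), 0), 1)
        ab_len <- round(f * L)
        if (ab_len <= 0) {
          return(data.frame(chrom = ch, start = 0, end = L, cn = 2L))
        }
        if (ab_len >= L) {
          return(data.frame(chrom = ch, start = 0, end = L,
                            cn = sample(c(1L, 3L, 4L), 1L)))
        }
        s <- floor(runif(1, 0, L - ab_len))
        cn_ab <- sample(c(1L, 3L, 4L), 1L)
        out <- data.frame(chrom = ch,
                          start = c(0, s, s + ab_len),
                          end = c(s, s + ab_len, L),
                          cn = c(2L, cn_ab, 2L))
        out[out$end > out$start, , drop = FALSE]
      })
    })
    sets[[i]] <- cn_segment_set(sid, do.call(rbind, segs), chrom_lengths)
  }
  names(sets) <- vapply(sets, `[[`, "", "sample_id")
  sets
}

#' Generate an expression matrix with planted fold-change structure
#'
#' Values are log-normal around gene baselines; the first `n_de / 2` genes
#' are upregulated in H by `fold_change`, the next `n_de / 2` downregulated,
#' and all remaining genes have group-mean ratio 1.
#'
#' @param config a [sim_config].
#' @param group_labels group label per column; default
#'   `expr_n_per_group` H columns followed by as many L columns.
#' @param prefix column-name prefix.
#' @param stream RNG stream label (distinct matrices per label).
#' @return list with `matrix` (genes x samples), `groups` (named labels) and
#'   `truth` (data frame of planted fold changes per gene).
#' @export
generate_expression <- function(config, group_labels = NULL,
                                prefix = "C", stream = "expression") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(group_labels)) {
    group_labels <- rep(c("H", "L"), each = config$expr_n_per_group)
  }
  n_genes <- config$n_genes
  n_up <- floor(config$n_de / 2)
  n_dn <- config$n_de - n_up
  assert_that(n_genes >= config$n_de, "n_de exceeds n_genes")
  genes <- sprintf("G%05d", seq_len(n_genes))
  lfc <- numeric(n_genes)
  if (n_up > 0) lfc[seq_len(n_up)] <- log2(config$fold_change)
  if (n_dn > 0) lfc[n_up + seq_len(n_dn)] <- -log2(config$fold_change)
  with_seed(derive_seed(config$seed, stream), {
    base <- rnorm(n_genes, 5, 1.5)
    m <- matrix(0, n_genes, length(group_labels))
    for (j in seq_along(group_labels)) {
      shift <- if (group_labels[j] == "H") lfc / 2 else -lfc / 2
      m[, j] <- 2^(base + shift + rnorm(n_genes, 0, config$expr_sigma))
    }
  })
  rownames(m) <- genes
  colnames(m) <- sprintf("%s%03d", prefix, seq_along(group_labels))
  truth <- data.frame(gene = genes, log2_fc = lfc,
                      direction = ifelse(lfc > 0, "up",
                                         ifelse(lfc < 0, "down", "none")))
  list(matrix = m, groups = setNames(group_labels, colnames(m)),
       truth = truth)
}

#' Generate a survival cohort with a planted hazard ratio
#'
#' Event times are exponential with the baseline hazard, multiplied by
#' `survival_hr` for patients whose score exceeds the cohort median.
#' A configured fraction of patients is independently censored at a uniform
#' time before their event.
#'
#' @param config a [sim_config].
#' @param scores per-patient covariate scores; default standard normal of
#'   size `surv_n`.
#' @param stream RNG stream label.
#' @return data frame with `id`, `time`, `event`, `score` and the true
#'   stratum in `truth_stratum`.
#' @export
generate_survival_cohort <- function(config, scores = NULL,
                                     stream = "survival") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, stream), {
    if (is.null(scores)) scores <- rnorm(config$surv_n)
    n <- length(scores)
    high <- scores > median(scores)
    rate <- config$baseline_hazard * ifelse(high, config$survival_hr, 1)
    t_event <- rexp(n, rate)
    censored <- runif(n) < config$censoring_rate
    time <- ifelse(censored, runif(n) * t_event, t_event)
    time <- pmax(time, 1e-6)
  })
  data.frame(id = sprintf("P%04d", seq_len(n)),
             time = time,
             event = as.integer(!censored),
             score = scores,
             truth_stratum = ifelse(high, "high", "low"))
}
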