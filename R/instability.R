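#' Weighted genome instability index (wGII)
#'
#' Sample ploidy is the length-weighted modal integer copy number across the
#' genome; each chromosome's aberrant fraction is the fraction of its length
#' at a copy number different from ploidy; wGII is the unweighted mean of
#' the per-chromosome fractions, so every chromosome contributes equally
#' regardless of its length.
#'
#' @param segments a [cn_segment_set] whose segments tile every chromosome.
#' @param chrom_lengths optional named lengths for coverage validation;
#'   defaults to the extent of the segments.
#' @param exclude optional chromosomes to drop (e.g. sex chromosomes).
#' @param ploidy optional known baseline ploidy; when `NULL` (default) the
#'   length-weighted modal copy number is inferred from the segments.
#' @return list with `sample_id`, `ploidy`, `per_chrom` (named aberrant
#'   fractions) and `wgii`.
#' @export
compute_wgii <- function(segments, chrom_lengths = NULL, exclude = NULL,
                         ploidy = NULL) {
  stopifnot(inherits(segments, "cn_segment_set"))
  seg <- segments$segments
  if (!is.null(exclude)) seg <- seg[!(seg$chrom %in% exclude), , drop = FALSE]
  assert_that(nrow(seg) > 0, "no segments left")
  if (!is.null(chrom_lengths)) {
    for (ch in unique(seg$chrom)) {
      covered <- sum(seg$end[seg$chrom == ch] - seg$start[seg$chrom == ch])
      assert_that(covered == chrom_lengths[[ch]],
                  sprintf("coverage gap on chromosome %s", ch))
    }
  }
  seg_len <- seg$end - seg$start
  if (is.null(ploidy)) {
    by_cn <- tapply(seg_len, seg$cn, sum)
    ploidy <- as.integer(names(by_cn)[which.max(by_cn)])
  }
  per_chrom <- vapply(split(seq_len(nrow(seg)), seg$chrom), function(i) {
    ab <- seg$cn[i] != ploidy
    sum(seg_len[i][ab]) / sum(seg_len[i])
  }, 0)
  list(sample_id = segments$sample_id, ploidy = ploidy,
       per_chrom = per_chrom, wgii = mean(per_chrom))
}

# multiplicative-update NMF (Lee-Seung, Frobenius loss), one run
.nmf_once <- function(V, k, max_iter, tol) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(runif(n * k, 0.1, 1), n, k)
  H <- matrix(runif(k * m, 0.1, 1), k, m)
  eps <- 1e-12
  err_prev <- Inf
  errs <- numeric(0)
  for (it in seq_len(max_iter)) {
    H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% H %*% t(H) + eps)
    err <- sqrt(sum((V - W %*% H)^2))
    errs <- c(errs, err)
    if (is.finite(err_prev) && err_prev - err < tol * max(err, 1)) break
    err_prev <- err
  }
  list(W = W, H = H, error = err, trace = errs)
}

#' Two-group NMF classification of samples by eccDNA abundance features
#'
#' Factorizes the non-negative samples-by-features matrix with
#' multiplicative updates minimizing the Frobenius error (best of
#' `n_restarts` restarts, ties to the lowest restart index). Each sample is
#' assigned to the component with the larger basis coefficient; the
#' component whose samples have the larger mean `abundance` is labelled H.
#'
#' @param feature_matrix samples x features non-negative matrix (e.g.
#'   per-chromosome normalized eccDNA counts, see
#'   [abundance_feature_matrix()]).
#' @param abundance named per-sample normalized abundance (EPM) used to
#'   orient the H/L labels.
#' @param k number of components (2).
#' @param n_restarts random restarts (default 50).
#' @param seed integer seed.
#' @param max_iter,tol update iteration controls.
#' @return list with `labels` (named H/L), `W`, `H`, `error` and the
#'   per-iteration error trace of the winning run.
#' @export
nmf_group <- function(feature_matrix, abundance, k = 2L, n_restarts = 50L,
                      seed = 1L, max_iter = 500L, tol = 1e-9) {
  stopifnot(is.matrix(feature_matrix))
  assert_that(all(feature_matrix >= 0), "feature matrix must be non-negative")
  assert_that(nrow(feature_matrix) >= 4, "need at least 4 samples")
  sids <- rownames(feature_matrix) %||% paste0("S", seq_len(nrow(feature_matrix)))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    with_seed(derive_seed(seed, paste0("nmf_", r)), {
      fit <- .nmf_once(feature_matrix, k, max_iter, tol)
    })
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  assert_that(all(diff(best$trace) <= 1e-8 * max(best$trace[1], 1)),
              "NMF error increased across iterations")
  # scale coefficients by the magnitude of each component's basis vector so
  # the assignment is invariant to the W/H scale indeterminacy
  scaled <- best$W %*% diag(sqrt(rowSums(best$H^2)), k, k)
  comp <- max.col(scaled, ties.method = "first")
  ab <- abundance[sids]
  mean_ab <- tapply(ab, comp, mean)
  h_comp <- as.integer(names(mean_ab)[which.max(mean_ab)])
  labels <- setNames(ifelse(comp == h_comp, "H", "L"), sids)
  list(labels = labels, W = best$W, H = best$H, error = best$error,
       trace = best$trace)
}

#' Per-sample per-chromosome abundance feature matrix for NMF
#'
#' Chromosome-level eccDNA counts per sample, scaled per million mapped
#' reads. By default each feature is complement-augmented (paired with its
#' distance to the cohort maximum), the standard mirror coding that lets a
#' two-component NMF resolve a burden (magnitude) split: without it,
#' high- and low-abundance samples have parallel chromosome profiles and
#' the factorization cannot tell them apart.
#'
#' @param catalogs list of [eccdna_catalog].
#' @param chrom_lengths named chromosome lengths.
#' @param augment add mirrored complement features (default `TRUE`).
#' @param log_scale apply `log1p` before augmentation (default `FALSE`).
#' @return samples x features non-negative matrix.
#' @export
abundance_feature_matrix <- function(catalogs, chrom_lengths,
                                     augment = TRUE, log_scale = FALSE) {
  m <- matrix(unlist(lapply(catalogs, function(ct) {
    cnt <- table(factor(ct$records$chrom, levels = names(chrom_lengths)))
    as.numeric(cnt) / ct$mapped_read_total * 1e6
  })), nrow = length(catalogs), byrow = TRUE,
  dimnames = list(vapply(catalogs, `[[`, "", "sample_id"),
                  names(chrom_lengths)))
  if (log_scale) m <- log1p(m)
  if (augment) {
    mx <- matrix(rep(apply(m, 2, max), each = nrow(m)), nrow(m))
    aug <- mx - m
    colnames(aug) <- paste0(colnames(m), "_mirror")
    m <- cbind(m, aug)
  }
  m
}

#' Association between genome instability and eccDNA abundance
#'
#' @param wgii list of [compute_wgii()] results.
#' @param abundance list of [compute_abundance()] results (or a named EPM
#'   vector).
#' @param labels optional named H/L labels for the group contrast.
#' @return list with Pearson and Spearman r/p, and (when labels are given)
#'   the H-vs-L wGII Mann-Whitney contrast.
#' @export
instability_association <- function(wgii, abundance, labels = NULL) {
  w <- setNames(vapply(wgii, `[[`, 0, "wgii"),
                vapply(wgii, `[[`, "", "sample_id"))
  if (is.list(abundance) && !is.numeric(abundance)) {
    abundance <- setNames(vapply(abundance, `[[`, 0, "epm"),
                          vapply(abundance, `[[`, "", "sample_id"))
  }
  common <- intersect(names(w), names(abundance))
  assert_that(length(common) >= 3, "need >= 3 shared samples")
  w <- w[common]; a <- abundance[common]
  if (sd(w) == 0 || sd(a) == 0) {
    warning("degenerate values: correlation undefined", call. = FALSE)
    return(list(pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_r = NA_real_, spearman_p = NA_real_,
                group_contrast = NULL))
  }
  pe <- cor.test(w, a, method = "pearson")
  sp <- cor.test(w, a, method = "spearman", exact = FALSE)
  contrast <- NULL
  if (!is.null(labels)) {
    lab <- labels[common]
    if (length(unique(lab)) == 2) {
      mw <- suppressWarnings(wilcox.test(w[lab == "H"], w[lab == "L"]))
      contrast <- list(mean_H = mean(w[lab == "H"]),
                       mean_L = mean(w[lab == "L"]),
                       p_value = mw$p.value)
    }
  }
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_r = unname(sp$estimate), spearman_p = sp$p.value,
       group_contrast = contrast)
}
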