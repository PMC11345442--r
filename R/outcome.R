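#' Group differential expression between H and L samples
#'
#' Fold change is `(mean_H + eps) / (mean_L + eps)` with a `1e-9`
#' pseudocount, so swapping the group labels maps every fold change to its
#' reciprocal and exchanges the up/down calls exactly. Significance is a
#' Wilcoxon rank-sum test per gene with Benjamini-Hochberg adjustment;
#' `gate = "fc_only"` reproduces the bare fold-change filter.
#'
#' @param matrix genes x samples non-negative expression matrix.
#' @param groups named `"H"`/`"L"` labels covering the columns.
#' @param fc_threshold fold-change threshold (default 1.2); a gene is up
#'   when FC > threshold, down when FC < 1/threshold.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param gate `"wilcoxon"` (default: FC and adjusted p) or `"fc_only"`.
#' @return data frame per gene: mean_H, mean_L, fold_change, p_value,
#'   p_adj, call (up/down/none).
#' @export
differential_expression <- function(matrix, groups, fc_threshold = 1.2,
                                    alpha = 0.05,
                                    gate = c("wilcoxon", "fc_only")) {
  gate <- match.arg(gate)
  stopifnot(is.matrix(matrix))
  groups <- groups[colnames(matrix)]
  assert_that(all(groups %in% c("H", "L")), "groups must be H/L over all columns")
  h <- which(groups == "H"); l <- which(groups == "L")
  assert_that(length(h) >= 3 && length(l) >= 3,
              "need >= 3 samples per group")
  eps <- 1e-9
  mean_h <- rowMeans(matrix[, h, drop = FALSE])
  mean_l <- rowMeans(matrix[, l, drop = FALSE])
  fc <- (mean_h + eps) / (mean_l + eps)
  if (gate == "wilcoxon") {
    p <- vapply(seq_len(nrow(matrix)), function(i) {
      suppressWarnings(wilcox.test(matrix[i, h], matrix[i, l])$p.value)
    }, 0)
  } else {
    p <- rep(NA_real_, nrow(matrix))
  }
  p_adj <- if (gate == "wilcoxon") p.adjust(p, "BH") else p
  up <- fc > fc_threshold
  dn <- fc < 1 / fc_threshold
  if (gate == "wilcoxon") {
    up <- up & p_adj < alpha
    dn <- dn & p_adj < alpha
  }
  data.frame(gene = rownames(matrix) %||% as.character(seq_len(nrow(matrix))),
             mean_H = mean_h, mean_L = mean_l, fold_change = fc,
             p_value = p, p_adj = p_adj,
             call = ifelse(up, "up", ifelse(dn, "down", "none")),
             row.names = NULL)
}

#' Build a gene panel from the top upregulated genes
#'
#' Up-called genes sorted by descending fold change, ties by ascending
#' adjusted p then lexicographic gene id; the first `n` are taken.
#'
#' @param de a [differential_expression()] result.
#' @param n panel size (default 100).
#' @return character vector of gene ids (length <= n; a shortfall is
#'   messaged).
#' @export
build_panel <- function(de, n = 100L) {
  up <- de[de$call == "up", , drop = FALSE]
  pa <- up$p_adj
  pa[is.na(pa)] <- 0
  up <- up[order(-up$fold_change, pa, up$gene), , drop = FALSE]
  if (nrow(up) < n) {
    message(sprintf("panel shortfall: %d up-genes available for a panel of %d",
                    nrow(up), n))
  }
  head(up$gene, n)
}

# ssGSEA score of one sample (rank-weighted integrated running difference)
.ssgsea_one <- function(x, in_set, alpha) {
  n <- length(x)
  rnk <- rank(x, ties.method = "average")
  ord <- order(-x)                       # walk from highest expression down
  w <- rnk[ord]^alpha
  inset <- in_set[ord]
  p_in <- cumsum(w * inset) / sum(w * inset)
  n_out <- n - sum(in_set)
  p_out <- if (n_out > 0) cumsum(!inset) / n_out else numeric(n)
  sum(p_in - p_out)
}

#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For each sample, genes are ranked by expression; walking the ranked list
#' from the top, the in-set cumulative weight (weight = within-sample
#' expression rank to the power `alpha`, normalized over panel genes) minus
#' the uniform out-of-set cumulative fraction is accumulated, and the score
#' is the sum of this running difference over all positions. The score
#' depends on expression only through within-sample ranks, so it is
#' invariant under any monotone transform of a sample's values.
#'
#' @param matrix genes x samples expression matrix.
#' @param panel character vector of panel gene ids; at least one must be in
#'   the matrix.
#' @param alpha rank weight exponent (default 0.25).
#' @param normalize min-max normalize scores across samples (default
#'   `TRUE`, the common ssGSEA convention; `FALSE` returns the raw
#'   integrated difference).
#' @return named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(matrix, panel, alpha = 0.25, normalize = TRUE) {
  stopifnot(is.matrix(matrix))
  in_set <- rownames(matrix) %in% panel
  assert_that(any(in_set), "no panel gene present in the matrix")
  if (length(setdiff(panel, rownames(matrix)))) {
    message(sprintf("%d panel gene(s) absent from the matrix",
                    length(setdiff(panel, rownames(matrix)))))
  }
  scores <- vapply(seq_len(ncol(matrix)), function(j) {
    .ssgsea_one(matrix[, j], in_set, alpha)
  }, 0)
  names(scores) <- colnames(matrix)
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1]) / diff(rng)
  }
  scores
}
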