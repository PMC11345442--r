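# Kaplan-Meier / log-rank machinery, maximally selected (optimal-cutoff)
# dichotomization with permutation correction, and marker ROC/AUC.

#' Two-group Kaplan-Meier comparison with the log-rank test
#'
#' Product-limit curves per group and the standard two-group log-rank
#' chi-square (1 df, hypergeometric variance with Breslow-style
#' simultaneous tie handling), plus a Cox hazard-ratio estimate for the
#' second level against the first.
#'
#' @param cohort data frame with `time` (> 0) and `event` (0/1).
#' @param labels group label per patient (two levels).
#' @return list with `curves` (per-group time / surv / n.risk / n.event),
#'   `chisq`, `p_value`, `hazard_ratio`, `group_sizes`.
#' @export
km_logrank <- function(cohort, labels) {
  assert_that(all(cohort$time > 0), "times must be positive")
  assert_that(all(cohort$event %in% c(0, 1)), "event must be 0/1")
  labels <- as.factor(labels)
  assert_that(nlevels(labels) == 2, "need exactly two groups")
  df <- data.frame(time = cohort$time, event = cohort$event, group = labels)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, censored = TRUE)
  curves <- data.frame(group = sub("^group=", "", as.character(sm$strata)),
                       time = sm$time, surv = sm$surv,
                       n_risk = sm$n.risk, n_event = sm$n.event)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chisq <- sd_$chisq
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  hr <- tryCatch({
    cx <- survival::coxph(survival::Surv(time, event) ~ group, data = df)
    unname(exp(coef(cx)))
  }, error = function(e) NA_real_, warning = function(w) NA_real_)
  list(curves = curves, chisq = chisq, p_value = p, hazard_ratio = hr,
       group_sizes = table(labels))
}

# Vectorized log-rank chi-square for every "first k samples in score order
# vs rest" split. Returns per-k O, E, V and chisq (hypergeometric variance,
# simultaneous tie handling). Internal engine of the optimal-cutoff scan.
.logrank_scan <- function(time, event, ord) {
  n <- length(time)
  ut <- sort(unique(time[event == 1]))
  if (!length(ut)) return(NULL)
  # risk/event indicators per (event time, sample), in scan order
  R <- outer(ut, time[ord], `<=`)           # at risk
  Ev <- outer(ut, time[ord], `==`) * rep(event[ord], each = length(ut))
  n_j <- rowSums(R)
  d_j <- rowSums(Ev)
  N1 <- t(apply(R, 1, cumsum))              # group-1 at risk, per k
  O_k <- cumsum(event[ord])
  E_k <- as.vector(crossprod(N1, d_j / n_j))
  cfac <- ifelse(n_j > 1, d_j * (n_j - d_j) / (n_j - 1), 0)
  frac <- N1 / n_j
  V_k <- as.vector(colSums(cfac * frac * (1 - frac)))
  chisq <- ifelse(V_k > 0, (O_k - E_k)^2 / V_k, 0)
  list(O = O_k, E = E_k, V = V_k, chisq = chisq)
}

#' Optimal-cutoff survival dichotomization (maximally selected log-rank)
#'
#' Scans every candidate cutoff (midpoints between consecutive distinct
#' scores) leaving both groups at least `min_group_frac` of the cohort and
#' selects the one maximizing the log-rank chi-square. The naive p-value
#' (chi-square of the selected split, ignoring selection) is
#' anti-conservative; a label-permutation p-value that re-maximizes over
#' cutoffs in every permutation corrects for the selection and is reported
#' as the primary p.
#'
#' @param scores named per-patient scores (names matching `cohort$id`, or
#'   positional).
#' @param cohort data frame with `id`, `time`, `event`.
#' @param min_group_frac minimum fraction of patients per group.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @return list with `cutoff`, `labels` (high/low), `chisq`,
#'   `p_naive`, `p_adjusted`, `group_sizes`, `km` (the [km_logrank()]
#'   comparison at the selected cutoff).
#' @export
optimal_cutoff <- function(scores, cohort, min_group_frac = 0.2,
                           n_perm = 1000L, seed = 1L) {
  if (!is.null(names(scores)) && all(cohort$id %in% names(scores))) {
    scores <- scores[cohort$id]
  }
  n <- nrow(cohort)
  assert_that(length(scores) == n, "scores must cover the cohort")
  assert_that(n >= 20 && sum(cohort$event) >= 5,
              "need >= 20 patients with >= 5 events")
  assert_that(length(unique(scores)) > 1, "all scores equal: no valid cutoff")
  time <- cohort$time; event <- cohort$event
  ord <- order(scores)
  k_min <- max(1L, ceiling(min_group_frac * n))
  k_max <- n - k_min
  assert_that(k_min <= k_max, "min_group_frac leaves no valid cutoff")
  s_sorted <- scores[ord]
  valid <- seq_len(n - 1) >= k_min & seq_len(n - 1) <= k_max &
    s_sorted[-n] < s_sorted[-1]
  assert_that(any(valid), "no valid cutoff between distinct scores")
  scan <- .logrank_scan(time, event, ord)
  ch <- scan$chisq[seq_len(n - 1)]
  ch[!valid] <- -Inf
  k_star <- which.max(ch)
  obs <- ch[k_star]
  cutoff <- (s_sorted[k_star] + s_sorted[k_star + 1]) / 2
  labels <- ifelse(scores > cutoff, "high", "low")
  p_naive <- pchisq(obs, df = 1, lower.tail = FALSE)
  p_adj <- NA_real_
  if (n_perm > 0) {
    exceed <- 0L
    with_seed(derive_seed(seed, "cutoff_perm"), {
      for (b in seq_len(n_perm)) {
        # permuting scores against (time, event) leaves the sorted score
        # vector - hence the valid cutoff mask - unchanged
        perm <- sample.int(n)
        sc <- .logrank_scan(time, event, perm)
        chp <- sc$chisq[seq_len(n - 1)]
        chp[!valid] <- -Inf
        if (max(chp) >= obs) exceed <- exceed + 1L
      }
    })
    p_adj <- (1 + exceed) / (1 + n_perm)
  }
  km <- km_logrank(cohort, factor(labels, levels = c("low", "high")))
  list(cutoff = cutoff, labels = setNames(labels, cohort$id),
       chisq = obs, p_naive = p_naive, p_adjusted = p_adj,
       group_sizes = table(labels), km = km)
}

#' ROC AUC of a marker against binary labels
#'
#' AUC by the rank (Mann-Whitney) formulation with midrank tie correction
#' and a DeLong confidence interval, oriented so that values above the
#' cutoff indicate the positive class.
#'
#' @param marker numeric marker values.
#' @param labels binary labels (0/1, logical, or two-level factor; the
#'   higher level / `1` is the positive class).
#' @param conf_level CI level (default 0.95).
#' @return list with `auc`, `ci` (lower, upper), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(marker, labels, conf_level = 0.95) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  assert_that(all(labels %in% c(0L, 1L)), "labels must be binary")
  assert_that(length(unique(labels)) == 2, "both labels must be present")
  r <- pROC::roc(response = labels, predictor = marker, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  ci <- suppressWarnings(pROC::ci.auc(r, conf.level = conf_level,
                                      method = "delong"))
  list(auc = as.numeric(pROC::auc(r)),
       ci = c(lower = as.numeric(ci[1]), upper = as.numeric(ci[3])),
       n_pos = sum(labels == 1L), n_neg = sum(labels == 0L))
}
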