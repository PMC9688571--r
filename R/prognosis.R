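#' Patient pseudotime value
#'
#' The bulk-level score: for each sample, the weighted sum of the clusters'
#' mean single-cell pseudotimes, weighted by that cluster's estimated
#' proportion in the sample (`score_b = sum_c w_bc * taubar_c`).
#'
#' @param proportions samples x clusters matrix (rows sum to 1), or a
#'   `"proportion_matrix"` from the deconvolution stage.
#' @param cluster_mean_pt named numeric of per-cluster mean pseudotimes
#'   (from [cluster_mean_pseudotime()]).
#' @return data.frame `sample_id`, `score`.
#' @export
patient_pseudotime_score <- function(proportions, cluster_mean_pt) {
  if (inherits(proportions, "proportion_matrix")) {
    proportions <- proportions$proportions
  }
  w <- as.matrix(proportions)
  missing <- setdiff(colnames(w), names(cluster_mean_pt))
  if (length(missing)) {
    stop("patient_pseudotime_score: no mean pseudotime for cluster(s): ",
         paste(missing, collapse = ", "))
  }
  tau <- cluster_mean_pt[colnames(w)]
  data.frame(sample_id = rownames(w),
             score = as.numeric(w %*% tau),
             stringsAsFactors = FALSE)
}

#' Split samples into good/poor prognosis by observed survival time
#'
#' Median split on the observed time (censored samples enter by their
#' censoring time); times at or above the median are "good".
#'
#' @param surv data.frame with columns `sample_id`, `time_days`, `event`.
#' @param method only `"median"` is implemented.
#' @return Character vector (`"good"`/`"poor"`) named by sample id.
#' @export
dichotomize_by_survival <- function(surv, method = "median") {
  method <- match.arg(method)
  if (nrow(surv) < 2) stop("dichotomize_by_survival: need at least 2 samples")
  t <- surv$time_days
  if (diff(range(t)) == 0) {
    stop("dichotomize_by_survival: all survival times are equal")
  }
  med <- stats::median(t)
  stats::setNames(ifelse(t >= med, "good", "poor"), surv$sample_id)
}

#' Compare cluster content between prognosis groups
#'
#' Per cluster, a two-sided Wilcoxon rank-sum test of the estimated
#' proportions between the two groups. A Benjamini-Hochberg adjusted column
#' is reported alongside the raw p-values; the `significant` flag uses the
#' raw p, matching the single-stage convention.
#'
#' @param proportions samples x clusters matrix or `"proportion_matrix"`.
#' @param groups two-level grouping named by (or aligned with) the samples.
#' @param alpha significance level for the flag.
#' @return data.frame `cluster`, `W`, `p`, `p_adj`, `significant`.
#' @export
compare_cluster_content <- function(proportions, groups, alpha = 0.05) {
  if (inherits(proportions, "proportion_matrix")) {
    proportions <- proportions$proportions
  }
  w <- as.matrix(proportions)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2 || any(table(groups) == 0)) {
    stop("compare_cluster_content: need exactly two non-empty groups")
  }
  g1 <- groups == lv[1]
  res <- lapply(colnames(w), function(cl) {
    x <- w[g1, cl]; y <- w[!g1, cl]
    if (stats::sd(c(x, y)) == 0) {
      warning("compare_cluster_content: constant proportions in cluster ",
              cl, "; p set to 1")
      return(data.frame(cluster = cl, W = length(x) * length(y) / 2, p = 1))
    }
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    data.frame(cluster = cl, W = unname(ht$statistic), p = ht$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank: the statistic is `(sum(O - E))^2 / sum(V)` accumulated
#' over event times, referred to a chi-square distribution with 1 df.
#'
#' @param surv data.frame `sample_id`, `time_days`, `event`.
#' @param groups two-level grouping aligned with the rows of `surv`.
#' @return List `statistic`, `p`.
#' @export
logrank_test <- function(surv, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) != 2) stop("logrank_test: need two groups")
  ev <- tapply(surv$event, groups, sum)
  if (any(ev == 0)) {
    warning("logrank_test: group(s) with zero events: ",
            paste(names(ev)[ev == 0], collapse = ", "))
  }
  if (sum(surv$event) == 0) return(list(statistic = 0, p = 1))
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ g,
                           data = data.frame(surv, g = groups))
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimate per group, with censoring counts retained.
#'
#' @param surv data.frame `sample_id`, `time_days`, `event`.
#' @param groups grouping aligned with the rows of `surv` (single group if
#'   omitted).
#' @return data.frame `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`.
#' @export
km_curve <- function(surv, groups = rep("all", nrow(surv))) {
  groups <- as.character(groups)
  fit <- survival::survfit(survival::Surv(time_days, event) ~ g,
                           data = data.frame(surv, g = groups))
  if (is.null(fit$strata)) {
    grp <- rep(unique(groups)[1], length(fit$time))
  } else {
    grp <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor,
             surv = fit$surv, stringsAsFactors = FALSE)
}

# Log-rank scores (Nelson-Aalen based): a_i = event_i - cumhaz(t_i).
# These are the per-subject scores whose group sums give the log-rank
# statistic in its permutation (conditional) form, as used by maximally
# selected rank statistics.
logrank_scores <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  if (!length(ut)) return(event - 0)
  step <- vapply(ut, function(t) sum(event[time == t]) / sum(time >= t),
                 numeric(1))
  cumch <- cumsum(step)
  idx <- findInterval(time, ut)
  ch_at <- ifelse(idx > 0, cumch[pmax(idx, 1)], 0)
  event - ch_at
}

#' Optimal survival cutpoint by maximally selected log-rank statistic
#'
#' Candidate cutpoints are the midpoints between consecutive distinct score
#' values leaving at least `minprop` of the samples on each side. Each
#' candidate is scored by the standardized log-rank statistic in its
#' permutation form (`|sum of log-rank scores in the low group|` scaled by
#' its hypergeometric variance), and the maximizing cutpoint is selected.
#' The reported p-value is the ordinary (naive) log-rank p at the chosen
#' cut; because the cut is optimized this p is biased low, so an optional
#' permutation-adjusted p (max statistic under score relabelings) is also
#' available via `n_perm`.
#'
#' @param scores numeric score per sample (e.g. patient pseudotime values).
#' @param surv data.frame `sample_id`, `time_days`, `event` aligned with
#'   `scores`.
#' @param minprop minimum fraction of samples on each side of the cut.
#' @param n_perm number of permutations for the adjusted p (0 = skip).
#' @return List: `cutpoint`, `statistic` (max standardized statistic),
#'   `groups` (`"high"`/`"low"` per sample), `chisq`, `p` (naive log-rank at
#'   the cut) and `p_perm` (NA unless `n_perm > 0`).
#' @export
optimal_cutpoint <- function(scores, surv, minprop = 0.1, n_perm = 0) {
  n <- length(scores)
  stopifnot(nrow(surv) == n)
  if (n < 10) stop("optimal_cutpoint: need at least 10 samples")
  if (sum(surv$event) < 2) stop("optimal_cutpoint: need at least 2 events")

  a <- logrank_scores(surv$time_days, surv$event)
  ord <- order(scores)
  s_sorted <- scores[ord]
  a_sorted <- a[ord]
  m_min <- max(1, ceiling(minprop * n))
  csum <- cumsum(a_sorted)
  var_a <- sum(a^2)
  # candidate after position m: requires a strict score increase there
  cand <- which(diff(s_sorted) > 0)
  cand <- cand[cand >= m_min & (n - cand) >= m_min]
  if (!length(cand)) {
    stop("optimal_cutpoint: no candidate cutpoint satisfies minprop = ",
         minprop)
  }
  sd_m <- sqrt(cand * (n - cand) / (n * (n - 1)) * var_a)
  stat <- abs(csum[cand]) / sd_m
  best <- cand[which.max(stat)]
  cutpoint <- (s_sorted[best] + s_sorted[best + 1]) / 2
  groups <- stats::setNames(ifelse(scores > cutpoint, "high", "low"),
                            surv$sample_id)
  lr <- logrank_test(surv, groups)

  p_perm <- NA_real_
  if (n_perm > 0) {
    obs <- max(stat)
    denom <- sqrt(cand * (n - cand) / (n * (n - 1)) * var_a)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      ap <- a[sample.int(n)]
      mstat <- max(abs(cumsum(ap)[cand]) / denom)
      if (mstat >= obs) exceed <- exceed + 1L
    }
    p_perm <- (exceed + 1) / (n_perm + 1)
  }
  list(cutpoint = cutpoint, statistic = max(stat), groups = groups,
       chisq = lr$statistic, p = lr$p, p_perm = p_perm)
}
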