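# Independent brute-force oracles used to validate package computations.
# These deliberately avoid the code paths (and, where possible, the library
# calls) used by the implementation.

oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- 0
  for (x in a) if (any(b == x)) inter <- inter + 1
  uni <- length(a) + length(b) - inter
  if (uni == 0) 0 else inter / uni
}

oracle_mad_keep <- function(expr, thr = 0) {
  keep <- logical(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    keep[i] <- median(abs(x - median(x))) > thr
  }
  which(keep)
}

oracle_tom <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, ]) - a[i, i]
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# minimum spanning tree weight by exhaustive search over edge subsets
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  pairs <- t(combn(n, 2))
  best <- Inf
  for (sel in combn(nrow(pairs), n - 1, simplify = FALSE)) {
    # union-find connectivity check
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in sel) {
      ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (ok) best <- min(best, sum(d[pairs[sel, , drop = FALSE]]))
  }
  best
}

# exact two-sided rank-sum p by enumeration of group assignments (no ties)
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(combn(n, n1), 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * (n - n1) / 2
  p <- if (u_obs > mu) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(1, p)
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  run_min <- 1
  for (i in n:1) {
    run_min <- min(run_min, p[o[i]] * n / i)
    adj[o[i]] <- run_min
  }
  adj
}

# Kaplan-Meier survival probability evaluated at time t
oracle_km_at <- function(time, event, t) {
  s <- 1
  for (u in sort(unique(time[event == 1]))) {
    if (u > t) break
    d <- sum(time == u & event == 1)
    n_at <- sum(time >= u)
    s <- s * (1 - d / n_at)
  }
  s
}

# Nelson-Aalen log-rank scores by explicit loops
oracle_logrank_scores <- function(time, event) {
  n <- length(time)
  a <- numeric(n)
  for (i in seq_len(n)) {
    ch <- 0
    for (u in sort(unique(time[event == 1]))) {
      if (u <= time[i]) ch <- ch + sum(time == u & event == 1) / sum(time >= u)
    }
    a[i] <- event[i] - ch
  }
  a
}

# brute-force maximally selected cutpoint scan
oracle_cutpoint <- function(scores, time, event, minprop = 0.1) {
  n <- length(scores)
  a <- oracle_logrank_scores(time, event)
  va <- sum(a^2)
  ss <- sort(unique(scores))
  best <- list(stat = -Inf, cut = NA)
  for (i in seq_len(length(ss) - 1)) {
    cut <- (ss[i] + ss[i + 1]) / 2
    low <- scores <= cut
    m <- sum(low)
    if (m < ceiling(minprop * n) || (n - m) < ceiling(minprop * n)) next
    stat <- abs(sum(a[low])) / sqrt(m * (n - m) / (n * (n - 1)) * va)
    if (stat > best$stat) best <- list(stat = stat, cut = cut)
  }
  best
}

# two-group log-rank chi-square via the O-E ledger over event times
oracle_logrank_chisq <- function(time, event, group) {
  g1 <- group == unique(group)[1]
  oe <- 0; v <- 0
  for (u in sort(unique(time[event == 1]))) {
    at <- time >= u
    n_at <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == u & event == 1)
    d1 <- sum(time == u & event == 1 & g1)
    oe <- oe + d1 - d * n1 / n_at
    if (n_at > 1) {
      v <- v + d * (n1 / n_at) * (1 - n1 / n_at) * (n_at - d) / (n_at - 1)
    }
  }
  if (v == 0) 0 else oe^2 / v
}

# exponential-rate hazard ratio between top and bottom score terciles
empirical_tercile_hr <- function(score, time, event) {
  qs <- quantile(score, c(1 / 3, 2 / 3))
  top <- score >= qs[2]; bot <- score <= qs[1]
  (sum(event[top]) / sum(time[top])) / (sum(event[bot]) / sum(time[bot]))
}

# adjusted Rand index, written out so the recovery checks do not depend on
# an external clustering package
local_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

small_surv <- function(n, seed = 1, rate = 0.01, censor = 0.004) {
  set.seed(seed)
  t_ev <- rexp(n, rate)
  t_c <- rexp(n, censor)
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             time_days = pmin(t_ev, t_c),
             event = as.integer(t_ev <= t_c))
}
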