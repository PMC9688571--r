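test_that("patient scores are the proportion-weighted cluster pseudotimes", {
  w <- matrix(c(1, 0, 0.25, 0.75), 2, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("1", "2")))
  tau <- c(`1` = 2, `2` = 9)
  sc <- patient_pseudotime_score(w, tau)
  expect_equal(sc$score, c(2, 0.25 * 2 + 0.75 * 9))
  expect_equal(patient_pseudotime_score(w, c(`1` = 4, `2` = 8))$score[2], 7)

  # convexity: constant cluster pseudotime gives constant scores
  expect_equal(patient_pseudotime_score(w, c(`1` = 5, `2` = 5))$score,
               c(5, 5))
  expect_error(patient_pseudotime_score(w, c(`1` = 5)), "cluster")

  # affine equivariance: shifting all cluster means shifts all scores
  shifted <- patient_pseudotime_score(w, tau + 3.5)
  expect_equal(shifted$score, sc$score + 3.5)
})

test_that("median dichotomization matches the sort-and-split rule", {
  surv <- data.frame(sample_id = paste0("s", 1:10), time_days = 1:10,
                     event = 1L)
  g <- dichotomize_by_survival(surv)
  expect_equal(sum(g == "good"), 5)
  expect_equal(unname(g[surv$time_days > 5.5]), rep("good", 5))

  two <- data.frame(sample_id = c("a", "b"), time_days = c(3, 9), event = 1L)
  expect_equal(unname(dichotomize_by_survival(two)), c("poor", "good"))
  expect_error(dichotomize_by_survival(
    data.frame(sample_id = letters[1:4], time_days = rep(5, 4), event = 1L)),
    "equal")

  set.seed(1)
  for (i in 1:50) {
    s <- data.frame(sample_id = paste0("s", 1:21),
                    time_days = sample(1000, 21), event = 1L)
    g <- dichotomize_by_survival(s)
    expect_equal(unname(g), ifelse(s$time_days >= sort(s$time_days)[11],
                                   "good", "poor"))
  }
})

test_that("cluster content comparison matches the rank-sum oracle", {
  set.seed(2)
  # identical group distributions: p near 1
  w <- matrix(rep(c(0.2, 0.8), each = 8), 8, 2,
              dimnames = list(paste0("s", 1:8), c("1", "2")))
  grp <- rep(c("good", "poor"), 4)
  expect_warning(res <- compare_cluster_content(w, grp), "constant")
  expect_true(all(res$p == 1))

  for (i in 1:50) {
    n <- 14
    w <- matrix(abs(rnorm(n * 3)), n, 3,
                dimnames = list(paste0("s", 1:n), as.character(1:3)))
    w <- w / rowSums(w)
    grp <- rep(c("a", "b"), each = 7)
    res <- compare_cluster_content(w, grp)
    for (cl in 1:3) {
      expect_equal(res$p[cl], oracle_ranksum_p(w[grp == "a", cl],
                                               w[grp == "b", cl]),
                   tolerance = 1e-12)
    }
  }
  expect_error(compare_cluster_content(w, rep("a", n)), "two")
})

test_that("a planted content shift is detected with adequate power", {
  set.seed(3)
  flagged <- 0
  for (i in 1:30) {
    n <- 80
    w <- matrix(rgamma(n * 5, 2), n, 5)
    grp <- rep(c("good", "poor"), each = 40)
    w[grp == "poor", 3] <- w[grp == "poor", 3] + rowSums(w[grp == "poor", ]) * 0.25
    w <- w / rowSums(w)
    dimnames(w) <- list(paste0("s", 1:n), as.character(1:5))
    res <- compare_cluster_content(w, grp)
    flagged <- flagged + res$significant[res$cluster == "3"]
  }
  expect_gte(flagged / 30, 0.9)
})

test_that("log-rank statistic matches the hand-worked O-E ledger", {
  surv <- data.frame(sample_id = paste0("s", 1:6),
                     time_days = 1:6, event = 1L)
  grp <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(surv, grp)
  expect_equal(lr$statistic, oracle_logrank_chisq(surv$time_days, surv$event,
                                                  grp),
               tolerance = 1e-9)
  # ledger by hand: O-E = 1.85, V = 0.6775 -> chi-square 5.0517
  expect_equal(lr$statistic, 1.85^2 / 0.6775, tolerance = 1e-6)

  # identical survival in both groups: statistic 0, p 1
  same <- data.frame(sample_id = paste0("s", 1:8),
                     time_days = rep(c(2, 5, 7, 9), 2), event = 1L)
  lr0 <- logrank_test(same, rep(c("A", "B"), each = 4))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-9)

  # symmetry under label swap
  s2 <- small_surv(40, seed = 4)
  g2 <- rep(c("x", "y"), 20)
  expect_equal(logrank_test(s2, g2)$statistic,
               logrank_test(s2, ifelse(g2 == "x", "y", "x"))$statistic)
  expect_warning(logrank_test(data.frame(sample_id = 1:4,
                                         time_days = c(1, 2, 3, 4),
                                         event = c(1, 1, 0, 0)),
                              c("A", "A", "B", "B")),
                 "zero events")
})

test_that("log-rank type-I error is near nominal", {
  set.seed(5)
  rej <- 0
  n_sim <- 400
  for (i in 1:n_sim) {
    s <- small_surv(60, seed = 1000 + i)
    p <- logrank_test(s, rep(c("a", "b"), 30))$p
    rej <- rej + (p < 0.05)
  }
  expect_lt(abs(rej / n_sim - 0.05), 0.03)
})

test_that("Kaplan-Meier curves match the product-limit oracle", {
  # no events: flat at 1
  s0 <- data.frame(sample_id = 1:5, time_days = 1:5, event = 0L)
  expect_true(all(km_curve(s0)$surv == 1))

  # two subjects, events at 1 and 2: steps to 0.5 then 0
  s2 <- data.frame(sample_id = 1:2, time_days = c(1, 2), event = 1L)
  expect_equal(km_curve(s2)$surv, c(0.5, 0))

  set.seed(6)
  for (i in 1:30) {
    s <- small_surv(25, seed = 2000 + i)
    km <- km_curve(s)
    for (r in seq_len(nrow(km))) {
      expect_equal(km$surv[r],
                   oracle_km_at(s$time_days, s$event, km$time[r]),
                   tolerance = 1e-12)
    }
  }
})

test_that("optimal cutpoint separates a separable score cleanly", {
  set.seed(7)
  n <- 40
  score <- c(runif(20, 0, 1), runif(20, 4, 5))
  t_ev <- c(rexp(20, 0.001), rexp(20, 0.02)) # high scores die early
  surv <- data.frame(sample_id = paste0("s", 1:n), time_days = t_ev,
                     event = 1L)
  cut <- optimal_cutpoint(score, surv)
  expect_gt(cut$cutpoint, 1)
  expect_lt(cut$cutpoint, 4)
  expect_lt(cut$p, 0.001)
  expect_equal(unname(cut$groups[score > 4]), rep("high", 20))
})

test_that("cutpoint scan equals the brute-force oracle", {
  set.seed(8)
  for (i in 1:100) {
    n <- sample(12:30, 1)
    s <- small_surv(n, seed = 3000 + i)
    score <- rnorm(n)
    cut <- suppressWarnings(optimal_cutpoint(score, s))
    orc <- oracle_cutpoint(score, s$time_days, s$event)
    expect_equal(cut$statistic, orc$stat, tolerance = 1e-9)
    expect_equal(cut$cutpoint, orc$cut, tolerance = 1e-9)
  }
})

test_that("selected statistic dominates the median-split statistic", {
  set.seed(9)
  for (i in 1:20) {
    n <- 30
    s <- small_surv(n, seed = 4000 + i)
    score <- rnorm(n)
    cut <- optimal_cutpoint(score, s)
    a <- oracle_logrank_scores(s$time_days, s$event)
    med <- median(score)
    low <- score <= med
    m <- sum(low)
    med_stat <- abs(sum(a[low])) /
      sqrt(m * (n - m) / (n * (n - 1)) * sum(a^2))
    expect_gte(cut$statistic, med_stat - 1e-9)
  }
  expect_error(optimal_cutpoint(rnorm(5), small_surv(5)), "at least 10")
})
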