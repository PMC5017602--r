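# Native Kaplan-Meier, log-rank and Fisher exact implementations, checked
# against hand calculations, brute-force oracles and the survival package.

test_that("KM with no censoring equals the empirical survival function", {
  km <- km_estimate(c(1, 2, 3, 4), rep(TRUE, 4))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_identical(km$at_risk, c(4L, 3L, 2L, 1L))

  set.seed(3)
  t <- sample(1:8, 30, replace = TRUE)  # ties on purpose
  km2 <- km_estimate(t, rep(TRUE, 30))
  ecdf_surv <- vapply(km2$event_times, function(x) mean(t > x), numeric(1))
  expect_equal(km2$survival, ecdf_surv)
})

test_that("all-censored input gives survival identically 1", {
  km <- km_estimate(c(2, 5, 9), rep(FALSE, 3))
  expect_length(km$event_times, 0L)
  expect_identical(km$n_total, 3L)
})

test_that("censoring reduces the risk set only: {1, 2+, 3} hand oracle", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km$event_times, c(1, 3))
  # S(1) = 2/3; at t=3 only one at risk, who dies: S(3) = 2/3 * 0 = 0
  expect_equal(km$survival, c(2/3, 0))
  or <- oracle_km(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km$survival, or$survival)
})

test_that("KM matches survival::survfit on random censored data", {
  skip_if_not_installed("survival")
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    t <- round(rexp(n, 0.1), 1)
    e <- runif(n) < 0.7
    if (!any(e)) next
    km <- km_estimate(t, e)
    sf <- survival::survfit(survival::Surv(t, e) ~ 1)
    ref <- summary(sf, times = km$event_times)
    expect_equal(km$survival, ref$surv, tolerance = 1e-12)
    expect_equal(as.numeric(km$at_risk), as.numeric(ref$n.risk))
  }
})

test_that("log-rank on identical groups is exactly null", {
  g <- list(times = c(1, 3, 5, 7), events = c(TRUE, TRUE, FALSE, TRUE))
  res <- logrank_test(list(g, g))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_identical(res$df, 1L)
})

test_that("log-rank statistic and p match survival::survdiff", {
  skip_if_not_installed("survival")
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(2:3, 1)
    n <- 25 * k
    t <- round(rexp(n, rep(c(0.05, 0.12, 0.08)[seq_len(k)], each = 25)), 1)
    e <- runif(n) < 0.8
    grp <- rep(seq_len(k), each = 25)
    groups <- lapply(seq_len(k), function(j)
      list(times = t[grp == j], events = e[grp == j]))
    res <- logrank_test(groups)
    sd <- survival::survdiff(survival::Surv(t, e) ~ grp)
    expect_equal(res$statistic, sd$chisq, tolerance = 1e-8)
    expect_equal(res$p, stats::pchisq(sd$chisq, k - 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("log-rank is invariant under swapping the two group labels", {
  g1 <- list(times = c(2, 4, 6, 9), events = c(TRUE, TRUE, FALSE, TRUE))
  g2 <- list(times = c(1, 3, 8, 10), events = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(logrank_test(list(g1, g2))$statistic,
               logrank_test(list(g2, g1))$statistic)
})

test_that("separated small samples agree with exhaustive label permutation", {
  # groups {1,2,3} vs {10,11,12}, all events: the observed labeling is the
  # most extreme of all C(6,3) = 20 relabelings
  t <- c(1, 2, 3, 10, 11, 12)
  e <- rep(TRUE, 6)
  obs <- logrank_test(list(list(times = t[1:3], events = e[1:3]),
                           list(times = t[4:6], events = e[4:6])))
  combs <- utils::combn(6, 3)
  perm_stats <- apply(combs, 2, function(idx) {
    logrank_test(list(list(times = t[idx], events = e[idx]),
                      list(times = t[-idx], events = e[-idx])))$statistic
  })
  expect_equal(max(perm_stats), obs$statistic, tolerance = 1e-10)
  # permutation tail probability: only the two extreme labelings reach it
  expect_equal(mean(perm_stats >= obs$statistic - 1e-10), 2 / 20)
})

test_that("log-rank error contracts hold", {
  g <- list(times = c(1, 2), events = c(FALSE, FALSE))
  expect_error(logrank_test(list(g)), ">= 2 groups")
  expect_error(logrank_test(list(g, g)), "no events")
  expect_error(logrank_test(list(g, list(times = numeric(), events = logical()))),
               "empty group")
})

test_that("Fisher 2x2 equals hand cases, the enumeration oracle and fisher.test", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2, byrow = TRUE)), 1)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 7), 2, byrow = TRUE)), 1)

  tab <- matrix(c(1, 9, 11, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab), oracle_fisher_2x2(tab), tolerance = 1e-12)
  expect_equal(fisher_exact(tab), stats::fisher.test(tab)$p.value, tolerance = 1e-9)

  set.seed(10)
  for (i in 1:25) {
    x <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact(x), stats::fisher.test(x)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "negative")
})

test_that("Freeman-Halton 2xk enumeration matches fisher.test", {
  set.seed(11)
  for (k in c(3, 4)) {
    for (i in 1:10) {
      x <- matrix(rpois(2 * k, 4), 2)
      if (any(colSums(x) == 0) || any(rowSums(x) == 0)) next
      expect_equal(fisher_exact(x), stats::fisher.test(x)$p.value, tolerance = 1e-7)
    }
  }
  # kx2 orientation is transposed transparently
  x <- matrix(c(2, 8, 7, 3, 5, 5, 9, 1), 4, 2, byrow = TRUE)
  expect_equal(fisher_exact(x), stats::fisher.test(x)$p.value, tolerance = 1e-7)
})

test_that("cluster-wise outcome comparison separates planted outcome models", {
  spec <- cohort_spec(seed = 0L)
  asg <- data.frame(sample_id = sprintf("p%03d", 1:200),
                    cluster = rep(1:4, each = 50), stringsAsFactors = FALSE)
  oc <- simulate_outcomes(asg, spec)
  report <- compare_clusters(asg, oc)
  expect_lte(report$mrd$cluster1_vs_rest_p, 0.05)
  expect_identical(dim(report$mrd$table), c(4L, 2L))
  expect_identical(sum(report$mrd$table), 200L)
  expect_length(report$mrd$pairwise_p, 3L)
  expect_s3_class(report$efs$omnibus, "logrank_result")
  expect_length(report$efs$pairwise, 6L)
  # cluster 1 has the mildest event hazard: best 5-year event-free survival
  surv_at <- function(cv, t) {
    i <- which(cv$event_times <= t)
    if (length(i)) cv$survival[max(i)] else 1
  }
  s5 <- vapply(report$efs$curves, surv_at, numeric(1), t = 5 * 365)
  expect_identical(names(which.max(s5)), "cluster1")
  expect_gt(s5[["cluster1"]], s5[["cluster3"]])

  out <- withr::local_tempfile(fileext = ".tsv")
  write_km_curves(report, out)
  tab <- utils::read.delim(out)
  expect_true(all(c("endpoint", "group", "time", "survival", "at_risk") %in% names(tab)))

  one <- asg[asg$cluster == 1, ]
  expect_error(compare_clusters(one, oc), ">= 2 clusters")
})

test_that("samples missing an outcome are excluded with a message", {
  spec <- cohort_spec(seed = 3L)
  asg <- data.frame(sample_id = sprintf("p%03d", 1:80),
                    cluster = rep(1:4, each = 20), stringsAsFactors = FALSE)
  oc <- simulate_outcomes(asg, spec)
  oc$mrd29_positive[1:5] <- NA
  expect_message(report <- compare_clusters(asg, oc), "5 sample")
  expect_identical(sum(report$mrd$table), 75L)
})
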