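# Natively implemented survival and contingency statistics for cluster-wise
# outcome comparison: Kaplan-Meier product-limit estimation, k-sample
# log-rank test with hypergeometric (tie-corrected) variance, and Fisher's
# exact test (2x2 hypergeometric tail, 2xk Freeman-Halton enumeration).

#' Kaplan-Meier product-limit survival estimate
#'
#' Censored observations reduce the risk set only; a censoring time equal to
#' an event time is processed after the event (the standard convention), so
#' such samples still count as at risk for that event.
#'
#' @param times nonnegative follow-up times.
#' @param events logical event indicators (`FALSE` = censored).
#' @return a `survival_curve`: list with `event_times` (distinct times with
#'   at least one event, increasing), `survival` (product-limit estimate at
#'   each event time), `at_risk` (risk-set size just before each event
#'   time), `n_events` (deaths at each event time) and `n_total`.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  stopifnot(length(times) == length(events))
  if (anyNA(times) || anyNA(events)) stop("NA in survival input")
  if (any(times < 0)) stop("negative survival time")
  events <- as.logical(events)
  ev_times <- sort(unique(times[events]))
  at_risk <- vapply(ev_times, function(t) sum(times >= t), integer(1L))
  n_events <- vapply(ev_times, function(t) sum(times == t & events), integer(1L))
  surv <- cumprod(1 - n_events / at_risk)
  structure(list(event_times = ev_times, survival = surv, at_risk = at_risk,
                 n_events = n_events, n_total = length(times)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("survival_curve: n = ", x$n_total, ", ", sum(x$n_events), " events at ",
      length(x$event_times), " distinct times\n", sep = "")
  invisible(x)
}

# Moore-Penrose pseudoinverse via SVD (for a singular log-rank covariance).
.pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 1)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' k-sample log-rank test
#'
#' At every distinct event time the observed group-wise deaths are compared
#' with their expectation under the pooled risk set, using the multivariate
#' hypergeometric variance (which corrects for tied deaths). The statistic
#' is the quadratic form over the first k-1 groups and is referred to a
#' chi-square with k-1 degrees of freedom.
#'
#' @param groups list with one element per group, each a list (or
#'   data.frame) with components `times` and `events`.
#' @return a `logrank_result`: list with `statistic`, `df`, `p`, `observed`
#'   and `expected` per group.
#' @export
logrank_test <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  k <- length(groups)
  for (g in groups) if (!length(g$times)) stop("empty group in log-rank test")
  times <- unlist(lapply(groups, `[[`, "times"))
  events <- as.logical(unlist(lapply(groups, `[[`, "events")))
  grp <- rep(seq_len(k), vapply(groups, function(g) length(g$times), integer(1L)))
  if (!any(events)) stop("no events in any group")

  ev_times <- sort(unique(times[events]))
  O <- numeric(k); E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    nj <- vapply(seq_len(k), function(j) sum(at_risk & grp == j), numeric(1L))
    dj <- vapply(seq_len(k), function(j) sum(times == t & events & grp == j), numeric(1L))
    d <- sum(dj)
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      c_t <- d * (n - d) / (n - 1)
      V <- V + c_t * (diag(nj / n, k) - tcrossprod(nj / n))
    }
  }
  idx <- seq_len(k - 1L)
  u <- (O - E)[idx]
  Vsub <- V[idx, idx, drop = FALSE]
  Vinv <- tryCatch(solve(Vsub), error = function(e) .pinv(Vsub))
  stat <- drop(t(u) %*% Vinv %*% u)
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = k - 1L,
                 p = stats::pchisq(stat, df = k - 1L, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("log-rank: chi-square = ", signif(x$statistic, 4), " on ", x$df,
      " df, p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Fisher's exact test for 2x2 and 2xk tables
#'
#' Two-sided p by probability-mass ordering: the sum of probabilities of all
#' tables with the observed margins whose point probability does not exceed
#' the observed one (within a 1e-7 relative tolerance, as is conventional).
#' 2x2 tables use the hypergeometric distribution directly; 2xk tables
#' (k <= 4) are handled by exhaustive Freeman-Halton enumeration over the
#' fixed margins.
#'
#' @param table nonnegative integer matrix of counts, 2 rows (or 2 columns:
#'   a kx2 table is transposed).
#' @return two-sided exact p-value.
#' @export
fisher_exact <- function(table) {
  x <- as.matrix(table)
  if (any(x < 0)) stop("negative count in contingency table")
  if (any(x != round(x))) stop("non-integer count in contingency table")
  if (nrow(x) != 2L && ncol(x) == 2L) x <- t(x)
  if (nrow(x) != 2L) stop("table must be 2xk (or kx2)")
  if (ncol(x) > 4L) stop("Freeman-Halton enumeration supports k <= 4 columns")
  if (sum(x) == 0L) stop("empty contingency table")
  r1 <- sum(x[1L, ]); N <- sum(x)
  cs <- colSums(x)
  # degenerate margins admit a single table
  if (r1 == 0L || r1 == N || sum(cs > 0) == 1L) return(1)

  if (ncol(x) == 2L) {
    support <- max(0L, r1 - cs[2L]):min(r1, cs[1L])
    probs <- stats::dhyper(support, cs[1L], cs[2L], r1)
    p_obs <- stats::dhyper(x[1L, 1L], cs[1L], cs[2L], r1)
    return(min(1, sum(probs[probs <= p_obs * (1 + 1e-7)])))
  }

  # Freeman-Halton: enumerate top-row fills of the first k-1 columns; the
  # last column is determined by the row margin
  k <- ncol(x)
  grids <- lapply(cs[-k], function(cj) 0:cj)
  combos <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  last <- r1 - rowSums(combos)
  ok <- last >= 0 & last <= cs[k]
  combos <- cbind(combos[ok, , drop = FALSE], last[ok])
  # log P(table) = sum_j log C(c_j, x_1j) - log C(N, r1)
  lp <- -lchoose(N, r1)
  logp <- rowSums(matrix(lchoose(rep(cs, each = nrow(combos)), combos),
                         nrow = nrow(combos))) + lp
  logp_obs <- sum(lchoose(cs, x[1L, ])) + lp
  min(1, sum(exp(logp[logp <= logp_obs + 1e-7])))
}

#' Cluster-wise outcome comparison
#'
#' Builds the clusters x MRD29 contingency table with the overall Fisher
#' exact p and Cluster-1-versus-each/rest 2x2 p-values, and Kaplan-Meier
#' curves with omnibus and pairwise log-rank tests for event-free and
#' overall survival. Samples missing an outcome are excluded from that
#' analysis (a message reports how many).
#'
#' @param assignment a `cluster_assignment` from [assign_clusters()].
#' @param outcomes data.frame with `sample_id` and outcome columns
#'   (`mrd29_positive`, `efs_time`/`efs_event`, `os_time`/`os_event`), e.g.
#'   from [simulate_outcomes()] or [read_annotations()].
#' @return a `cluster_outcome_report`: list with elements `mrd` (table,
#'   overall p, pairwise and cluster-1-vs-rest p) and `efs`/`os` (KM curves
#'   per cluster, omnibus and pairwise log-rank results).
#' @export
compare_clusters <- function(assignment, outcomes) {
  df <- merge(as.data.frame(assignment)[, c("sample_id", "cluster")], outcomes,
              by = "sample_id")
  clusters <- sort(unique(df$cluster))
  if (length(clusters) < 2L) stop("need >= 2 clusters with outcome data")
  report <- list(clusters = clusters,
                 n_per_cluster = table(factor(df$cluster, levels = clusters)))

  if ("mrd29_positive" %in% names(df)) {
    sub <- df[!is.na(df$mrd29_positive), ]
    if (nrow(sub) < nrow(df))
      message(nrow(df) - nrow(sub), " sample(s) without MRD29 excluded")
    tab <- t(vapply(clusters, function(cl) {
      c(positive = sum(sub$cluster == cl & sub$mrd29_positive),
        negative = sum(sub$cluster == cl & !sub$mrd29_positive))
    }, integer(2L)))
    rownames(tab) <- paste0("cluster", clusters)
    c1 <- which(clusters == 1L)
    pairwise <- if (length(c1)) {
      others <- setdiff(seq_along(clusters), c1)
      stats::setNames(vapply(others, function(j)
        fisher_exact(tab[c(c1, j), , drop = FALSE]), numeric(1L)),
        paste0("cluster1_vs_cluster", clusters[others]))
    } else NULL
    c1_vs_rest <- if (length(c1))
      fisher_exact(rbind(tab[c1, ], colSums(tab[-c1, , drop = FALSE]))) else NA_real_
    report$mrd <- list(table = tab, overall_p = fisher_exact(tab),
                       pairwise_p = pairwise, cluster1_vs_rest_p = c1_vs_rest,
                       positive_fraction = tab[, "positive"] / rowSums(tab))
  }

  for (ep in c("efs", "os")) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    if (!all(c(tcol, ecol) %in% names(df))) next
    sub <- df[!is.na(df[[tcol]]), ]
    if (nrow(sub) < nrow(df))
      message(nrow(df) - nrow(sub), " sample(s) without ", ep, " outcome excluded")
    grps <- lapply(clusters, function(cl) {
      s <- sub[sub$cluster == cl, ]
      list(times = s[[tcol]], events = as.logical(s[[ecol]]))
    })
    names(grps) <- paste0("cluster", clusters)
    nonempty <- vapply(grps, function(g) length(g$times) > 0L, logical(1L))
    curves <- lapply(grps[nonempty], function(g) km_estimate(g$times, g$events))
    omnibus <- tryCatch(logrank_test(grps[nonempty]), error = function(e) NULL)
    pairs <- utils::combn(which(nonempty), 2L, simplify = FALSE)
    pairwise <- stats::setNames(
      lapply(pairs, function(ij) tryCatch(logrank_test(grps[ij]),
                                          error = function(e) NULL)),
      vapply(pairs, function(ij) paste(names(grps)[ij], collapse = "_vs_"), character(1L)))
    report[[ep]] <- list(curves = curves, omnibus = omnibus, pairwise = pairwise)
  }
  structure(report, class = "cluster_outcome_report")
}

#' @export
print.cluster_outcome_report <- function(x, ...) {
  cat("cluster_outcome_report over clusters ",
      paste(x$clusters, collapse = ", "), "\n", sep = "")
  if (!is.null(x$mrd)) {
    cat("  MRD29 positive fraction: ",
        paste(sprintf("%s %.2f", rownames(x$mrd$table), x$mrd$positive_fraction),
              collapse = ", "), "\n",
        "  MRD29 overall Fisher p = ", signif(x$mrd$overall_p, 4),
        "; cluster 1 vs rest p = ", signif(x$mrd$cluster1_vs_rest_p, 4), "\n", sep = "")
  }
  for (ep in c("efs", "os")) {
    if (is.null(x[[ep]])) next
    cat("  ", toupper(ep), " omnibus log-rank p = ",
        if (is.null(x[[ep]]$omnibus)) "NA" else signif(x[[ep]]$omnibus$p, 4),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write Kaplan-Meier curves of a report as TSV
#'
#' One row per (endpoint, cluster, event time) with survival and risk-set
#' size.
#'
#' @param report a `cluster_outcome_report`.
#' @param path output path.
#' @param comment optional `#` comment line.
#' @export
write_km_curves <- function(report, path, comment = NULL) {
  rows <- list()
  for (ep in c("efs", "os")) {
    if (is.null(report[[ep]])) next
    for (nm in names(report[[ep]]$curves)) {
      cv <- report[[ep]]$curves[[nm]]
      if (!length(cv$event_times)) next
      rows[[paste(ep, nm)]] <- data.frame(endpoint = ep, group = nm,
                                          time = cv$event_times,
                                          survival = cv$survival,
                                          at_risk = cv$at_risk,
                                          stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(endpoint = character(), group = character(), time = numeric(),
               survival = numeric(), at_risk = integer())
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
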