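# Independent brute-force oracles used to validate the native
# implementations. These deliberately use naive stepwise logic, not the
# package's vectorised code paths.

# Stepwise weight-0 running-sum walk: +1/k at a hit, -1/(N-k) at a miss;
# returns the value of maximal absolute deviation (first such step).
# Steps are scaled by k*(N-k) so the walk is exact integer arithmetic and
# ties resolve without floating-point ambiguity.
oracle_es_walk <- function(hit) {
  N <- length(hit)
  k <- sum(hit)
  run <- 0L
  best <- 0L
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) (N - k) else -k
    if (abs(run) > abs(best)) best <- run
  }
  best / (k * (N - k))
}

# Welch t for one gene via stats::t.test (oracle for the vectorised ranker).
oracle_welch_t <- function(x_target, x_rest) {
  unname(stats::t.test(x_target, x_rest, var.equal = FALSE)$statistic)
}

# Product-limit estimate by explicit sequential multiplication.
oracle_km <- function(times, events) {
  ev <- sort(unique(times[events]))
  s <- 1
  out <- numeric(length(ev))
  for (i in seq_along(ev)) {
    n_at_risk <- sum(times >= ev[i])
    d <- sum(times == ev[i] & events)
    s <- s * (1 - d / n_at_risk)
    out[i] <- s
  }
  list(event_times = ev, survival = out)
}

# Two-sided Fisher p for a 2x2 table by full enumeration over the fixed
# margins, with table probabilities from the factorial formula.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  N <- r1 + r2
  logp <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    if (b < 0 || c < 0 || d < 0) return(-Inf)
    (lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(c2 + 1)) -
      (lgamma(N + 1) + lgamma(a + 1) + lgamma(b + 1) + lgamma(c + 1) + lgamma(d + 1))
  }
  lp_all <- vapply(0:min(r1, c1), logp, numeric(1))
  lp_obs <- logp(tab[1, 1])
  sum(exp(lp_all[lp_all <= lp_obs + 1e-7]))
}

# Small two-group expression fixture: n1 target + n2 rest samples,
# `shifted` genes up-shifted by delta in the target group.
make_two_group_matrix <- function(n_genes = 100, n1 = 10, n2 = 10,
                                  shifted = 10, delta = 2, sd = 1,
                                  baseline = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n_genes * (n1 + n2), baseline, sd), nrow = n_genes)
    if (shifted > 0) X[seq_len(shifted), seq_len(n1)] <- X[seq_len(shifted), seq_len(n1)] + delta
    rownames(X) <- sprintf("g%03d", seq_len(n_genes))
    colnames(X) <- sprintf("s%02d", seq_len(n1 + n2))
    ann <- data.frame(sample_id = colnames(X),
                      group = rep(c("target", "rest"), c(n1, n2)),
                      stringsAsFactors = FALSE)
    list(matrix = X, annotations = ann,
         shifted_genes = rownames(X)[seq_len(shifted)])
  })
}
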