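# Native rank-based gene-set enrichment: running-sum enrichment score (ES),
# normalized enrichment score (NES) and permutation p-value. The walk
# increases at gene-set members and decreases otherwise; weight 0 gives the
# classic equal-step Kolmogorov-Smirnov form, weight 1 the stat-weighted one.

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Full running-sum walk. hit: logical over the ranked universe; w: per-gene
# step weights (|statistic|^weight). Returns es, the running sum and the
# walk index of the extremum (first index of maximal |deviation|).
.es_walk <- function(hit, w) {
  N <- length(hit)
  k <- sum(hit)
  wh <- sum(w[hit])
  if (wh == 0) w[hit] <- 1  # all-zero weights degenerate to equal steps
  inc <- rep(-1 / (N - k), N)
  inc[hit] <- w[hit] / sum(w[hit])
  run <- cumsum(inc)
  # first index attaining the maximal |deviation|; 1e-12 tolerance so that
  # accumulated rounding cannot flip a mathematically exact tie
  idx <- which(abs(run) >= max(abs(run)) - 1e-12)[1L]
  list(es = run[idx], running_sum = run, extremum = idx)
}

# Fast weight-0 ES from the sorted ranks of the set genes (pos) in a
# universe of N. Candidate extrema sit immediately before/after each hit;
# ties on |deviation| resolve to the earliest walk index, matching
# which.max() over the full running sum.
.es_weight0 <- function(pos, N) {
  k <- length(pos)
  hs <- 1 / k
  ms <- 1 / (N - k)
  i <- seq_len(k)
  after <- i * hs - (pos - i) * ms       # value at walk index pos[i]
  before <- after - hs                   # value at walk index pos[i] - 1
  ok <- pos > 1L
  val <- c(after, before[ok])
  idx <- c(pos, pos[ok] - 1L)
  keep <- abs(val) >= max(abs(val)) - 1e-12
  val[keep][which.min(idx[keep])]
}

#' Running-sum enrichment score of a gene set in a ranked list
#'
#' Walks the ranked gene list from top to bottom, stepping up at gene-set
#' members and down otherwise. With `weight = 0` every member contributes an
#' equal step `1/|S|`; with `weight > 0` members step by
#' `|statistic|^weight / sum(|statistic|^weight)`. Non-members always step
#' down by `1/(N - |S|)`. The enrichment score is the running-sum value of
#' maximal absolute deviation; the leading edge is the set genes at or
#' before the extremum (at or after it, for a negative score).
#'
#' @param ranked a `ranked_list` from [rank_genes()] (or any data.frame with
#'   `gene_id` and `statistic` sorted descending).
#' @param gene_set a [gene_signature] or character vector of gene ids.
#' @param weight exponent on `|statistic|` for member steps (default 0).
#' @return list with `es`, `running_sum` (length = universe) and
#'   `leading_edge` (character vector).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 0) {
  genes <- if (inherits(gene_set, "gene_signature")) gene_set$genes else as.character(gene_set)
  hit <- ranked$gene_id %in% genes
  k <- sum(hit)
  N <- length(hit)
  if (k == 0L) stop("no overlap between gene set and ranked universe")
  if (k == N) stop("gene set covers the whole universe; miss step undefined")
  w <- abs(ranked$statistic)^weight
  walk <- .es_walk(hit, w)
  le <- if (walk$es >= 0) ranked$gene_id[hit & seq_len(N) <= walk$extremum]
        else ranked$gene_id[hit & seq_len(N) >= walk$extremum]
  list(es = walk$es, running_sum = walk$running_sum, leading_edge = le)
}

# Batch Welch t statistics for B permuted target indicators.
# X: genes x samples; P: samples x B 0/1 matrix with constant column sum n1.
# Returns list(t = genes x B, mdiff = genes x B).
.welch_t_batch <- function(X, P) {
  n <- ncol(X)
  n1 <- sum(P[, 1L])
  n2 <- n - n1
  S1 <- X %*% P
  SS1 <- (X * X) %*% P
  tot <- rowSums(X)
  tot2 <- rowSums(X * X)
  m1 <- S1 / n1
  m2 <- (tot - S1) / n2
  v1 <- pmax((SS1 - S1^2 / n1) / (n1 - 1), 0)
  v2 <- pmax(((tot2 - SS1) - (tot - S1)^2 / n2) / (n2 - 1), 0)
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- (m1 - m2) / se
  zero <- se == 0
  if (any(zero)) {
    t[zero] <- sign((m1 - m2)[zero]) * Inf
    t[zero & m1 == m2] <- 0
  }
  list(t = t, mdiff = m1 - m2)
}

# All (or n_perm random) target-subset indicator matrices for phenotype
# permutation of an n1-vs-(n-n1) contrast.
.perm_indicators <- function(n, n1, n_perm, exhaustive) {
  if (exhaustive) {
    combs <- utils::combn(n, n1)
    P <- matrix(0, n, ncol(combs))
    P[cbind(as.vector(combs), rep(seq_len(ncol(combs)), each = n1))] <- 1
  } else {
    P <- matrix(0, n, n_perm)
    for (b in seq_len(n_perm)) P[sample.int(n, n1), b] <- 1
  }
  P
}

# Shared engine: enrichment of several gene sets against one target-vs-rest
# contrast with a common permutation null. Returns a list of
# enrichment_result objects (one per set).
.gsea_contrast <- function(matrix, annotations, target_group, gene_sets,
                           n_perm = 1000L, seed = 0L, weight = 0,
                           mode = c("auto", "phenotype", "gene_label"),
                           exhaustive = FALSE) {
  mode <- match.arg(mode)
  ranked <- rank_genes(matrix, annotations, target_group)
  X <- matrix[, annotations$sample_id, drop = FALSE]
  target <- annotations$group == target_group
  n1 <- sum(target); n2 <- sum(!target)
  if (mode == "auto") mode <- if (min(n1, n2) >= 5L) "phenotype" else "gene_label"
  if (mode == "phenotype" && (n1 < 2L || n2 < 2L)) {
    warning("too few samples for phenotype permutation; falling back to gene_label")
    mode <- "gene_label"
  }

  obs <- lapply(gene_sets, function(s) enrichment_score(ranked, s, weight = weight))
  set_sizes <- vapply(gene_sets, function(s) {
    genes <- if (inherits(s, "gene_signature")) s$genes else s
    sum(ranked$gene_id %in% genes)
  }, integer(1L))

  nulls <- .with_seed(seed, {
    if (mode == "phenotype") {
      P <- .perm_indicators(n1 + n2, n1, n_perm, exhaustive)
      bt <- .welch_t_batch(X, P)
      rn <- rownames(X)
      B <- ncol(P)
      # one ranking per permutation, shared by all gene sets
      ords <- lapply(seq_len(B), function(b)
        order(-bt$t[, b], -bt$mdiff[, b], rn))
      lapply(seq_along(gene_sets), function(j) {
        genes <- if (inherits(gene_sets[[j]], "gene_signature")) gene_sets[[j]]$genes
                 else gene_sets[[j]]
        set_idx <- which(rn %in% genes)
        vapply(seq_len(B), function(b) {
          pos <- sort.int(match(set_idx, ords[[b]]))
          if (weight == 0) .es_weight0(pos, length(rn))
          else {
            hit <- logical(length(rn)); hit[pos] <- TRUE
            .es_walk(hit, abs(bt$t[ords[[b]], b])^weight)$es
          }
        }, numeric(1L))
      })
    } else {
      N <- nrow(ranked)
      lapply(seq_along(gene_sets), function(j) {
        k <- set_sizes[[j]]
        vapply(seq_len(n_perm), function(b) {
          pos <- sort.int(sample.int(N, k))
          if (weight == 0) .es_weight0(pos, N)
          else {
            hit <- logical(N); hit[pos] <- TRUE
            .es_walk(hit, abs(ranked$statistic)^weight)$es
          }
        }, numeric(1L))
      })
    }
  })

  out <- lapply(seq_along(gene_sets), function(j) {
    s <- gene_sets[[j]]
    nm <- if (inherits(s, "gene_signature")) s$name else paste0("set", j)
    np <- nes_and_p(obs[[j]]$es, nulls[[j]])
    structure(list(
      signature_name = nm,
      contrast = paste0(target_group, "_vs_rest"),
      es = obs[[j]]$es, nes = np$nes, p_perm = np$p_perm,
      n_permutations = length(nulls[[j]]),
      leading_edge = obs[[j]]$leading_edge,
      running_sum = obs[[j]]$running_sum,
      null_es = nulls[[j]], mode = mode, weight = weight, seed = seed
    ), class = "enrichment_result")
  })
  names(out) <- vapply(out, `[[`, character(1L), "signature_name")
  out
}

#' Permutation null distribution of the enrichment score
#'
#' `phenotype` mode shuffles the target-vs-rest sample labels, re-ranks all
#' genes and re-scores the set for each permutation; `gene_label` mode keeps
#' the observed ranking fixed and scores random gene sets of the same size.
#' With `exhaustive = TRUE` (phenotype mode) all `choose(n, n1)` relabelings
#' are enumerated exactly once instead of sampled.
#'
#' @inheritParams rank_genes
#' @param gene_set a [gene_signature] or character vector of gene ids.
#' @param n_perm number of permutations (ignored when `exhaustive`).
#' @param seed RNG seed; identical seeds give identical null vectors.
#' @param mode `"phenotype"` or `"gene_label"`; phenotype falls back to
#'   gene_label with a warning when either group has < 2 samples.
#' @param exhaustive enumerate all relabelings (phenotype mode only).
#' @param weight ES weight exponent, as in [enrichment_score()].
#' @return numeric vector of null enrichment scores, with the mode used in
#'   attribute `"mode"`.
#' @export
permutation_null <- function(matrix, annotations, target_group, gene_set,
                             n_perm = 1000L, seed = 0L,
                             mode = c("phenotype", "gene_label"),
                             exhaustive = FALSE, weight = 0) {
  mode <- match.arg(mode)
  res <- .gsea_contrast(matrix, annotations, target_group, list(gene_set),
                        n_perm = n_perm, seed = seed, weight = weight,
                        mode = mode, exhaustive = exhaustive)[[1L]]
  structure(res$null_es, mode = res$mode)
}

#' Normalized enrichment score and permutation p-value
#'
#' The NES divides the observed ES by the mean absolute null ES of the same
#' sign; if no null shares the sign the NES is undefined (`NA`). The
#' p-value uses the add-one (permutation-inclusive) rule on the same-signed
#' nulls, so its floor is `1/(B + 1)` with `B` same-signed nulls.
#'
#' @param es observed enrichment score.
#' @param null_es numeric vector of null enrichment scores (nonempty).
#' @return list with `nes` and `p_perm`.
#' @export
nes_and_p <- function(es, null_es) {
  if (!length(null_es)) stop("empty null distribution")
  same <- if (es >= 0) null_es >= 0 else null_es < 0
  B <- sum(same)
  nes <- if (B == 0L) NA_real_ else es / mean(abs(null_es[same]))
  p <- (1 + sum(same & abs(null_es) >= abs(es))) / (1 + B)
  list(nes = nes, p_perm = p)
}

#' Gene-set enrichment analysis for one contrast
#'
#' Composes [rank_genes()], [enrichment_score()], [permutation_null()] and
#' [nes_and_p()]: ranks genes for `target_group` vs the rest, scores the
#' set, builds a permutation null and reports ES, NES, permutation p and
#' leading edge.
#'
#' @inheritParams permutation_null
#' @param mode `"auto"` (phenotype when both groups have >= 5 samples, else
#'   gene_label), `"phenotype"` or `"gene_label"`.
#' @return an `enrichment_result` object.
#' @export
gsea <- function(matrix, annotations, target_group, gene_set,
                 n_perm = 1000L, seed = 0L, weight = 0,
                 mode = c("auto", "phenotype", "gene_label"),
                 exhaustive = FALSE) {
  mode <- match.arg(mode)
  .gsea_contrast(matrix, annotations, target_group, list(gene_set),
                 n_perm = n_perm, seed = seed, weight = weight,
                 mode = mode, exhaustive = exhaustive)[[1L]]
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result: '", x$signature_name, "' in ", x$contrast, "\n",
      "  ES = ", signif(x$es, 4), ", NES = ", signif(x$nes, 4),
      ", p = ", signif(x$p_perm, 4),
      " (", x$n_permutations, " ", x$mode, " permutations)\n",
      "  leading edge: ", length(x$leading_edge), " genes\n", sep = "")
  invisible(x)
}

#' Write enrichment results as a TSV table
#'
#' @param results an `enrichment_result` or list of them.
#' @param path output path.
#' @param comment optional `#` comment line.
#' @export
write_enrichment_results <- function(results, path, comment = NULL) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(signature = r$signature_name, contrast = r$contrast,
               es = r$es, nes = r$nes, p_perm = r$p_perm,
               n_permutations = r$n_permutations, mode = r$mode,
               seed = r$seed,
               leading_edge = paste(r$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
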