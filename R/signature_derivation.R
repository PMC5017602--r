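# Supervised one-vs-rest gene ranking and top-N "highly expressed"
# signature derivation.

# Vectorised Welch t statistics for target columns vs the rest.
# X: genes x samples matrix; target: logical vector over columns.
# Returns per-gene t (target mean - rest mean, unequal variances).
.welch_t <- function(X, target) {
  n1 <- sum(target); n2 <- sum(!target)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  X1 <- X[, target, drop = FALSE]
  X2 <- X[, !target, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1L)
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- (m1 - m2) / se
  # zero variance in both groups: equal means -> 0; unequal -> signed Inf
  t[se == 0] <- sign(m1 - m2)[se == 0] * Inf
  t[se == 0 & m1 == m2] <- 0
  t
}

# Signal-to-noise ratio ranking statistic (alternative to Welch t).
.snr <- function(X, target) {
  n1 <- sum(target); n2 <- sum(!target)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  X1 <- X[, target, drop = FALSE]
  X2 <- X[, !target, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  s1 <- sqrt(rowSums((X1 - m1)^2) / (n1 - 1L))
  s2 <- sqrt(rowSums((X2 - m2)^2) / (n2 - 1L))
  denom <- s1 + s2
  r <- (m1 - m2) / denom
  r[denom == 0] <- sign(m1 - m2)[denom == 0] * Inf
  r[denom == 0 & m1 == m2] <- 0
  r
}

#' Rank genes for one group versus all remaining samples
#'
#' Computes a per-gene two-group statistic (default: Welch two-sample t,
#' target mean minus rest mean with unequal variances) and sorts genes in
#' strictly non-increasing order. Ties are broken by larger mean difference,
#' then lexicographic gene id, so the ordering is deterministic.
#'
#' @param matrix genes x samples expression matrix (log2 scale).
#' @param annotations data.frame with `sample_id` and `group` columns; every
#'   sample id must be a matrix column.
#' @param target_group group label to contrast against the rest.
#' @param statistic `"welch_t"` (default) or `"snr"` (signal-to-noise ratio).
#' @return a `ranked_list`: data.frame with columns `gene_id` and
#'   `statistic`, sorted descending.
#' @export
rank_genes <- function(matrix, annotations, target_group,
                       statistic = c("welch_t", "snr")) {
  statistic <- match.arg(statistic)
  validate_expression_matrix(matrix)
  validate_annotations(annotations, matrix)
  X <- matrix[, annotations$sample_id, drop = FALSE]
  target <- annotations$group == target_group
  if (!any(target)) stop("no samples with group '", target_group, "'")
  stat <- switch(statistic, welch_t = .welch_t(X, target), snr = .snr(X, target))

  mdiff <- rowMeans(X[, target, drop = FALSE]) - rowMeans(X[, !target, drop = FALSE])
  ord <- order(-stat, -mdiff, rownames(X))
  res <- data.frame(gene_id = rownames(X)[ord], statistic = stat[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("ranked_list", "data.frame")
  attr(res, "target_group") <- target_group
  attr(res, "statistic_name") <- statistic
  res
}

#' Take the top-N up-regulated genes of a ranked list
#'
#' Genes with statistic <= 0 are excluded: a "highly expressed" signature
#' must be up-regulated in its group. Fewer than `n` genes may be returned
#' (with a warning) when the ranked list has fewer positive statistics.
#'
#' @param ranked a `ranked_list` from [rank_genes()].
#' @param n number of genes requested (default 400).
#' @param name signature name; defaults to `<source_group>_top<n>`.
#' @param source_group group label recorded on the signature.
#' @return a [gene_signature].
#' @export
derive_signature <- function(ranked, n = 400L,
                             name = NULL, source_group = NA_character_) {
  stopifnot(n >= 1L)
  if (is.null(name)) {
    sg <- if (!is.na(source_group)) source_group else attr(ranked, "target_group")
    name <- paste0(if (is.null(sg) || is.na(sg)) "signature" else sg, "_top", n)
  }
  if (is.na(source_group) && !is.null(attr(ranked, "target_group")))
    source_group <- attr(ranked, "target_group")
  pos <- ranked$gene_id[ranked$statistic > 0]
  if (length(pos) < n)
    warning("only ", length(pos), " genes with positive statistic; signature '",
            name, "' shorter than requested n = ", n)
  gene_signature(name, utils::head(pos, n), source_group = source_group,
                 n_requested = n)
}

#' Derive one top-N signature per group label
#'
#' @inheritParams rank_genes
#' @param n top-N per signature (default 400).
#' @return named list of [gene_signature] objects, one per distinct group.
#' @export
derive_all_group_signatures <- function(matrix, annotations, n = 400L,
                                        statistic = "welch_t") {
  groups <- sort(unique(annotations$group))
  if (length(groups) < 2L)
    stop("need >= 2 distinct groups to derive one-vs-rest signatures")
  sigs <- lapply(groups, function(g) {
    derive_signature(rank_genes(matrix, annotations, g, statistic = statistic),
                     n = n, name = g, source_group = g)
  })
  names(sigs) <- groups
  sigs
}

#' Write a ranked list in .rnk format (gene_id <tab> statistic)
#'
#' @param ranked a `ranked_list`.
#' @param path output path.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(ranked[, c("gene_id", "statistic")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
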