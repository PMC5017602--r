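# Quartile binning of marker expression and the four-cluster rule on
# IGHM / IGLL1 / VPREB1 positivity.

PRE_BCR_MARKERS <- c("IGHM", "IGLL1", "VPREB1", "CD79A", "CD79B")
CLUSTER_MARKERS <- c("IGHM", "IGLL1", "VPREB1")

#' Quartile bins of one marker's expression
#'
#' Samples are sorted by marker expression (ties broken by sample id, so the
#' partition is deterministic) and evenly divided into four bins whose sizes
#' differ by at most one; when the cohort size is not divisible by four the
#' larger bins sit at the low-expression end. Bin 1 is lowest expression,
#' bin 4 highest.
#'
#' @param matrix genes x samples expression matrix.
#' @param marker gene id present in the matrix.
#' @return named integer vector (one bin in 1..4 per sample, in matrix
#'   column order).
#' @export
quartile_bins <- function(matrix, marker) {
  validate_expression_matrix(matrix)
  if (!marker %in% rownames(matrix)) stop("marker not in matrix: ", marker)
  n <- ncol(matrix)
  if (n < 4L) stop("need >= 4 samples for quartile binning")
  vals <- matrix[marker, ]
  ord <- order(vals, colnames(matrix))
  sizes <- rep(n %/% 4L, 4L)
  if (n %% 4L) sizes[seq_len(n %% 4L)] <- sizes[seq_len(n %% 4L)] + 1L
  bins <- integer(n)
  bins[ord] <- rep(1:4, times = sizes)
  names(bins) <- colnames(matrix)
  bins
}

#' Per-sample positivity calls for a set of markers
#'
#' Default method `"median"`: a sample is positive for a marker iff its
#' expression strictly exceeds the cohort median of that marker.
#' `"top_half_quartiles"`: positive iff the sample falls in quartile bin 3
#' or 4. `"threshold"`: positive iff expression strictly exceeds a fixed
#' cutoff (same cutoff for all markers unless a named vector is given).
#'
#' @param matrix genes x samples expression matrix.
#' @param markers gene ids to call (default IGHM, IGLL1, VPREB1).
#' @param method `"median"`, `"top_half_quartiles"` or `"threshold"`.
#' @param threshold numeric cutoff(s) for `method = "threshold"`.
#' @return a `positivity_table`: data.frame with `sample_id` and one logical
#'   column per marker; the method and per-marker thresholds are kept in
#'   attributes `"method"` and `"thresholds"`.
#' @export
call_positivity <- function(matrix, markers = CLUSTER_MARKERS,
                            method = c("median", "top_half_quartiles", "threshold"),
                            threshold = NULL) {
  method <- match.arg(method)
  validate_expression_matrix(matrix)
  missing <- setdiff(markers, rownames(matrix))
  if (length(missing)) stop("marker(s) not in matrix: ", paste(missing, collapse = ", "))
  if (ncol(matrix) < 2L) stop("need >= 2 samples for positivity calls")
  if (method == "threshold") {
    if (is.null(threshold)) stop("method 'threshold' needs a threshold value")
    if (is.null(names(threshold))) threshold <- stats::setNames(rep(threshold[[1L]], length(markers)), markers)
  }
  calls <- lapply(markers, function(m) {
    switch(method,
      median = {
        cut <- stats::median(matrix[m, ])
        list(call = matrix[m, ] > cut, threshold = cut)
      },
      top_half_quartiles = {
        list(call = quartile_bins(matrix, m) >= 3L, threshold = NA_real_)
      },
      threshold = {
        list(call = matrix[m, ] > threshold[[m]], threshold = threshold[[m]])
      })
  })
  df <- data.frame(sample_id = colnames(matrix), stringsAsFactors = FALSE)
  for (i in seq_along(markers)) df[[markers[[i]]]] <- unname(calls[[i]]$call)
  structure(df, class = c("positivity_table", "data.frame"),
            method = method,
            thresholds = stats::setNames(vapply(calls, `[[`, numeric(1L), "threshold"), markers))
}

#' Assign the four-cluster label from IGHM/IGLL1/VPREB1 positivity
#'
#' The rule is total over all 8 positivity patterns:
#' \itemize{
#'   \item Cluster 1: IGHM+ IGLL1+ VPREB1+ (all three high);
#'   \item Cluster 2: IGHM+ and not Cluster 1 (any other IGHM+ pattern);
#'   \item Cluster 3: IGHM- with IGLL1+ and/or VPREB1+;
#'   \item Cluster 4: IGHM- IGLL1- VPREB1- (all three low).
#' }
#'
#' @param positivity a `positivity_table` from [call_positivity()] with
#'   calls for exactly IGHM, IGLL1 and VPREB1.
#' @return a `cluster_assignment`: data.frame with `sample_id`, the three
#'   logical marker calls and integer `cluster` in 1..4.
#' @export
assign_clusters <- function(positivity) {
  need <- CLUSTER_MARKERS
  if (!all(need %in% names(positivity)))
    stop("positivity table must have calls for ", paste(need, collapse = ", "))
  ighm <- positivity$IGHM; igll1 <- positivity$IGLL1; vpreb1 <- positivity$VPREB1
  cluster <- ifelse(ighm & igll1 & vpreb1, 1L,
             ifelse(ighm, 2L,
             ifelse(igll1 | vpreb1, 3L, 4L)))
  df <- data.frame(sample_id = positivity$sample_id,
                   IGHM = ighm, IGLL1 = igll1, VPREB1 = vpreb1,
                   cluster = cluster, stringsAsFactors = FALSE)
  structure(df, class = c("cluster_assignment", "data.frame"),
            method = attr(positivity, "method"),
            thresholds = attr(positivity, "thresholds"))
}

#' Write cluster assignments as TSV
#'
#' Records the positivity method and thresholds in a `#` header line.
#'
#' @param assignment a `cluster_assignment`.
#' @param path output path.
#' @param comment optional extra `#` comment line.
#' @export
write_cluster_assignment <- function(assignment, path, comment = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  thr <- attr(assignment, "thresholds")
  writeLines(paste0("# method=", attr(assignment, "method"), " thresholds=",
                    paste(names(thr), signif(thr, 6), sep = ":", collapse = ",")), con)
  utils::write.table(as.data.frame(assignment), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
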