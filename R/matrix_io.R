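# I/O for expression matrices, sample annotations and GMT gene sets.
# All tables are tab-delimited UTF-8; expression values are log2 scale.

OUTCOME_COLUMNS <- c("mrd29_positive", "efs_time", "efs_event", "os_time", "os_event")

#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix of log2 expression values
#' with unique gene ids as rownames and unique sample ids as colnames.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return `x` invisibly, after validation.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop("expression matrix is empty")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene ids: ", paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ", paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (!all(is.finite(x)))
    stop("expression matrix contains non-finite values (NA/NaN/Inf)")
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Duplicate gene ids are collapsed by keeping the row with the highest mean
#' (the usual microarray probe-collapse convention); a message reports how
#' many rows were dropped.
#'
#' @param path path to a tab-delimited text file. Lines starting with `#`
#'   are skipped.
#' @param log2_transform if `TRUE`, apply `log2(x + 1)` to raw-scale values.
#'   Input is otherwise assumed to be log2 scale already.
#' @return a validated numeric genes x samples matrix.
#' @export
read_expression_matrix <- function(path, log2_transform = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L)
    stop("parse error in ", path, ": need a header line and at least one gene row")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop("parse error in ", path, " line 1: header must name at least one sample")
  sample_ids <- header[-1L]
  # header may or may not carry a leading gene-id column name; detect by
  # comparing field counts with the first data row
  n_fields <- length(strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]])
  if (n_fields == length(header) + 1L) sample_ids <- header

  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids))
  for (i in seq_along(body)) {
    fields <- body[[i]][-1L]
    if (length(fields) != length(sample_ids))
      stop("parse error in ", path, " line ", i + 1L, ": expected ",
           length(sample_ids), " values, got ", length(fields))
    v <- suppressWarnings(as.numeric(fields))
    if (anyNA(v) || any(!is.finite(v)))
      stop("parse error in ", path, " line ", i + 1L,
           ": non-numeric or missing expression value")
    vals[i, ] <- v
  }
  rownames(vals) <- gene_ids
  colnames(vals) <- sample_ids

  if (anyDuplicated(gene_ids)) {
    means <- rowMeans(vals)
    # keep, per gene id, the row with the highest mean
    ord <- order(gene_ids, -means)
    keep <- ord[!duplicated(gene_ids[ord])]
    message("collapsed ", nrow(vals) - length(keep),
            " duplicate gene rows (kept highest-mean row)")
    vals <- vals[sort(keep), , drop = FALSE]
  }
  if (log2_transform) vals <- log2(vals + 1)
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' @param x validated expression matrix.
#' @param path output path.
#' @param comment optional comment line (written prefixed with `#`).
#' @export
write_expression_matrix <- function(x, path, comment = NULL) {
  validate_expression_matrix(x)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  writeLines(paste(rownames(x),
                   apply(format(x, trim = TRUE, digits = 15), 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Tab-delimited with required columns `sample_id` and `group`; optional
#' outcome columns `mrd29_positive`, `efs_time`, `efs_event`, `os_time`,
#' `os_event`. A time column must be accompanied by its event flag.
#' Unknown columns are dropped with a warning.
#'
#' @param path path to a tab-delimited annotation file.
#' @return data.frame with one row per sample.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  known <- c("sample_id", "group", OUTCOME_COLUMNS)
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warning("ignoring unknown annotation columns: ", paste(extra, collapse = ", "))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  for (col in intersect(c("mrd29_positive", "efs_event", "os_event"), names(df)))
    df[[col]] <- as.logical(df[[col]])
  validate_annotations(df)
  df
}

#' Validate a sample annotation table
#'
#' @param df data.frame with columns `sample_id`, `group` and optional
#'   outcome columns.
#' @param matrix optional expression matrix; if given, every `sample_id`
#'   must be one of its columns.
#' @return `df` invisibly.
#' @export
validate_annotations <- function(df, matrix = NULL) {
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("annotations need 'sample_id' and 'group' columns")
  if (anyNA(df$sample_id) || any(!nzchar(df$sample_id)))
    stop("missing sample_id in annotations")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in annotations: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (anyNA(df$group) || any(!nzchar(df$group)))
    stop("empty group label in annotations")
  for (pair in list(c("efs_time", "efs_event"), c("os_time", "os_event"))) {
    has_t <- pair[1L] %in% names(df)
    has_e <- pair[2L] %in% names(df)
    if (has_t != has_e)
      stop("annotation column ", pair[c(has_t, has_e)], " present without its partner ",
           pair[c(!has_t, !has_e)])
    if (has_t) {
      bad <- is.na(df[[pair[1L]]]) != is.na(df[[pair[2L]]])
      if (any(bad))
        stop("sample(s) ", paste(df$sample_id[bad], collapse = ", "),
             ": ", pair[1L], " present iff ", pair[2L], " is present")
      if (any(df[[pair[1L]]] < 0, na.rm = TRUE))
        stop("negative ", pair[1L], " in annotations")
    }
  }
  if (!is.null(matrix)) {
    missing <- setdiff(df$sample_id, colnames(matrix))
    if (length(missing))
      stop("annotation sample(s) absent from matrix: ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Write a sample annotation table as TSV
#'
#' @param df annotation data.frame.
#' @param path output path.
#' @param comment optional `#` comment line.
#' @export
write_annotations <- function(df, path, comment = NULL) {
  validate_annotations(df)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Construct a gene signature
#'
#' A named, ordered gene list derived for one group (stage, subtype or
#' cluster).
#'
#' @param name signature name.
#' @param genes ordered character vector of unique gene ids.
#' @param description free-text description (GMT second field).
#' @param source_group group label the signature was derived for.
#' @param n_requested the top-N that was asked for (`length(genes)` may be
#'   smaller when fewer genes qualified).
#' @return object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, description = "", source_group = NA_character_,
                           n_requested = length(genes)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate genes in signature '", name, "'")
  if (length(genes) > n_requested)
    stop("signature '", name, "' longer than n_requested")
  structure(list(name = name, genes = genes, description = description,
                 source_group = source_group, n_requested = n_requested),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("gene_signature '", x$name, "': ", length(x$genes), " genes",
      if (!is.na(x$source_group)) paste0(" (group ", x$source_group, ")"), "\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name <tab> description <tab> gene ...`.
#' Duplicate genes within a set are removed with a warning; a line with
#' fewer than three fields is an error.
#'
#' @param path GMT file path.
#' @return list of [gene_signature] objects, named by signature name.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sigs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT parse error in ", path, " line ", i,
           ": need name, description and at least one gene")
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) in set '", fields[1L], "', deduplicated")
      genes <- unique(genes)
    }
    gene_signature(fields[1L], genes, description = fields[2L])
  })
  names(sigs) <- vapply(sigs, `[[`, character(1L), "name")
  sigs
}

#' Write gene sets to a GMT file
#'
#' @param signatures list of [gene_signature] objects (a single signature is
#'   accepted too).
#' @param path output path.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- vapply(signatures, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
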