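# Bidirectional cross-projection: healthy-stage signatures tested in every
# leukemia subtype contrast, subtype signatures tested in every healthy
# stage contrast, then a per-subtype arrest-stage call.

#' Cross-project stage and subtype signatures between two cohorts
#'
#' Restricts both cohorts to their common gene universe, derives a top-`n`
#' signature for every healthy stage and every leukemia subtype, and fills
#' two enrichment grids: forward (each stage signature scored in each
#' subtype-vs-rest contrast of the leukemia cohort) and reverse (each
#' subtype signature scored in each stage-vs-rest contrast of the healthy
#' cohort).
#'
#' @param healthy_matrix,healthy_annotations healthy B-cell cohort (groups =
#'   developmental stages).
#' @param leukemia_matrix,leukemia_annotations leukemia cohort (groups =
#'   genetic subtypes).
#' @param n top-N per signature (default 400).
#' @param n_perm permutations per enrichment test.
#' @param seed RNG seed for all permutation nulls.
#' @param weight ES weight exponent.
#' @return a `projection_grid`: list with data.frames `forward` and
#'   `reverse` (columns direction, signature, contrast, es, nes, p_perm,
#'   n_permutations, mode) plus the signature lists.
#' @export
cross_project <- function(healthy_matrix, healthy_annotations,
                          leukemia_matrix, leukemia_annotations,
                          n = 400L, n_perm = 1000L, seed = 0L, weight = 0) {
  common <- intersect(rownames(healthy_matrix), rownames(leukemia_matrix))
  if (!length(common)) stop("healthy and leukemia matrices share no genes")
  if (length(common) < nrow(healthy_matrix) || length(common) < nrow(leukemia_matrix))
    message("restricting analysis to ", length(common), " shared genes")
  H <- healthy_matrix[common, , drop = FALSE]
  L <- leukemia_matrix[common, , drop = FALSE]

  stage_sigs <- derive_all_group_signatures(H, healthy_annotations, n = n)
  subtype_sigs <- derive_all_group_signatures(L, leukemia_annotations, n = n)
  subtypes <- names(subtype_sigs)
  stages <- names(stage_sigs)

  grid_rows <- function(results, direction, contrast_group) {
    do.call(rbind, lapply(results, function(r) {
      data.frame(direction = direction, signature = r$signature_name,
                 contrast = contrast_group, es = r$es, nes = r$nes,
                 p_perm = r$p_perm, n_permutations = r$n_permutations,
                 mode = r$mode, stringsAsFactors = FALSE)
    }))
  }

  # forward: stage signatures in each subtype contrast (one shared null per
  # contrast); seeds stay distinct and below 2^31
  forward <- do.call(rbind, lapply(seq_along(subtypes), function(i) {
    res <- .gsea_contrast(L, leukemia_annotations, subtypes[[i]], stage_sigs,
                          n_perm = n_perm, seed = (seed + i) %% .Machine$integer.max,
                          weight = weight)
    grid_rows(res, "healthy_to_leukemia", subtypes[[i]])
  }))
  reverse <- do.call(rbind, lapply(seq_along(stages), function(i) {
    res <- .gsea_contrast(H, healthy_annotations, stages[[i]], subtype_sigs,
                          n_perm = n_perm,
                          seed = (seed + length(subtypes) + i) %% .Machine$integer.max,
                          weight = weight)
    grid_rows(res, "leukemia_to_healthy", stages[[i]])
  }))
  rownames(forward) <- rownames(reverse) <- NULL

  structure(list(forward = forward, reverse = reverse,
                 stage_signatures = stage_sigs, subtype_signatures = subtype_sigs,
                 n_shared_genes = length(common)),
            class = "projection_grid")
}

#' @export
print.projection_grid <- function(x, ...) {
  cat("projection_grid: ", length(x$stage_signatures), " stage signatures x ",
      length(x$subtype_signatures), " subtype signatures (",
      x$n_shared_genes, " shared genes)\n", sep = "")
  invisible(x)
}

#' Call the developmental arrest stage of each leukemia subtype
#'
#' A (stage, subtype) pair qualifies when the forward test (stage signature
#' in the subtype contrast) and the reverse test (subtype signature in the
#' stage contrast) are both significant at `alpha` with positive enrichment.
#' A subtype is called arrested at stage `s` when (s, subtype) is the unique
#' qualifying pair both in its row (no other stage qualifies for the
#' subtype) and in its column (the stage qualifies for no other subtype):
#' an enrichment shared by several subtypes, or several stages, is not
#' specific. Everything else is `"unassigned"`; ambiguous candidates are
#' reported in a message.
#'
#' @param grid a `projection_grid` from [cross_project()].
#' @param alpha significance level for each direction (default 0.05).
#' @return data.frame with columns `subtype`, `stage`, `forward_p`,
#'   `reverse_p`.
#' @export
call_arrest_stage <- function(grid, alpha = 0.05) {
  stopifnot(inherits(grid, "projection_grid"))
  stages <- names(grid$stage_signatures)
  subtypes <- names(grid$subtype_signatures)
  fp <- rp <- Q <- matrix(NA_real_, length(stages), length(subtypes),
                          dimnames = list(stages, subtypes))
  for (st in subtypes) {
    f <- grid$forward[grid$forward$contrast == st, ]
    r <- grid$reverse[grid$reverse$signature == grid$subtype_signatures[[st]]$name, ]
    for (s in stages) {
      fi <- f[f$signature == grid$stage_signatures[[s]]$name, ]
      ri <- r[r$contrast == s, ]
      if (nrow(fi) != 1L || nrow(ri) != 1L)
        stop("incomplete projection grid at (", s, ", ", st, ")")
      fp[s, st] <- fi$p_perm
      rp[s, st] <- ri$p_perm
      Q[s, st] <- as.numeric(fi$es > 0 && ri$es > 0 &&
                             fi$p_perm <= alpha && ri$p_perm <= alpha)
    }
  }
  out <- lapply(subtypes, function(st) {
    hits <- stages[Q[, st] == 1]
    s <- if (length(hits) == 1L && sum(Q[hits, ]) == 1L) hits else NULL
    if (is.null(s)) {
      if (length(hits) > 1L)
        message("subtype ", st, ": multiple qualifying stages (",
                paste(hits, collapse = ", "), "); unassigned")
      else if (length(hits) == 1L)
        message("subtype ", st, ": stage ", hits,
                " also qualifies for other subtype(s); not specific, unassigned")
      data.frame(subtype = st, stage = "unassigned", forward_p = NA_real_,
                 reverse_p = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(subtype = st, stage = s, forward_p = fp[s, st],
                 reverse_p = rp[s, st], stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a projection grid as long-format TSV
#'
#' @param grid a `projection_grid`.
#' @param path output path.
#' @param comment optional `#` comment line.
#' @export
write_projection_grid <- function(grid, path, comment = NULL) {
  df <- rbind(grid$forward, grid$reverse)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
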