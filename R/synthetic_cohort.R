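# Synthetic expression-cohort generator: healthy B-cell stages with planted
# stage-specific gene blocks and pre-BCR marker patterns, leukemia subtypes
# with a planted developmental arrest stage, and cluster-dependent
# MRD/survival outcomes. Everything is deterministic for a fixed seed, so
# the whole pipeline is testable without external data.

.default_marker_pattern <- function() {
  # pre-BCR component expression across healthy stages: CLP expresses none;
  # pro-B the surrogate light chain (VPREB1, IGLL1) and CD79A/B; pre-B all
  # five components; immature B only IGHM and CD79A/B.
  list("CLP"   = character(),
       "pro-B" = c("VPREB1", "IGLL1", "CD79A", "CD79B"),
       "pre-B" = c("IGHM", "IGLL1", "VPREB1", "CD79A", "CD79B"),
       "iB"    = c("IGHM", "CD79A", "CD79B"))
}

.default_outcome_model <- function() {
  # per-cluster MRD29 positive probability, exponential event hazards
  # (per day) and censoring hazard. Cluster 1 has the best early response
  # and longest survival, cluster 3 the shortest.
  list(
    "1" = list(mrd_prob = 0.13, efs_hazard = 1.6e-4, os_hazard = 0.9e-4, censor_rate = 1.5e-4),
    "2" = list(mrd_prob = 0.45, efs_hazard = 3.3e-4, os_hazard = 2.0e-4, censor_rate = 1.5e-4),
    "3" = list(mrd_prob = 0.45, efs_hazard = 5.8e-4, os_hazard = 3.8e-4, censor_rate = 1.5e-4),
    "4" = list(mrd_prob = 0.45, efs_hazard = 3.3e-4, os_hazard = 2.0e-4, censor_rate = 1.5e-4))
}

.default_subtype_map <- function() {
  c("TCF3-PBX1" = "pre-B", "ETV6-RUNX1" = "pro-B", "BCR-ABL1" = "none",
    "MLL" = "none", "HH" = "none", "other" = "none")
}

#' Specify a synthetic cohort
#'
#' Defines the gene universe (five pre-BCR marker genes plus numbered
#' background genes), disjoint stage- and subtype-specific up-regulated gene
#' blocks, per-stage marker patterns, a subtype-to-arrest-stage map and a
#' per-cluster outcome model. Blocks are laid out automatically unless given
#' explicitly.
#'
#' @param n_genes total genes including the five markers (default 3000).
#' @param genes_per_stage_signature planted block size per stage (default 200).
#' @param genes_per_subtype_signature planted block size per subtype
#'   (default: same as the stage block size).
#' @param stages ordered developmental stages.
#' @param subtype_map named character vector, subtype -> arrest stage or
#'   `"none"` for subtypes without stage structure.
#' @param samples_per_group samples per stage and per subtype (default 20).
#' @param effect_size up-shift of planted blocks, log2 units (default 2).
#' @param marker_effect_size up-shift of positive markers (default: same as
#'   `effect_size`).
#' @param noise_sd Gaussian noise SD in log2 space (default 1).
#' @param baseline baseline log2 expression (default 6).
#' @param marker_pattern list stage -> character vector of positive markers.
#' @param outcome_model list cluster label -> list(mrd_prob, efs_hazard,
#'   os_hazard, censor_rate); hazards per day.
#' @param stage_blocks,subtype_blocks optional explicit named lists of gene
#'   ids; must be mutually disjoint and marker-free.
#' @param seed integer seed governing all three generators.
#' @return a validated `cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 3000L,
                        genes_per_stage_signature = 200L,
                        genes_per_subtype_signature = genes_per_stage_signature,
                        stages = c("CLP", "pro-B", "pre-B", "iB"),
                        subtype_map = .default_subtype_map(),
                        samples_per_group = 20L,
                        effect_size = 2,
                        marker_effect_size = effect_size,
                        noise_sd = 1,
                        baseline = 6,
                        marker_pattern = .default_marker_pattern(),
                        outcome_model = .default_outcome_model(),
                        stage_blocks = NULL,
                        subtype_blocks = NULL,
                        seed = 0L) {
  n_markers <- length(PRE_BCR_MARKERS)
  if (n_genes <= n_markers) stop("n_genes must exceed the ", n_markers, " marker genes")
  gene_ids <- c(PRE_BCR_MARKERS, sprintf("G%05d", seq_len(n_genes - n_markers)))
  background <- setdiff(gene_ids, PRE_BCR_MARKERS)

  subtypes <- names(subtype_map)
  if (is.null(subtypes)) stop("subtype_map must be a named vector (subtype -> stage)")
  if (is.null(stage_blocks)) {
    need <- length(stages) * genes_per_stage_signature
    if (need > length(background)) stop("n_genes too small for the stage blocks")
    stage_blocks <- split(background[seq_len(need)],
                          rep(seq_along(stages), each = genes_per_stage_signature))
    names(stage_blocks) <- stages
    offset <- need
  } else {
    offset <- 0L  # explicit blocks: subtype blocks must also be explicit or fit after markers
  }
  if (is.null(subtype_blocks)) {
    used <- unlist(stage_blocks, use.names = FALSE)
    free <- setdiff(background, used)
    need <- length(subtypes) * genes_per_subtype_signature
    if (need > length(free)) stop("n_genes too small for the subtype blocks")
    subtype_blocks <- split(free[seq_len(need)],
                            rep(seq_along(subtypes), each = genes_per_subtype_signature))
    names(subtype_blocks) <- subtypes
  }

  spec <- structure(list(
    n_genes = n_genes, gene_ids = gene_ids, stages = stages,
    subtype_map = subtype_map, samples_per_group = as.integer(samples_per_group),
    effect_size = effect_size, marker_effect_size = marker_effect_size,
    noise_sd = noise_sd, baseline = baseline,
    marker_pattern = marker_pattern, outcome_model = outcome_model,
    stage_blocks = stage_blocks, subtype_blocks = subtype_blocks,
    seed = as.integer(seed)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' @param spec a `cohort_spec`.
#' @return `spec` invisibly.
#' @export
validate_cohort_spec <- function(spec) {
  blocks <- c(spec$stage_blocks, spec$subtype_blocks)
  all_block_genes <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(all_block_genes))
    stop("invariant violated: signature gene blocks overlap")
  if (length(intersect(all_block_genes, PRE_BCR_MARKERS)))
    stop("invariant violated: signature blocks must not contain marker genes")
  missing <- setdiff(all_block_genes, spec$gene_ids)
  if (length(missing))
    stop("invariant violated: block gene(s) absent from universe: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  if (!all(PRE_BCR_MARKERS %in% spec$gene_ids))
    stop("invariant violated: marker genes must exist in the gene universe")
  if (!all(names(spec$stage_blocks) == spec$stages))
    stop("stage_blocks must be named by the stages, in order")
  bad <- setdiff(setdiff(unique(spec$subtype_map), "none"), spec$stages)
  if (length(bad))
    stop("subtype_map references unknown stage(s): ", paste(bad, collapse = ", "))
  if (!all(names(spec$marker_pattern) %in% spec$stages) ||
      !all(spec$stages %in% names(spec$marker_pattern)))
    stop("marker_pattern must cover exactly the stages")
  if (!all(unlist(spec$marker_pattern) %in% PRE_BCR_MARKERS))
    stop("marker_pattern may only name pre-BCR markers")
  for (cl in names(spec$outcome_model)) {
    m <- spec$outcome_model[[cl]]
    if (m$mrd_prob < 0 || m$mrd_prob > 1)
      stop("invariant violated: mrd_prob for cluster ", cl, " outside [0,1]")
    if (m$efs_hazard <= 0 || m$os_hazard <= 0)
      stop("invariant violated: hazards must be > 0 (cluster ", cl, ")")
    if (m$censor_rate < 0)
      stop("invariant violated: censor_rate must be >= 0 (cluster ", cl, ")")
  }
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$samples_per_group < 1L) stop("samples_per_group must be >= 1")
  invisible(spec)
}

# Mean log2 profile for one group: baseline + block shift + marker shift.
.group_mean_profile <- function(spec, block_genes, positive_markers) {
  mu <- stats::setNames(rep(spec$baseline, length(spec$gene_ids)), spec$gene_ids)
  mu[block_genes] <- mu[block_genes] + spec$effect_size
  mu[positive_markers] <- mu[positive_markers] + spec$marker_effect_size
  mu
}

.simulate_cohort <- function(spec, groups, profiles, prefix) {
  n <- spec$samples_per_group
  sample_ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%s_%02d", prefix, gsub("[^A-Za-z0-9]", "", g), seq_len(n))))
  mu <- do.call(cbind, lapply(groups, function(g)
    matrix(profiles[[g]], nrow = length(spec$gene_ids), ncol = n)))
  noise <- matrix(stats::rnorm(length(mu), sd = spec$noise_sd),
                  nrow = nrow(mu), ncol = ncol(mu))
  X <- mu + noise
  rownames(X) <- spec$gene_ids
  colnames(X) <- sample_ids
  ann <- data.frame(sample_id = sample_ids,
                    group = rep(groups, each = n),
                    stringsAsFactors = FALSE)
  list(matrix = X, annotations = ann)
}

#' Simulate the healthy B-cell cohort
#'
#' Every sample of stage `s` has mean `baseline + effect_size` on the
#' stage-`s` block, `baseline + marker_effect_size` on the stage's positive
#' markers and `baseline` elsewhere, plus Gaussian noise in log2 space.
#'
#' @param spec a `cohort_spec`.
#' @return list with `matrix` (genes x samples) and `annotations`.
#' @export
simulate_healthy <- function(spec) {
  validate_cohort_spec(spec)
  profiles <- lapply(stats::setNames(spec$stages, spec$stages), function(s)
    .group_mean_profile(spec, spec$stage_blocks[[s]], spec$marker_pattern[[s]]))
  .with_seed(spec$seed, .simulate_cohort(spec, spec$stages, profiles, "H"))
}

#' Simulate the leukemia cohort
#'
#' A subtype mapped to arrest stage `s` inherits that stage's mean profile
#' (stage block and marker pattern) and additionally up-shifts its own
#' subtype-specific block, so subtype signatures are derivable. Subtypes
#' mapped to `"none"` get only their subtype block (no stage structure, no
#' marker shift).
#'
#' @param spec a `cohort_spec`.
#' @return list with `matrix` (genes x samples) and `annotations`.
#' @export
simulate_leukemia <- function(spec) {
  validate_cohort_spec(spec)
  subtypes <- names(spec$subtype_map)
  profiles <- lapply(stats::setNames(subtypes, subtypes), function(st) {
    arrest <- spec$subtype_map[[st]]
    block <- spec$subtype_blocks[[st]]
    if (arrest == "none")
      .group_mean_profile(spec, block, character())
    else
      .group_mean_profile(spec, c(block, spec$stage_blocks[[arrest]]),
                          spec$marker_pattern[[arrest]])
  })
  .with_seed(spec$seed + 1L, .simulate_cohort(spec, subtypes, profiles, "L"))
}

#' Simulate cluster-dependent clinical outcomes
#'
#' MRD29 positivity is Bernoulli with the cluster's `mrd_prob`; event-free
#' and overall survival times are exponential with the cluster's hazards,
#' censored by an independent exponential at `censor_rate` (per day).
#'
#' @param assignment a `cluster_assignment` (column `cluster` drives the
#'   outcome model).
#' @param spec a `cohort_spec` providing the `outcome_model` and seed.
#' @return data.frame with `sample_id`, `mrd29_positive`, `efs_time`,
#'   `efs_event`, `os_time`, `os_event` (times in days).
#' @export
simulate_outcomes <- function(assignment, spec) {
  validate_cohort_spec(spec)
  df <- as.data.frame(assignment)
  missing <- setdiff(as.character(unique(df$cluster)), names(spec$outcome_model))
  if (length(missing))
    stop("outcome_model has no entry for cluster(s): ", paste(missing, collapse = ", "))
  .with_seed(spec$seed + 2L, {
    n <- nrow(df)
    model <- spec$outcome_model[as.character(df$cluster)]
    mrd_p <- vapply(model, `[[`, numeric(1L), "mrd_prob")
    efs_h <- vapply(model, `[[`, numeric(1L), "efs_hazard")
    os_h <- vapply(model, `[[`, numeric(1L), "os_hazard")
    cens <- vapply(model, `[[`, numeric(1L), "censor_rate")
    t_efs <- stats::rexp(n, efs_h)
    t_os <- stats::rexp(n, os_h)
    t_cens <- ifelse(cens > 0, stats::rexp(n, pmax(cens, .Machine$double.xmin)), Inf)
    data.frame(sample_id = df$sample_id,
               mrd29_positive = stats::runif(n) < mrd_p,
               efs_time = pmin(t_efs, t_cens),
               efs_event = t_efs <= t_cens,
               os_time = pmin(t_os, t_cens),
               os_event = t_os <= t_cens,
               stringsAsFactors = FALSE)
  })
}
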