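# stagescan

Developmental-stage projection of B-cell precursor acute lymphoblastic
leukemia (BCP-ALL) transcriptomes from pre-BCR component expression.

BCP-ALL blasts are thought to be arrested at a defined stage of normal
B-cell development — common lymphoid progenitor (CLP), pro-B, pre-B or
immature B (iB) — and the components of the pre-B-cell receptor (*IGHM*,
the surrogate light chain *VPREB1*/*IGLL1*, and *CD79A*/*CD79B*) are
expressed in stage-specific patterns. `stagescan` is for computational
biologists who want to place leukemia transcriptomes on that developmental
axis and relate the placement to clinical outcome. It provides, as tested
reusable functions:

* **Signature derivation** — the top-*n* (default 400) genes highly
  expressed in one group versus the rest, ranked by Welch *t*
  (`rank_genes()`, `derive_signature()`);
* **A native rank-based enrichment engine** — running-sum enrichment score
  ES ∈ [−1, 1] (step +1/|S| at set members, −1/(N−|S|) otherwise, weight-0
  default; optionally |t|^w-weighted), normalized score
  NES = ES / mean|ES_null, same sign|, and an add-one permutation p with
  phenotype or gene-label nulls (`gsea()`, `enrichment_score()`,
  `permutation_null()`, `nes_and_p()`);
* **Bidirectional stage projection** — every stage signature scored in
  every leukemia subtype contrast and vice versa; a subtype is called
  arrested at stage *s* only when (s, subtype) is the unique pair
  significant with positive ES in both directions, along both axes of the
  grid (`cross_project()`, `call_arrest_stage()`);
* **Four-cluster marker classification** — per-marker positivity
  (median / quartile / fixed threshold) and the total rule
  Cluster 1 = IGHM+IGLL1+VPREB1+, Cluster 2 = other IGHM+,
  Cluster 3 = IGHM− with IGLL1+ and/or VPREB1+, Cluster 4 = triple
  negative (`call_positivity()`, `assign_clusters()`, `quartile_bins()`);
* **Native outcome statistics** — Kaplan–Meier product-limit curves,
  tie-corrected k-sample log-rank, and two-sided Fisher exact tests
  (hypergeometric for 2×2, Freeman–Halton enumeration for 2×k), combined
  into a cluster-wise MRD/survival report (`km_estimate()`,
  `logrank_test()`, `fisher_exact()`, `compare_clusters()`);
* **A synthetic cohort generator** — healthy stages with planted expression
  blocks and pre-BCR marker patterns, leukemia subtypes with planted arrest
  stages, cluster-dependent MRD/survival outcomes; fully deterministic per
  seed (`cohort_spec()`, `simulate_healthy()`, `simulate_leukemia()`,
  `simulate_outcomes()`);
* **An end-to-end pipeline** with TSV/GMT inputs and outputs, YAML config,
  config-hash-stamped artifacts and a JSON run manifest (`run_pipeline()`;
  a thin CLI wrapper lives in `inst/scripts/stagescan.R`).

See the methods vignette (`vignettes/stage-projection-methods.Rmd`) for the
models, conventions and design decisions.

## Worked example

Simulate a cohort under the default study conditions (3000 genes, four
healthy stages and six leukemia subtypes at 20 samples each, planted
effect 2 log2 units, noise SD 1), project stages bidirectionally, and
compare cluster outcomes:

```r
library(stagescan)

spec     <- cohort_spec(seed = 1L)
healthy  <- simulate_healthy(spec)
leukemia <- simulate_leukemia(spec)

grid  <- cross_project(healthy$matrix, healthy$annotations,
                       leukemia$matrix, leukemia$annotations,
                       n = 400, n_perm = 199, seed = 1)
call_arrest_stage(grid)
#>      subtype      stage   forward_p  reverse_p
#> 1   BCR-ABL1 unassigned          NA         NA
#> 2 ETV6-RUNX1      pro-B 0.011627907 0.01086957
#> 3         HH unassigned          NA         NA
#> 4        MLL unassigned          NA         NA
#> 5      other unassigned          NA         NA
#> 6  TCF3-PBX1      pre-B 0.009615385 0.01030928
```

The two subtypes generated with a planted arrest stage are recovered
(TCF3-PBX1 → pre-B, ETV6-RUNX1 → pro-B; the permutation p-values are
bounded below by 1/(B+1) with B same-signed nulls of the 199
permutations), and the four structureless subtypes stay unassigned.

```r
assignment <- assign_clusters(call_positivity(leukemia$matrix))
table(cluster = assignment$cluster, subtype = leukemia$annotations$group)
#>        subtype
#> cluster BCR-ABL1 ETV6-RUNX1 HH MLL other TCF3-PBX1
#>       1        0          7  1   0     1        15
#>       2        9          2  8   5     8         4
#>       3        6         11  5   7     6         1
#>       4        5          0  6   8     5         0

outcomes <- simulate_outcomes(assignment, spec)
compare_clusters(assignment, outcomes)
#> cluster_outcome_report over clusters 1, 2, 3, 4
#>   MRD29 positive fraction: cluster1 0.21, cluster2 0.47, cluster3 0.28, cluster4 0.46
#>   MRD29 overall Fisher p = 0.09766; cluster 1 vs rest p = 0.1004
#>   EFS omnibus log-rank p = 0.1445
#>   OS omnibus log-rank p = 1.866e-05
```

Most triple-positive samples come from the pre-B-arrested subtype (15 of
the 24 cluster-1 samples are TCF3-PBX1-like). Cluster 1 shows the planted
low MRD positivity (0.21 observed against a generative 0.13, with only 24
samples in the cluster); at this cohort size the MRD contrast is not yet
significant, while the overall-survival log-rank is. Larger cohorts (e.g.
50 samples per cluster, as in the acceptance script) separate the MRD
model at p < 1e-4.

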