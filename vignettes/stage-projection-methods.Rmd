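---
title: "Methods: developmental-stage projection of BCP-ALL transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: developmental-stage projection of BCP-ALL transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagescan)
```

## Scientific background

B-cell precursor acute lymphoblastic leukemia (BCP-ALL) arises from B cells
blocked at some stage of their normal development: common lymphoid
progenitor (CLP), pro-B, pre-B, or immature B (iB). The pre-B-cell receptor
(pre-BCR) — the complex of the mu heavy chain (*IGHM*), the surrogate light
chain (*VPREB1* + *IGLL1*) and the signaling chains *CD79A*/*CD79B* — is
expressed only at the pre-B stage, so the mRNA levels of its components
carry information about the arrest stage of a leukemia. `stagescan`
implements a transcriptome-level pipeline around this idea:

1. derive, for every healthy stage and every leukemia genetic subtype, the
   signature of its most highly expressed genes (supervised one-vs-rest
   comparison);
2. score each signature in each contrast of the other cohort with a native
   rank-based gene-set enrichment engine;
3. call each subtype's arrest stage from the bidirectional projection grid;
4. classify leukemia samples into four clusters from *IGHM*/*IGLL1*/*VPREB1*
   positivity and compare cluster-wise clinical outcomes (MRD day 29,
   event-free and overall survival).

A synthetic cohort generator emulates the structure of the real data
(healthy stages with stage-specific expression programs and pre-BCR marker
patterns; leukemia subtypes with a planted arrest stage; cluster-dependent
outcomes), so every stage of the pipeline is tested end to end without any
external download.

## Signature derivation

For a target group versus all remaining samples the per-gene ranking
statistic is the Welch two-sample t (target mean minus rest mean, unequal
variances); a signal-to-noise-ratio alternative is available. The ranked
list is sorted non-increasingly with deterministic tie-breaks (larger mean
difference, then lexicographic gene id). The signature is the top *n*
genes, default *n* = 400, **excluding** genes with statistic <= 0: a
"highly expressed" signature must be up-regulated, so fewer than *n* genes
may be returned. No multiple-testing correction is applied — selection is
by rank, not significance. Genes with zero variance in both groups and
equal means receive statistic 0; with unequal means they receive a signed
infinite statistic and sort to the extremes.

One-vs-rest (rather than one-vs-one) contrasts are used throughout: a
stage's signature contrasts it against the other three stages, a subtype's
against all other subtypes in the cohort.

## Enrichment engine

Given a ranked list of N genes and a set S (overlap k, 0 < k < N), the
walk visits genes from top to bottom and accumulates

* +w_i / sum(w in S) at a member (w_i = |statistic|^weight; the default
  weight 0 gives equal steps 1/k),
* -1/(N-k) at a non-member.

The enrichment score (ES) is the running-sum value of maximal absolute
deviation, in [-1, 1]; the leading edge is the members at or before the
extremum (at or after it for a negative ES). The running sum ends at 0 for
weight 0. Weight 0 is the default because it matches the equal-step
description of the classic Kolmogorov-Smirnov walk; weight 1 is available.

**Tie handling.** The extremum is the *first* index whose |deviation| is
within 1e-12 of the maximum. The tolerance exists because equal-step walks
attain mathematically exact ties (e.g. +a and -a in one walk) that naive
floating-point comparison would resolve arbitrarily. One consequence is
worth stating: when the maximal positive and negative deviations tie
exactly, the sign of the ES is a convention, and no deterministic rule can
make ranking-reversal negate the ES on such walks (a set occupying
mirror-symmetric ranks maps to itself under reversal). Reversal always
preserves |ES|, and negates the ES whenever the extremum sign is
determined.

**Permutation null.** Two modes:

* *phenotype* — relabel target/rest samples, re-rank all genes, re-score;
  for small cohorts an exhaustive flag enumerates every relabeling exactly
  once;
* *gene label* — keep the observed ranking and score random same-size gene
  sets.

The automatic choice is phenotype when both groups have >= 5 samples, gene
label otherwise (with fewer samples the phenotype null support is too
coarse to be useful). The normalized enrichment score divides the observed
ES by the mean |null ES| of the same sign, as in the original GSEA
formulation; the p-value is the add-one (permutation-inclusive) tail
fraction among same-signed nulls, so its floor is 1/(B+1). The RNG seed is
an explicit argument everywhere and is recorded in every result.

The engine follows the classic GSEA formulation; commercial GSEA tools
often leave their exact statistic, null and p-value convention
undocumented, so reports label these defaults explicitly.

## Stage projection and the arrest call

Both cohorts are first restricted to their shared gene universe, so
signatures never contain genes absent from the matrix they are projected
into. The forward grid scores every stage signature in every
subtype-vs-rest contrast of the leukemia cohort; the reverse grid scores
every subtype signature in every stage-vs-rest contrast of the healthy
cohort.

A (stage, subtype) pair *qualifies* when both directions have positive ES
and p <= alpha (default 0.05, no correction across the grid; a Bonferroni
option can be emulated by lowering alpha). The arrest stage of a subtype is
called only when its pair is the **unique** qualifying pair in both its row
and its column of the grid. The column condition — the stage must not also
qualify for another subtype — is this package's formalization of
"specifically enriched": an enrichment that several subtypes share carries
no subtype-specific information. It matters in practice: in cohorts where
some subtypes carry planted stage programs, the signatures of the
*unplanted* stages consist of genes that are flat everywhere, and in a
structureless subtype's contrast those genes are systematically displaced
upward (the planted blocks of the other subtypes occupy the depleted tail),
which inflates their ES in several structureless subtypes at once. Row
uniqueness alone occasionally leaves exactly one such stage standing;
column uniqueness removes it. Everything else is reported `"unassigned"`.

## Marker clustering

Quartile binning sorts samples by a marker's expression (ties broken by
sample id) and splits them into four bins whose sizes differ by at most
one, larger bins at the low-expression end. Binning depends only on ranks,
so it is invariant under any strictly monotone transform.

Positivity calls default to a per-marker median split with strict
inequality (a constant marker is all-negative); quartile-based (bins 3-4)
and fixed-threshold alternatives exist, and the method and thresholds are
recorded in all outputs. The four-cluster rule on (*IGHM*, *IGLL1*,
*VPREB1*) positivity is total over all 8 patterns:

| Cluster | Pattern |
|---|---|
| 1 | IGHM+ IGLL1+ VPREB1+ |
| 2 | IGHM+ and not cluster 1 |
| 3 | IGHM- with IGLL1+ and/or VPREB1+ |
| 4 | IGHM- IGLL1- VPREB1- |

Cluster 2 is defined as *all* remaining IGHM+ patterns (including
IGHM+ IGLL1+ VPREB1- and IGHM+ IGLL1- VPREB1+ but also
IGHM+ IGLL1- VPREB1-). A narrower verbal description of cluster 2 —
"IGHM+ with either IGLL1 or VPREB1 but not both" — circulates alongside
this rule but does not yield a total partition; the table above is the
definition this package uses.

## Outcome statistics

All three tests are implemented natively in the package.

* **Kaplan-Meier**: product-limit estimator; censored observations reduce
  the risk set only, and censoring tied with an event time is processed
  after the event (the standard convention). With no censoring the curve
  equals one minus the empirical CDF.
* **Log-rank**: k-sample statistic with the multivariate hypergeometric
  variance at each distinct event time (tie-corrected, no continuity
  correction); quadratic form over k-1 groups (singular covariances fall
  back to a pseudoinverse), referred to chi-square with k-1 df.
* **Fisher's exact test**: two-sided by probability-mass ordering — the sum
  of probabilities of all margin-fixed tables whose point probability does
  not exceed the observed one within a 1e-7 relative tolerance (the
  dominant convention; others exist, which is why it is documented). 2x2
  tables use the hypergeometric distribution directly; 2xk tables (k <= 4)
  are enumerated exhaustively (Freeman-Halton).

The cluster-wise report combines the clusters x MRD29 table with the
overall Fisher p and cluster-1-versus-each/rest p-values, and per-cluster
KM curves with omnibus and all pairwise log-rank tests for event-free and
overall survival, because a figure-level p-value can reasonably be either.
Samples missing an outcome are excluded from that analysis only, with a
message. No correction is applied across pairwise contrasts.

## Synthetic cohort generator

Expression is Gaussian in log2 space (log-normal raw intensities, the
standard microarray noise model) around a baseline mu0 = 6. Stage-specific
blocks of genes (default 200 per stage, disjoint) and the stage's positive
pre-BCR markers are shifted up by the effect size Delta (default 2 log2
units, sigma = 1; markers share Delta by default, with an independent
marker effect available). The marker patterns encode the biology: CLP
expresses none of the five components; pro-B expresses *VPREB1*, *IGLL1*,
*CD79A*, *CD79B*; pre-B all five; iB only *IGHM* and *CD79A*/*CD79B*.

Leukemia subtypes with a planted arrest stage inherit that stage's mean
profile (block + markers) plus their own disjoint subtype block, so subtype
signatures are derivable; subtypes mapped to `"none"` receive only their
subtype block. The default map plants pre-B for the TCF3-PBX1-like subtype
and pro-B for the ETV6-RUNX1-like subtype, leaving BCR-ABL1, MLL, HH and
"other" structureless.

Outcomes depend on expression only through the cluster label: MRD29 is
Bernoulli (defaults 0.13 for cluster 1 and 0.45 for clusters 2-4), and
event-free/overall survival are exponential with per-cluster hazards,
censored by an independent exponential. The default hazards (per day) were
chosen once to give plausible five-year survival for a high-risk pediatric
cohort — e.g. EFS ~0.75 for cluster 1 (1.6e-4/day) down to ~0.35 for
cluster 3 (5.8e-4/day), overall survival uniformly better, censoring
hazard 1.5e-4/day — making cluster 1 the best-prognosis and cluster 3 the
worst-prognosis group.

All three generators are deterministic for a fixed seed; healthy, leukemia
and outcome draws use distinct sub-streams (seed, seed + 1, seed + 2) so
they remain independent but reproducible.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: probe-level array artifacts, batch and
platform effects between cohorts, correlated gene-gene noise, copy-number
driven expression changes, non-Gaussian tails, and any coupling between
expression and outcome beyond the cluster label. Cross-dataset
normalization/harmonization is the user's responsibility; the pipeline
assumes log2-scale input (a `log2_transform` flag applies log2(x+1) for
raw-scale matrices).

## Numerical and design choices

* Duplicate gene ids collapse to the highest-mean row (deterministic, the
  common microarray convention).
* Quartile remainders go to the low-expression bins; all rank ties break by
  sample or gene id, never by storage order.
* ES extremum ties: first index within 1e-12, as above.
* The permutation p uses the add-one rule, so p = 0 is impossible and the
  p floor is visible from `n_permutations`.
* Welch t rather than a moderated statistic: no shrinkage across genes, so
  each gene's rank depends only on its own values; moderated/shrinkage
  statistics and batch correction are out of scope.
* The pipeline's config hash covers the analysis parameters but not the
  output directory, so identical analyses written to different places share
  a hash; manifests contain no timestamps, making byte-identical reruns
  checkable.

## Problem sizes used by the test suite

The suite exercises the pipeline at the default study conditions (3000
genes, 200-gene stage blocks, 20 samples per group, Delta = 2, sigma = 1)
with 199 permutations per enrichment test and 20 replicate cohorts for the
arrest-call property; oracle comparisons run exhaustively (all gene sets
over universes up to 8 genes; all 2x2 tables with total <= 40; all 20
relabelings of 3-vs-3 contrasts), and null-calibration checks use 200-500
replicates. These sizes are the package's choice of a thorough-but-compact
test design; the functions themselves accept arbitrary sizes.

## Known limitations

* The enrichment engine implements the classic GSEA formulation;
  numerical agreement with commercial GSEA tools whose statistic and null
  are undocumented cannot be asserted.
* Arrest calls are only as meaningful as the alpha and the permutation
  resolution allow; with 199 permutations the smallest achievable p is
  1/200.
* The positivity threshold behind the four clusters is a median split by
  default; on cohorts where a marker's distribution is not bimodal the
  split is arbitrary, and the quartile or fixed-threshold methods may be
  more appropriate.
* Probe-to-gene mapping, cross-platform id matching beyond exact
  intersection, Cox regression, competing risks and continuous MRD
  modelling are out of scope.
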