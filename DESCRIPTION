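Package: stagescan
Title: Developmental-Stage Projection of B-Cell Precursor Leukemia Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Relates pre-B-cell-receptor component expression to the
    developmental arrest stage and clinical outcome of B-cell precursor acute
    lymphoblastic leukemia (BCP-ALL). Derives top-N "highly expressed"
    signatures for healthy B-cell stages (CLP, pro-B, pre-B, immature B) and
    leukemia subtypes by supervised one-vs-rest comparison, tests them with a
    native rank-based gene-set enrichment engine (running-sum enrichment
    score, normalized enrichment score, permutation p-value), calls the
    arrest stage from a bidirectional projection grid, classifies samples
    into four clusters from IGHM/IGLL1/VPREB1 positivity, and compares
    cluster outcomes with natively implemented Kaplan-Meier estimation,
    log-rank tests and Fisher's exact tests. A synthetic cohort generator
    with planted stage signatures, marker patterns and cluster-dependent
    outcomes makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    fgsea
Config/testthat/edition: 3
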