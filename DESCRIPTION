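Package: scfidelity
Title: Benchmarking Cell-Type Fidelity of In Vitro Cell Populations
    Against In Vivo Single-Cell References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A single-cell RNA-seq pipeline for scoring how faithfully in
    vitro (e.g. organoid-derived) cell populations represent an in vivo
    reference cell type. Covers UMI count-matrix input/output, quality
    control filtering, depth normalization, variable-gene selection,
    principal component analysis, shared-nearest-neighbor modularity
    clustering, ROC-AUC marker-gene signature derivation, a bimodal
    likelihood-ratio differential expression test, transcriptome-fraction
    gene-signature scoring with Cohen's d effect sizes, and a benchmark
    orchestrator that ranks conditions by signature score. Includes a
    synthetic UMI count simulator with planted marker genes, rare
    populations, and a fidelity dial, so the full pipeline is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    Rtsne,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
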