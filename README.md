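# scfidelity

Benchmarking how faithfully in vitro cell populations represent an in
vivo reference cell type, from single-cell RNA-seq UMI count matrices.

Organoids and other stem-cell-derived cultures are widely used as stand-ins
for rare in vivo cell types (the motivating case: Paneth cells of the
small-intestinal crypt). `scfidelity` turns "does this culture contain the
cell type?" into a quantitative pipeline:

1. **QC and normalization** — retain cells with ≥ 1000 UMIs, ≥ 400 genes
   and < 8000 UMIs, genes detected in ≥ 5 cells; normalize as
   log(count / cell total × 10,000 + 1).
2. **Clustering** — variable genes (mean > 0.14, dispersion > 0.4), exact
   PCA over z-scored variable genes, a shared-nearest-neighbor graph with
   Jaccard edge weights (k = 20, prune ≤ 1/15), Louvain modularity
   clustering.
3. **Signature derivation** — per-gene ROC-AUC for the reference cluster
   versus the rest (exact rank statistic with tie credit); genes with
   AUC > 0.65 form the cell-type signature.
4. **Transcriptome-fraction scoring** — the core statistic: for cell *c*
   and signature *S*, score(c) = Σ_{g∈S} v_cg / Σ_g v_cg, the fraction of
   the cell's log-normalized transcriptome devoted to *S* (all-genes
   score ≡ 1; disjoint signatures add).
5. **Comparison** — Welch t tests and Cohen's d
   (d = (x̄₁ − x̄₂)/s_pooled) between populations, a bimodal
   (zero-inflated normal) likelihood-ratio test for per-gene differential
   expression with Bonferroni correction, per-condition cluster
   frequencies, and z-score heatmap matrices.

A synthetic UMI simulator (multinomial sampling over expression programs
with planted markers, log-normal library sizes, mitochondrial/ribosomal
gene blocks, and a fidelity dial δ that interpolates a program toward the
reference) provides ground truth for every stage.

## Worked example

Generate a synthetic in vivo reference and a matched "organoid" dataset,
then benchmark the organoid against the reference cell type (program 1):

```r
library(scfidelity)

ref <- generate_counts(synthetic_benchmark_spec(n_cells = 600, rng_seed = 11))
qry <- generate_counts(synthetic_benchmark_spec(n_cells = 600, rng_seed = 22))
markers <- gene_list(ref$ground_truth$markers[["program1"]], "canonical_markers")

cfg <- analysis_config(resolution = 0.5, rng_seed = 1)
rep <- run_benchmark(ref$counts, list(organoid = qry$counts),
                     cfg = cfg, ref_markers = markers)
print(rep)
```

```
benchmark_report: 20-gene signature (cluster 2 of reference), 3 query clusters
 cluster n_cells mean_score d_vs_rest p_vs_rest d_vs_reference p_vs_reference
       0     225    0.00927    -1.205  4.79e-51         7.4700      6.29e-177
       1     184    0.00950    -0.989  2.55e-45         7.2680      9.46e-177
       2     171    0.03114     8.643 1.57e-159        -0.0367       7.29e-01
```

Reading the report: the pipeline re-derived a 20-gene signature from the
reference dataset's marker-rich cluster, and query cluster 2 devotes on
average 3.1% of its transcriptome to it — an effect size of 8.6 versus
the other query cells, and statistically indistinguishable from the
reference population itself (d = −0.04, p = 0.73), exactly what a
faithful population should look like. The other clusters sit near the
0.9% background.

The signature itself carries its per-gene AUCs:

```r
print(rep$signature)
#> gene_signature 'reference_signature': 20 genes with AUC > 0.65
#>   top:  g0017 (0.999), g0011 (0.998), g0002 (0.998), g0013 (0.998), g0001 (0.997)
```

`run_fidelity_experiment()` runs the dial version — five conditions at
δ ∈ {0, 0.25, 0.5, 0.75, 1} toward the reference in one merged benchmark
— and reports each condition's best-population score, which recovers the
planted ordering.

A command-line launcher over the same functions is installed at
`inst/scripts/scfidelity-cli` with subcommands `simulate`, `qc`,
`cluster`, `markers`, `de`, `score`, `compare` and `benchmark`; every run
writes a JSON manifest (config snapshot, seed, input digests) sufficient
to reproduce its outputs bit for bit.

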