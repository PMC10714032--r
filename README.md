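# evcargo

Multiomic integration of extracellular-vesicle (EV) cargo with the cell
types of its source tissue, developed around neuronal-to-glial EV
signalling in the retina.

EV carry protein and microRNA cargo between cells, and in degeneration
both the cargo and its cellular origin shift. `evcargo` is for analysts
who have (a) a two-group EV proteomics experiment, (b) cell-type-labelled
single-cell expression for the same tissue, (c) a curated ligand–receptor
table, and/or (d) qPCR/OpenArray Ct panels, and who want to answer: which
cell types produced the vesicle cargo, did that composition shift between
conditions, which cell types do the altered vesicle surfaces target, and
were the microRNAs found in glia made there or imported?

## What is inside

| Stage | Functions | Method |
|---|---|---|
| Proteomics preprocessing | `filter_missing`, `impute_minprob`, `vst_normalize` | group-wise missingness rule (>2 missing in a group removes the protein), left-censored Gaussian imputation (mu = observed minimum, sigma = median per-protein SD of well-observed proteins), monotone variance stabilization |
| Differential expression | `fit_two_group`, `ebayes_moderate`, `top_table` | empirical-Bayes moderated t: posterior variance (d0·s0² + d·s²)/(d0 + d), prior estimated by moments on log-variances |
| Signatures | `derive_markers`, `build_signature_matrix`, `minmax_scale` | one-vs-rest log2 fold-change markers (top 100 by default) from labelled cells; gene-wise [0,1] scaling |
| Deconvolution | `deconvolve_cohort`, `deconvolve_sample` | linear nu-SVR over a ν grid {0.25, 0.5, 0.75}, best reconstruction RMSE, clamp-and-renormalize, NNLS polish; Welch tests on per-type fractions |
| Enrichment | `gsea_preranked`, `ora_hypergeom`, `celltype_target_enrichment` | running-sum ES with permutation p (1000 label permutations, add-one), leading-edge extraction; exact hypergeometric tail |
| Ligand–receptor | `extract_de_ligands`, `map_receptors`, `receptor_modules`, `score_modules` | join DE proteins (p < 0.05, \|logFC\| > 0.5) to an interaction table; score up/down receptor modules across cell types |
| Ct arrays | `filter_unreliable`, `normalize_ct`, `ddct_percent`, `ct_de`, `classify_origin` | Ct/AmpScore reliability filter (>3 unreliable of 12 drops the miRNA), three normalizations, 2^(−ΔΔCt) percent of control, DICER-knockout origin logic |
| Synthetic data | `gen_cell_signatures`, `gen_ev_proteome`, `gen_single_cell_counts`, `gen_ct_array`, `gen_lr_database` | every input above with planted ground truth (convex mixtures, MNAR dropout, negative-binomial counts, Ct shifts, bipartite interaction tables) |
| Orchestration | `pipeline_config`, `run_pipeline` | end-to-end run from one seed, plain-text outputs, JSON manifest |

The deconvolution model treats each sample's linear-scale proteome as a
convex combination of cell-type signatures, m = S·p with p ≥ 0 and
Σp = 1, estimated CIBERSORT-style by support-vector regression on
unit-scaled matrices.

## Worked example

The packaged demo simulates a full study — five retinal cell types, five
EV samples per group, intensity noise 0.1 log2 units, 10% left-censored
missingness — with a planted composition shift from photoreceptors toward
Müller glia and microglia, then runs every stage:

```r
library(evcargo)
res <- run_pipeline(pipeline_config(seed = 1), quiet = TRUE)
print(res$decon$summary, digits = 2)
#>   cell_type mean_control mean_case pct_control pct_case       p   p_adj
#> 1       rod        0.421      0.19        42.1       19 5.1e-05 1.3e-04
#> 2   bipolar        0.265      0.19        26.5       19 1.1e-03 1.3e-03
#> 3  amacrine        0.125      0.18        12.5       18 1.3e-03 1.3e-03
#> 4    muller        0.023      0.21         2.3       21 1.6e-07 8.0e-07
#> 5 microglia        0.166      0.24        16.6       24 8.5e-04 1.3e-03
```

The planted truth had Müller glia at 3% of control cargo and 22% of case
cargo; the estimate (2.3% → 21%, BH-adjusted p = 8×10⁻⁷) recovers both
the composition and the shift. The ligand stage joins the differentially
expressed proteins to the toy interaction table and summarizes the
predicted receptor topology:

```r
res$lr$mapping$summary
#> $n_ligands      [1] 4
#> $n_receptors    [1] 24
#> $n_interactions [1] 27
```

Moderated DE on the stabilized matrix ranks both the spiked effects and
the composition-driven marker changes:

```r
head(top_table(res$de, p_cut = 0.05, lfc_cut = 0.5)[, 1:5], 3)
#>   feature     logFC         t            p        p_adj
#> 1   G0462  3.213021  24.62159 1.114541e-09 8.515091e-07
#> 2   G0734  2.682714  22.49862 2.513438e-09 9.601334e-07
#> 3   G0138 -7.268633 -19.85625 7.724467e-09 1.967164e-06
```

All outputs land as TSV/JSON when `out_dir` is set, together with a
manifest of seeds, parameters and file hashes that makes the run exactly
reproducible.

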