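---
title: "Methods: linking extracellular-vesicle cargo to retinal cell types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking extracellular-vesicle cargo to retinal cell types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evcargo)
```

## The scientific problem

Extracellular vesicles (EV) are nanosized membrane particles that carry
protein and small-RNA cargo between cells. In the retina — as elsewhere in
the central nervous system — EV traffic molecular messages between neurons
and glia, and that traffic changes in degeneration. Three analytical
questions recur in this setting:

1. **Who made the cargo?** Given the EV proteome of a tissue and reference
   expression signatures of its cell types, estimate the fractional
   contribution of each cell type to the bulk cargo, and ask whether the
   composition shifts between a control and a degenerating condition
   (e.g. from photoreceptor-dominated toward Müller glia and microglia).
2. **Who receives it?** EV uptake is mediated by surface ligand–receptor
   binding. Joining differentially expressed EV surface proteins to a
   curated ligand–receptor table and scoring the receptors' expression
   across cell types predicts the tropism of the altered vesicles.
3. **Was a glial miRNA made locally or imported?** A miRNA that rises in
   glia during degeneration may be transcribed there or delivered by EV.
   If the miRNA *falls* when the glial cell loses DICER (and so cannot
   mature any miRNA), it was endogenous; if it persists or rises in the
   knockout, with no primary transcript detectable and no change in the
   precursor, it must have been imported.

`evcargo` implements the quantitative machinery for all three, plus the
supporting preprocessing (proteomics and qPCR/OpenArray), moderated
differential expression, and enrichment statistics. Because the questions
are only testable against known ground truth, the package ships a
synthetic-data generator that emulates each input with planted answers.

## Proteomics preprocessing

Raw intensities are assumed log2-transformed on entry (`ev_matrix()`).
The pipeline order is fixed and recorded in a provenance trail:
log2 → missingness filter → imputation → variance stabilization.

**Missingness filter.** A protein is removed if it has more than
`max_missing_per_group` (default 2) missing values in *either* group.
With five samples per group this keeps only proteins quantified in at
least three samples of every group, so group means and variances are
always estimable.

**Left-censored imputation.** Label-free proteomics misses
preferentially at low abundance: the missing mass sits on the left tail
of the intensity distribution (missing-not-at-random). Accordingly,
missing entries are drawn from a Gaussian centred at the *minimum*
observed intensity of the whole matrix (its 0.0-th quantile), with
standard deviation equal to the median of per-protein standard
deviations among proteins observed in more than half of the samples.
Draws are not truncated — values below the minimum are legitimate, since
the minimum itself is a censoring boundary, not a physical floor. If no
protein is observed in more than half the samples the spread is
undefined and the function stops rather than guessing. Imputation is
seeded explicitly; observed entries are never touched, which the tests
assert bit-wise. Note one consequence for downstream testing: the
*fits* (fold changes, variances) of fully observed proteins are
independent of the imputation seed, but moderated p-values are not
strictly so, because the variance prior is pooled across all proteins
including imputed ones.

**Variance stabilization.** Two steps: (i) per-sample affine calibration
(median-centring and MAD-scaling to the pooled reference), which removes
sample-wise shifts and scale differences; (ii) a monotone
trend-flattening transform — the SD-versus-mean trend across proteins is
estimated by lowess and values are passed through the integral of
1/trend, which is strictly increasing and equalizes the spread along the
intensity axis. The result is re-calibrated to the input's median and
MAD so the numbers stay on a familiar log2-like scale. The residual
trend slope is returned as a diagnostic and warned about above 0.05.
The literature names several variance-stabilizing constructions; the
integral-of-inverse-trend form was chosen because it is monotone by
construction (rank order within each sample is provably preserved, and
tested), assumption-light, and exposes a single interpretable
diagnostic.

## Moderated differential expression

Per feature, a two-group linear fit gives the log2 fold change
(case − control), the pooled within-group variance \(s^2\) and its
degrees of freedom \(d = n_1 + n_2 - 2\). Empirical-Bayes moderation
shrinks each variance toward a prior with weight \(d_0\):

\[
\tilde s^2 = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d},\qquad
t = \frac{\widehat{\mathrm{logFC}}}{\tilde s\sqrt{1/n_1 + 1/n_2}},
\]

referred to a t distribution on \(d_0 + d\) degrees of freedom (capped
at the pooled residual df across features). The prior \((d_0, s_0^2)\)
is estimated by the method of moments on \(\log s^2\), using the
digamma/trigamma moments of the log of a scaled chi-square and a Newton
inversion of the trigamma function; when the log-variances show no
excess dispersion the prior degrees of freedom go to infinity and the
prior variance collapses to the mean variance. Two limits are exact and
tested: \(d_0 = 0\) reproduces the ordinary pooled two-sample t, and
\(d_0 = \infty\) gives a z-like statistic with fixed variance. On
simulated data the whole chain (prior, t, p) agrees with the standard
Bioconductor implementation of moderated t-statistics to
\(10^{-9}\), which serves as an independent cross-check, not as the
implementation. Benjamini–Hochberg adjustment is applied across all
tested features; `top_table()` filters with *strict* inequalities
(`p < p_cut`, `|logFC| > lfc_cut`).

Ct-scale differential expression (`ct_de()`) feeds *negated* Ct values
through the same machinery, because a lower cycle threshold means higher
expression; a planted Ct decrease of 1 cycle in the case group is
reported as logFC = +1.

## Cell-of-origin deconvolution

The bulk EV proteome of sample \(j\) is modelled as a convex mixture of
cell-type signatures in *linear* intensity space,
\(m_j = S\,p_j\), \(p_j \ge 0\), \(\sum_k p_{jk} = 1\). Estimation is
CIBERSORT-style: a linear nu-support-vector regression of the scaled
mixture on the scaled signature columns, over a grid of
\(\nu \in \{0.25, 0.5, 0.75\}\); the fit with the smallest
reconstruction RMSE wins; negative coefficients are clamped to zero and
the rest renormalized to fractions. Two deliberate design choices:

* **Scaling.** Both matrices are bounded to the unit interval before
  regression. The default (`scaling = "signature"`) first rescales each
  mixture column to the signature's overall mean intensity — cancelling
  cross-platform unit differences, e.g. counts-per-million signatures
  against arbitrary MS intensity units — and then divides both matrices,
  per feature, by the signature's per-feature maximum. This is an
  *offset-free* map: dividing preserves the convex mixing equation
  exactly, whereas subtracting a per-feature minimum (plain min-max)
  would inject a spurious offset term whenever the two matrices are
  scaled by different affine maps. The package therefore recovers
  noise-free mixtures exactly (tested to \(10^{-6}\)); independent
  per-matrix min-max scaling remains available as
  `scaling = "separate"`.
* **Polish.** The nu-SVR solver's duality-gap tolerance leaves
  coefficients accurate only to about \(10^{-4}\). After the best-ν fit
  is chosen, a non-negative least-squares refinement restricted to the
  SVR-selected support is accepted whenever it does not worsen the
  reconstruction RMSE. The SVR stage does the robust support selection;
  the polish supplies numerical precision.

Deconvolution consumes the *filtered and imputed* matrix, not the
variance-stabilized one: the monotone trend-flattening transform is
nonlinear and would distort the additive mixing of cell-type
contributions. Differential expression, by contrast, uses the
stabilized matrix.

Per cell type, group shifts in the per-sample fractions are tested with
a two-sided Welch t test (the design's group comparison does not assume
equal variances of compositional estimates) and BH adjustment; means are
also reported as percentages. On synthetic cohorts mirroring the study
design — five cell types, five samples per group, intensity noise 0.1
log2 units, 10% MNAR dropout, a Müller-glia fraction of 3% in controls
versus 22% in cases — the planted shift is detected at
\(p_{\mathrm{adj}} < 0.05\) in effectively every cohort, and mean
absolute proportion errors stay below 0.05 per type.

## Enrichment statistics

**Preranked GSEA.** Genes are ranked by a metric (average abundance,
fold change, or cell-type specificity z-score), descending, ties broken
by gene ID for determinism. Walking down the list, each gene-set hit
adds its normalized weight \(|r|^w / \sum_{\mathrm{set}} |r|^w\)
(default weight \(w = 1\); \(w = 0\) gives the unweighted form) and
every position subtracts the uniform \(1/N\). The enrichment score (ES)
is the running sum at its maximum absolute deviation; a set occupying
the top \(|S|\) ranks at \(w = 0\) scores exactly \(1 - |S|/N\). The
leading edge contains the set members at or before the extremum for
positive ES, and at or after it for negative ES — the genes that carry
the signal. Significance comes from gene-label permutations (default
1000) with add-one correction, so p is never below \(1/(n_{perm}+1)\);
for small universes an exact mode enumerates all \(\binom{N}{|S|}\)
placements, and the tests sweep every universe up to \(N = 8\) with set
sizes up to 3 against an independently coded enumeration. The
normalized ES divides by the mean |ES| of same-signed permutations —
necessary because the weighted statistic's null is asymmetric (the
unweighted one is centred at zero, which the tests verify; the
permutation p-value is calibrated in either case).

**Over-representation.** The exact hypergeometric upper tail
\(P(X \ge k)\) via the distribution function, not simulation.

**Per-cell-type grids.** For target-set-versus-cell-type questions
(miRNA targetomes, receptor modules), genes are ranked per cell type by
the z-score of that type's expression across types, each set is scored
by preranked GSEA, and BH adjustment spans the whole grid. Within a
grid, permutation seeds are derived from the cell type and set size
only, so identical gene sets always receive identical scores.

## Ligand–receptor modules

Differentially expressed EV proteins (strict `p < 0.05`,
`|logFC| > 0.5` by default) are joined to a user-supplied curated
interaction table (the package never downloads one); multi-subunit
receptor complexes are expanded to individual subunit genes, since
module scoring operates on gene-level profiles. Receptors of
upregulated and of downregulated ligands form two modules, which are
scored across cell types with the GSEA grid above (a mean-z permutation
alternative is provided, since figure-level "enrichment scores" in this
literature are sometimes computed either way).

## Ct (OpenArray/qPCR) processing

An entry is unreliable if its Ct exceeds `ct_max` or its amplification
score falls below `amp_min`; a miRNA with more than `max_unreliable`
(default 3) unreliable entries across the panel is dropped, and
surviving stray entries become missing. `ct_max = 35` and
`amp_min = 1.24` are *defaults to be reviewed* against a Ct-versus-AmpScore
density plot of the data at hand — no printed consensus values exist —
and they are stored on the object and echoed by `print()`.

Three normalizations operate directly on the log-scale Ct values:
subtracting each sample's mean Ct (the log-space equivalent of dividing
by the geometric mean), or normalizing to rank-invariant features
(cross-sample rank SD ≤ 1) or to scale-invariant features (CV ≤ 2%),
both falling back to the geometric-mean form with a warning when no
feature qualifies. Relative-log-expression medians before and after are
returned as diagnostics. Which normalization to pin for a final DE call
is left to the analyst; the defaults report `geomean`.

ΔΔCt follows the comparative-Ct convention:
\(\Delta Ct = Ct_{target} - Ct_{ref}\) per sample,
\(\Delta\Delta Ct = \overline{\Delta Ct}_{case} - \overline{\Delta Ct}_{control}\),
reported as \(2^{-\Delta\Delta Ct} \times 100\%\) of control.

**Origin classification** is a total function of the evidence: a miRNA
is *endogenous* if it drops significantly in the DICER-knockout
contrast or its primary transcript is detected; *exogenous* if it rises
or does not change in the knockout while no pri-form is detected and
the pre-form is unchanged; *indeterminate* otherwise (e.g. a
non-significant knockout change alongside a changed precursor).
"Unchanged" for the precursor means \(|logFC| < 0.5\) with
\(p \ge 0.05\) in the upstream evidence preparation.

## The synthetic-data generator

Every generator is a pure function of its parameters and seed —
bit-identical on repeat, and the caller's RNG state is untouched.

* **Signatures** (`gen_cell_signatures()`): a shared log-normal baseline
  (mean 5, SD 1.5 on the log2 scale — mid-dynamic-range intensities
  typical of label-free proteomics) with `n_markers_per_type` disjoint
  marker genes per type elevated by `marker_log2fc` (default 3, a
  strong but realistic one-vs-rest marker effect).
* **EV proteome** (`gen_ev_proteome()`): per sample,
  \(\log_2(\sum_k p_k 2^{sig_k})\) plus spiked group effects plus
  Gaussian noise (default study condition 0.1 log2 units), then MNAR
  dropout: the missingness probability is a logistic curve *decreasing*
  in the noiseless intensity, midpoint at the matrix's lower quartile,
  width 1 log2 unit, with its amplitude tuned so the expected global
  missing rate equals `dropout_rate`. (Tuning the amplitude rather than
  the width is deliberate: with the midpoint pinned at the lower
  quartile, width alone can only produce global rates between 25% and
  50%.) Generated missingness is verifiably left-skewed: the true
  intensities behind missing entries average lower than observed ones.
* **Single cells** (`gen_single_cell_counts()`): negative-binomial
  counts (Poisson at dispersion 0) with gene means proportional to the
  linear-scale signature column, scaled to a library size.
* **Ct arrays** (`gen_ct_array()`): per-miRNA baselines uniform on
  22–32 cycles, replicate noise 0.25 Ct (consistent with qPCR technical
  replicate variability of 0.1–0.3 Ct), a planted Ct shift in the case
  group (negative = upregulation), and a stated fraction of entries
  made unreliable through either a low amplification score or a Ct
  above the ceiling.
* **Interaction tables** (`gen_lr_database()`): a bipartite
  ligand–receptor table with a controlled fraction of receptors shared
  between ligands, so a fixture with six ligands, per-ligand receptor
  counts (7,7,7,7,6,6) and 20% sharing deterministically yields 40
  interactions over 32 distinct receptors.

What the generator does *not* emulate: correlated protein complexes,
batch effects, isotope-labelling artefacts, ambient RNA or doublets in
the single-cell counts, probe-specific amplification chemistry. Passing
tests therefore demonstrate correctness of the algorithms under the
stated generative model, not robustness to every pathology of real
data.

## Numerical choices and degenerate inputs

* Strict inequalities at every DE threshold; a fold change of exactly
  zero is never "differential".
* Ranking ties (GSEA input, marker ordering) break by identifier so
  every run is reproducible; marker ordering prefers higher detection
  fraction first.
* Min-max scaling maps constant rows to zero and flags them instead of
  dropping or erroring.
* A gene set covering the whole ranked universe is scored but flagged
  degenerate; an empty intersection with the universe is an error.
* Deconvolution refuses to return proportions when every SVR
  coefficient is non-positive, and demands at least 50 shared features
  (configurable).
* Proportion estimates are invariant to per-sample intensity offsets up
  to the SVR solver tolerance (~\(10^{-4}\)); the affine part of the
  transform cancels algebraically in the scaling.
* The pipeline orchestrator validates every enabled stage's inputs
  before executing anything, and ragged input tables fail with the
  offending line number.

## Problem sizes

The shipped demo and the verification runs use compact sizes chosen to
exercise every code path with comfortable statistical margins: 500–800
genes, 5 cell types, 50–100 markers per type, 5 samples per group, 40
cells per type, 139-miRNA Ct panels, and 20-cohort repetitions for
recovery and detection-rate estimates. All scale linearly if larger
studies are simulated.

## Known limitations

* Two-group designs only; no covariates, batch terms or random effects.
* Deconvolution reports relative fractions in signature units, not
  absolute vesicle counts; systematic per-type capture biases are not
  modelled and small fractions are estimated with a mild downward bias.
* The ligand–receptor stage consumes whatever interaction table it is
  given; curation quality is inherited, not checked.
* The origin classifier is deliberately rule-based; it propagates, but
  does not model, uncertainty in its inputs.
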