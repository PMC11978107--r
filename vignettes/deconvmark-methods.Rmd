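---
title: "Marker selection and deconvolution benchmarking with deconvmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker selection and deconvolution benchmarking with deconvmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deconvmark)
```

## The problem

Reference-based deconvolution estimates, for each bulk RNA-seq sample, the
fraction of the sample contributed by each cell type, using per-type
expression profiles from a single-nucleus reference. Two ingredients
dominate accuracy in practice: which marker genes enter the signature, and
how predictions are validated. Compositions derived from the snRNA-seq
reference itself are biased by sorting and quality-control losses, so the
benchmark design this package supports validates against an *orthogonal*
assay: multiplexed in-situ imaging of tissue sections, where segmented and
phenotyped nuclei are counted directly. `deconvmark` implements the
marker statistic at the centre of that design, a self-contained
deconvolution baseline, the evaluation metrics, the sensitivity
experiments, and a synthetic generator that reproduces the design's
structure with known ground truth.

## The Mean Ratio statistic

For gene $g$ and target type $k$ with per-type mean expression
$\bar{x}_{gk}$ (log-normalized by default):

$$\mathrm{MeanRatio}(g,k) =
\frac{\bar{x}_{gk}}{\max_{k' \ne k} \bar{x}_{gk'}}$$

A ratio above 1 means the gene is expressed more highly in the target than
in *every* other type; large ratios identify genes whose worst off-target
type is still quiet. This is deliberately stricter than the one-vs-all
contrast (also provided, as Welch tests of the target against the pooled
complement): pooling lets a single highly expressing off-target type hide
behind the complement average, which is exactly the failure mode that
corrupts signature matrices.

Conventions, chosen once and applied everywhere:

* **Expression scale.** Means are taken on log-normalized expression
  (`log2(count × median library / library + 1)`); a `scale = "linear"`
  switch uses library-size-normalized counts instead. The log scale is the
  one marker heatmaps and violin figures are drawn on; ratios of linear
  means are invariant to global depth rescaling, and tests cover both.
* **Zero denominator.** If a gene is silent in every non-target type but
  expressed in the target, the ratio is $+\infty$ and sorts before every
  finite ratio (it is a perfectly specific marker). Silent everywhere
  gives ratio 0.
* **Ties.** Ranks break ties by higher target mean, then lexicographic
  gene id, so all outputs are deterministic.
* **Set rules.** `select_top_n()` takes rank ≤ N per type *then*
  intersects with the gene universe shared with the bulk data (so a type
  can contribute fewer than N genes); `select_over_threshold()` keeps
  ratios strictly above 2 by default; `select_mad_rule()` restricts to
  finite ratios strictly above 1 and keeps ratios above
  median + 3·MAD, with the MAD scaled by the normal-consistency constant
  1.4826 (the constant is exposed because "MAD" is used both raw and
  scaled in the literature). For the threshold rules the universe
  intersection is applied after thresholding, mirroring the top-N rule.
* **FDR.** Benjamini–Hochberg correction is applied within each target
  type independently; one-vs-all ranking uses the standardized log fold
  change (logFC / pooled SD) by default, with raw logFC as an option.

The highly-variable-gene ranking (`select_hvg()`) orders genes by the
residual of their log-expression variance over a running-median
mean–variance trend. This is intentionally a simple trend — adequate as
plumbing for gene-set sweeps, and selections nest across the proportion
argument by construction — not a replacement for a full variance
decomposition.

## Deconvolution baseline and cell-size adjustment

The built-in engine solves, per sample, non-negative least squares
$\min_{w \ge 0} \lVert S w - b \rVert_2$ over the marker genes and
normalizes $w$ to proportions. It is labelled `baseline-nnls` in every
output: it is the package's own self-contained engine so the benchmark
harness runs without external dependencies, and is not a reimplementation
of any published method; published engines plug in through
`external_adapter()`, which validates their output against the
proportion-table invariants (all types present, non-negative, rows within
$10^{-6}$ of 1).

Two numerical choices matter:

* **Scaling.** Each bulk sample is scaled to unit total mass (depth
  removal; the normalized solution is unchanged). The signature is scaled
  by a *single global factor*, not per column: `build_signature()` first
  rescales every cell to the median library size, so each type's
  full-transcriptome profile carries equal mass and the relative
  magnitudes of the marker-restricted columns encode how much of each
  type's RNA the markers capture. Rescaling columns individually would
  destroy that information and silently change what the weights mean —
  with a global scale, the fitted weights are RNA fractions, and the
  cell-size closure below holds. Solving at unit scale also keeps the
  active-set solver's absolute tolerances meaningful.
* **Linear mixing.** Signatures and bulk are mixed and solved on the
  linear scale, since bulk RNA is physically a linear combination of the
  component cells' RNA.

Because a type with larger cells contributes more RNA per cell, linear
deconvolution estimates *RNA fractions*. Given per-type sizes $s_k$ —
median nuclear area, median copies of a total-RNA marker gene (TREG, e.g.
*AKT3*), or the median per-cell product, all computed by
`cell_size_metrics()` — `adjust_for_cell_size()` converts to cell
fractions: $p'_k \propto p_k / s_k$. On synthetic data generated with the
size-aware mixing model the round trip is exact to machine precision when
the true signature is used (the `signature_from_truth()` helper separates
signature-estimation error from solver error).

## Imaging-derived compositions

Segmentation tables are filtered before proportions are computed
(the documented order): cells whose nuclear radius exceeds 5 µm are
excluded as segmentation artifacts, with the radius derived as
$\sqrt{A/\pi}$ when only the area is exported (an explicit radius column
wins; a relative epsilon of $10^{-4}$ absorbs the rounding of exported
areas, which move a derived radius near the boundary by about
$3\times10^{-5}$ relative). Proportions divide each phenotype's nuclei by
the section total, with unphenotyped "Other" cells in the denominator.
Cell-size medians are computed after the radius filter (a flag exposes the
alternative). Because each imaging combination probes only three of the
six broad classes, predicted Oligo and OPC proportions are summed into
OligoOPC before comparison (`merge_types()`), and the `Other` class is
excluded from pairing.

## Evaluation metrics

`metric_suite()` reports Pearson and Spearman correlation, rmse, and
relative rmse (rmse divided by the mean of the reference proportions —
errors on the scale of the quantities being predicted). Correlations pool
all (sample × cell type) pairs, which is the convention behind "overall"
benchmark annotations; grouped records (e.g. per library type × RNA
extraction) are emitted alongside. NA pairs are dropped pairwise with
counts reported; zero-variance vectors yield NA correlations rather than
errors. Within-block consistency uses the relative standard deviation
(σ/μ, $n-1$ denominator — the convention is stated because it is rarely
written down) of the summed excitatory + inhibitory fraction across the
samples of one tissue block.

## Sensitivity experiments

* **Equal-proportion downsampling** draws exactly $n$ cells per type
  without replacement (counts are never resampled) and repeats the
  deconvolution across replicates with seeds derived additively from a
  base seed — simple, auditable, and every replicate is independently
  re-executable bit-identically from the stored seed ledger. The harness
  uses a single per-type count; engine-side cell dropping (which made two
  published engines use 1599 vs 1601 cells) has no analogue here.
* **Donor subsampling** draws random donor subsets and, by default,
  *recomputes* Mean Ratio markers on each subset, keeping top-25 genes per
  type whose recomputed ratio strictly exceeds 1 — marker degradation is
  part of what shrinking a reference does, so fixing the markers would
  understate the effect (a flag provides that ablation).
* **Gene-set sweeps** run any list of marker sets through an engine and
  tabulate metrics per set, the input for marker-set comparison figures.

## The synthetic generator

`simulate_reference()` emulates the structure the benchmark assumes, at
defaults chosen to mirror a broad-cell-type cortical reference: $K = 7$
types (Astro, EndoMural, Micro, Oligo, OPC, Excit, Inhib — the names are
defaults so merge maps and probe masks work out of the box), $G = 2000$
genes, $m = 25$ planted markers per type at 8-fold linear elevation,
$D = 10$ donors × 100 cells per type, negative-binomial counts with
dispersion 0.5 (variance $\mu + 0.5\mu^2$, stated explicitly because
"dispersion" is overloaded), log-uniform baseline means, lognormal
per-cell library sizes (σ = 0.3 around 3000 counts — typical snRNA-seq
depth), and gene-wise lognormal donor effects (σ = 0.2) renormalized to
mean 1 per gene so the population mean equals the stored truth profile —
the minimal structure that makes donor subsampling meaningful. Type
profiles are normalized to unit mass; per-type relative RNA content is
carried separately (defaults give neurons the largest values, consistent
with total-RNA-marker imaging) and enters only the bulk mixing model
$b_g \propto \sum_k \pi_k s_k \mu_{gk}$ (with $s \equiv 1$ when size
weighting is off). Bulk samples get lognormal gene-wise noise, Poisson
sampling (both optional), and cyclic library-type × RNA-extraction labels;
true compositions are drawn per tissue block from a Dirichlet around a
cortex-like base composition with concentration 50, so the six samples of
a block share one truth, as repeated library preparations of one tissue
do. `simulate_cell_table()` emulates segmentation exports: per-section
Dirichlet compositions, an unphenotyped "Other" mass (default 0.2),
lognormal nuclear areas with per-type medians between 22 and 50 µm²
(σ_log = 0.25, which puts roughly 1–2% of cells beyond the 5 µm radius
filter, the order observed in real sections), negative-binomial TREG
copies proportional to type RNA content, and Star/Circle masking of
unprobed types.

What the generator does **not** emulate: library-preparation-specific
gene quantification biases (polyA vs RiboZeroGold differences beyond the
label), ambient RNA, doublets, batch structure beyond donors, or
segmentation errors other than the oversized-radius artifact. Passing
tests therefore demonstrate correctness of the statistics and the closure
of the model chain — not that any engine will achieve comparable accuracy
on real tissue, where reference-bulk platform effects dominate.

## Problem sizes and numerical tolerances

The test suite and acceptance script run the generator at its defaults
(2000 × 7000 reference) for recovery and closure checks, and at reduced
sizes (hundreds of genes, tens of cells per type) where only wiring is
under test; the replicated-downsampling check uses 200 replicates of 300
cells per type against 12 bulk samples. Exact identities (mean-ratio
oracle equivalence, rrmse ≡ rmse/mean) are asserted bitwise; noiseless
solver closures at $10^{-6}$–$10^{-3}$; stochastic recoveries at the
tolerances Monte-Carlo error warrants (for the replicate-mean comparison,
a cell-wise 2-standard-error gate would flag about 5% of cells for an
unbiased estimator, so the aggregate deviation is compared to the
aggregate Monte-Carlo yardstick). Ranks and set rules are deterministic
by construction, so no tolerance applies there.

## Known limitations

* The NNLS baseline ignores measurement error structure (no weighting);
  it is a floor, not a competitor, for published engines.
* Gene identifiers are matched by exact string after stripping version
  suffixes; symbol-level disambiguation is the caller's concern.
* The HVG trend is a running median, not a fitted mean–variance model.
* `CellExpressionSet` supports sparse counts; bulk matrices are dense.
* HDF5-based containers are not read; MTX/TSV/CSV only.
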