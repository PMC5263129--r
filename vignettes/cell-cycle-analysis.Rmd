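---
title: "Cell-cycle analysis of single-cell RT-qPCR profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-cycle analysis of single-cell RT-qPCR profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccycle)
```

This vignette explains the statistical machinery of `sccycle`, the
assumptions behind each stage, the parameters worth tuning, and the design
decisions taken where the underlying methodology left choices open.

## The measurement model

Single-cell RT-qPCR reports, for every cell and panel gene, a
quantification cycle Cq — the PCR cycle at which amplification crosses
threshold. One cycle corresponds to one doubling at 100% efficiency, so Cq
is minus log2 of the initial template amount plus a constant. `sccycle`
anchors that constant by declaring one Cq value (default 25) equal to one
molecule:

$$\text{molecules} = (1+E)^{\,\text{anchor} - \min(\text{Cq},\ \text{cap})},
\qquad E = 1 \text{ by default.}$$

Assumptions worth making explicit:

* **Absolute scale, no normalization.** Because the cell is lysed directly
  into the assay, there is no extraction loss to normalize away, and
  per-cell totals are meaningful. Nothing in the package ever rescales one
  cell relative to another; every downstream statistic inherits this.
* **The cap.** Cq values above the cap (default 25, equal to the anchor) are
  truncated, so every measured well maps to ≥ 1 molecule. Amplification
  beyond that point is considered unreliable single-molecule territory.
* **Imputation at 0.5 molecules.** Missing wells (no amplification, or a QC
  flag for an aberrant melting curve) are below detection, not zero; they
  are imputed at half a molecule, i.e. log2 = −1, and marked in a detection
  mask. Imputed entries never count as "detected" for the 50% filter but do
  enter totals and the cell-cycle index. The anchor, cap, efficiency and
  imputation constant are all arguments of `cq_to_molecules()` so their
  impact can be checked; with defaults their influence is confined to the
  sub-detection tail.

`autoscale()` standardizes each gene to mean 0, sample (n−1) SD 1. It is
applied to **log2** molecules: single-cell expression is closer to
log-normal than normal, and distance-based methods (PCA, Ward, SOM) behave
badly on raw skewed scales. Whether the historical desktop software scaled
log or linear data is not documented; log scale is this package's choice and
is applied consistently. Zero-variance genes cannot be autoscaled and are
dropped with a warning.

## Random-forest classification

Each two-class task (a phase pair, or small vs large) is handled by
ensembles of random forests implemented in compiled code inside the package
(no forest implementation ships with the target R installation). The trees
are classic CART: fully grown (nodes split until pure), Gini impurity
splitting, `mtry` candidate genes drawn uniformly at each node, trained on
bootstrap samples of the cells. Out-of-bag (OOB) majority votes give each
forest a confusion matrix without a held-out set — important when a class
has only ~15–30 cells.

The protocol has two levels:

1. **mtry scan.** Candidate subset sizes (default the full range
   1…n_genes) are each evaluated with a small pilot sub-ensemble (default
   10 forests); the smallest mtry attaining the minimal mean OOB error
   wins. Ties go to the smaller subset — smaller mtry decorrelates trees.
   The pilot forests use a seed stream disjoint from the reporting
   ensemble, so model selection cannot leak into the reported statistics.
2. **Reporting ensemble.** Default 100 forests × 1000 trees at the chosen
   mtry. Confusion matrices, OOB error, balanced accuracy and Gini
   importances are reported as mean ± SD over forests, which separates
   classification uncertainty from forest-sampling noise.

Balanced accuracy (mean of per-class recalls) is the headline metric; with
near-balanced classes it is close to plain accuracy but cannot be inflated
by imbalance. The single Fisher exact p is computed on the ensemble-mean
confusion matrix **rounded to integers** — the mean matrix has fractional
counts and the exact test needs integers; per-forest p-values aggregated by
the median are available behind `fisher_method = "per_forest_median"`.
`fisher_exact_2x2()` implements the standard two-sided convention (sum of
hypergeometric probabilities not exceeding the observed table's, with a
1e-7 relative tolerance) and is cross-checked in the test suite against an
independent implementation.

Two calibration facts that the test suite quantifies rather than assumes:
OOB majority votes are slightly pessimistic for small samples (each tree's
bootstrap, conditioned on the test cell being excluded, leans toward the
other class), so null-data balanced accuracy centres near 0.47–0.48, not
0.50; and balanced accuracy evaluated on 30 + 30 cells carries irreducible
binomial sampling noise of SD ≈ 0.065 regardless of ensemble size.

## Recursive feature elimination

RFE iterates: train an ensemble, drop the gene with the lowest mean Gini
importance, repeat until one gene remains. Design choices:

* **Tie-breaks.** Equal mean importance is broken toward the gene with the
  **larger** importance SD (the less stable gene goes first), then
  lexicographically by gene id, making elimination deterministic.
* **mtry during RFE** is re-scanned every cycle by default
  (`rescan_stride` trades accuracy for speed on large panels).
* **Optimal size — the one-SD rule.** The performance-vs-size curve is
  typically flat near its optimum, and three redundant criteria (OOB error
  minimal, balanced accuracy maximal, Fisher p minimal) are expected to
  agree rather than define a single formula. The default rule picks the
  smallest panel whose mean OOB error is within one ensemble SD of the
  global minimum — parsimony at statistically indistinguishable
  performance. Strict OOB or Fisher minimizers are available via `rule=`.
  A `consistent` flag reports whether the three criteria agree on the
  chosen cycle (balanced accuracy within one SD of its maximum, Fisher p
  within one order of magnitude of its minimum).
* **Directions.** Signature genes are signed by the difference of class
  medians of log2 expression (medians because the distributions are
  skewed); a zero median difference falls back to means, then to +1.

## Subpopulation discovery

The historical workflow gated a subpopulation by eye in a PCA score plot of
the signature genes, then confirmed it with hierarchical clustering and a
self-organizing map. `sccycle` replaces the manual gate with an objective
consensus:

* `pca_gate_clusters()` — k-means in the space of the leading principal
  components, initialized from a Ward cut so no random start is needed;
* `ward_clusters()` — Ward's minimum-variance criterion on Euclidean
  distances (`hclust` method `ward.D2`);
* `som_clusters()` — a 1-D Kohonen map (defaults 3 nodes, 2 neighbors,
  learning rate 0.4, 150 epochs). Weights are initialized evenly spaced
  along PC1; each epoch presents all cells in random order, pulling the
  best-matching node and its neighborhood toward the cell, with both the
  learning rate and the neighborhood radius decaying linearly to zero. The
  exact decay schedule of the original desktop software is undocumented;
  linear decay is this package's choice, and the resulting partitions are
  insensitive to it on separated data (tested).

In the pipeline, Ward and the SOM run on the leading two PC scores of the
autoscaled signature matrix rather than the full gene space: the consensus
stands in for a gate drawn in exactly that score plot, and the projection
denoises the per-gene measurement noise. Both functions accept any matrix,
so the full-gene-space route remains available. Within each partition the
cluster with the lowest mean per-cell score (total transcripts by default)
is the candidate subpopulation, and cells nominated by ≥ 2 of the 3 methods
form the consensus; per-method Jaccard agreement is reported.

PCA components are oriented so the largest-magnitude loading is positive —
a pure sign convention that makes scores reproducible.

The discovered group is characterized two ways. The **volcano** table
computes per-gene log2 fold changes as differences of group means of log2
molecules (means, not medians, so a planted uniform shift is recovered
exactly; medians via `fc_stat`), Mann–Whitney p-values, and colors genes
regulated at least two-fold: red (p ≥ 0.05), yellow (0.05 > p ≥ α/n), green
(p < α/n). The Bonferroni denominator n is the number of tested genes
(0.05/93 ≈ 0.00054 for a full panel) and is an explicit argument because
the panel size after per-line filtering varies. The **totals contrast**
reports 100 × (1 − mean(members)/mean(rest)) with a Mann–Whitney p.

## Cell-cycle index

For a directed signature the per-cell index is

$$\mathrm{index} = \frac{\sum_{g \in \mathrm{up}} \log_2 x_g
  - \sum_{g \in \mathrm{down}} \log_2 x_g}{|\mathrm{up}| + |\mathrm{down}|}$$

— linear in log2 expression, so a global shift of c moves the index by
c(|up|−|down|)/(|up|+|down|), and swapping the sets negates it (both are
tested properties). Imputed values enter at log2 = −1 like any other
measurement.

The crossover point — where the index stops rising and plateaus (cells past
the G1/S commitment) — was originally annotated visually. Here it is
operationalized: cells are ordered by index, and a continuous two-segment
piecewise-linear model is fit by least squares over every admissible
breakpoint (≥ 4 cells per segment); the reported crossover is the fitted
index value at the knot. When the plateau slope is not clearly smaller than
the rising slope (less than half), the fit is flagged `distinct = FALSE` —
a population in smooth transition has no crossover, and the estimator says
so rather than inventing one. Constant input or too few cells yield `NA`
with a warning.

## The synthetic world

`generate_dataset()` draws log2 molecule counts as

baseline(gene) + phase effect + size effect + global phase shift +
cell factor + noise,

with per-gene baselines uniform in `baseline_log2_mean` ± 2 (default 3–7
log2 molecules, the realistic range for a curated qPCR panel), then applies
logistic detection and Cq anchoring. Defaults and their reasoning:

| parameter | default | why |
|---|---|---|
| `groups` | 6 phase×size groups of 15–16 cells | sorted-cell design of this assay type |
| `n_informative_phase` | 20 of 93 | a curated panel is enriched for cycle genes |
| `phase_fold_changes` | 1.5 log2/step | ~3-fold per phase step, typical for cycle-regulated transcripts |
| `gene_noise_sd` | 0.8 log2 | per-gene biological + technical noise of single-cell qPCR |
| `cell_scale_sd` | 0.3 log2 | residual shared per-cell factor *within* a phase×size group; see below |
| `phase_total_log2` | 0.5 log2/step | total transcription roughly doubles G1→G2M |
| `detection_midpoint` | 2 molecules | 50% detection near a few molecules; 0 disables dropout |
| `cq_anchor`, `cq_cap` | 25, 25 | the one-molecule anchor convention |

The shared cell factor deserves a note. Across a whole dataset, totals vary
by one to almost three orders of magnitude; most of that spread comes from
the phase shift and the skewed high tail, and the module's own example
reproduces >10-fold ranges with `cell_scale_sd = 1.5`. The *default* 0.3
models only the residual within-group factor, and is deliberately small
enough that a planted subpopulation with a −1 log2 global shift is
separable from it — the recoverability of that planted structure at default
parameters is part of the stated test contract for this generator.

Planted subpopulations (`subpop_spec()`) shift all genes of a sampled
fraction (`round(fraction × n)`, without replacement) of one phase's cells
by a global log2 amount, plus an extra shift on one marker gene **on top
of** the global shift. Ground truth (true molecule matrix before dropout,
informative genes with directions, members) is returned alongside.

What the generator does **not** emulate: amplification curves and melting
behavior (QC flags are inputs, not simulated), preamplification bias,
gene–gene correlation beyond the shared cell factor, doublets, and
cross-well contamination. A green test on synthetic data therefore
establishes that the algorithms recover the structure they target under
this noise model — not that any particular biological dataset satisfies the
model.

Every stochastic stage derives its seed from one master seed through
`derive_seed()`, so runs are bitwise reproducible and any stage can be
re-executed in isolation.

## Numerical and degenerate-input conventions

* Mann–Whitney tests are exact when there are no ties and the combined
  sample is ≤ 25 cells, otherwise normal approximation with continuity and
  tie corrections; complete ties (zero-variance rank statistic) return
  p = 1. Exactness is verified against full rank enumeration in the tests.
* Spearman correlations use midranks for ties and agree with
  rank-then-Pearson to 1e-12 (tested).
* The combined phase×size encoding orders small before large within each
  phase (ranks 1–6); the ordering is a convention exposed via
  `default_combined_order()`.
* Undefined gene–gene correlations (zero-variance genes) are excluded from
  both numerator and denominator of the positive fraction and counted
  separately.
* OOB vote ties go to the first class; cells never out-of-bag (negligible
  beyond ~50 trees) are assigned the majority class.
* Forest ensembles refuse classes with fewer than 5 cells — OOB estimates
  below that are not meaningful.

## Limitations

* The forest is binary by design; multi-class questions are asked as all
  pairwise comparisons.
* The consensus gate assumes the subpopulation is the *low*-score cluster;
  a high-transcription subpopulation needs a negated score.
* The crossover estimator models exactly one breakpoint; multi-phase
  plateau structure is out of scope.
* Published per-dataset numbers that depend on unavailable raw matrices
  (specific correlation values, confusion counts, gene lists) are not
  reproduction targets; the package's claims are the structural and
  statistical properties its test suite computes.
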