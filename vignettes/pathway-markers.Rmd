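---
title: "Identifying dysregulated pathways with network-constrained marker selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying dysregulated pathways with network-constrained marker selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmark)
library(dplyr)
```

## The problem

Single-gene biomarkers from case/control expression studies replicate
poorly: disease processes perturb coordinated functional modules rather
than isolated transcripts, and gene-level rankings are unstable across
cohorts and platforms. `pathmark` works at the pathway level instead. It
summarizes each annotated gene set as one per-sample *activity* score,
asks which pathways' activities discriminate disease from control, and
constrains the search for a multi-pathway marker panel to pathways that
plausibly interact — so the selected panel is a connected piece of a
pathway crosstalk network, not an arbitrary union of features.

## The model

### Standardization

Each gene $i$ is standardized across samples,
$z_{ij} = (g_{ij} - \bar g_i)/s_i$, with $s_i$ the sample standard
deviation (divisor $n-1$; the convention is stated nowhere by the
procedure itself, and $n-1$ is the usual choice for expression data).
Genes with zero variance cannot be standardized and are removed with a
message. If probe-level data are supplied, probes without a gene
annotation are dropped and multi-probe genes are averaged per sample
*before* standardization. Standardization is applied to all measured
genes before restriction to pathway-mapped genes; the restriction step
(`map_genes_to_pathways()`) only intersects memberships, so the order
affects nothing downstream except which genes exist.

### Pathway activity

For pathway $k$ with member-gene submatrix $Z_k$ (genes × samples), the
activity of sample $j$ is the projection onto the first principal
component:
$$P_{kj} = \mathbf{w}_k^\top \mathbf{z}_{\cdot j}, \qquad
  \mathbf{w}_k = \arg\max_{\|\mathbf{w}\| = 1}
  \operatorname{var}(\mathbf{w}^\top Z_k),$$
i.e. the unit-norm leading eigenvector of the gene–gene covariance of
$Z_k$. The pathway becomes a "meta-gene": one score per sample. PCA is
fitted once on all samples jointly — activities must live on a common
scale for classification — and on the covariance of the standardized
matrix (equivalent to correlation PCA up to the $n-1$ factor). A PC's
sign is arbitrary, so we fix it deterministically: flip so the loadings
sum positive; if the sum is exactly zero, require the loading of the
lexicographically smallest gene id to be positive. Single-gene pathways
are allowed (activity = the gene's standardized row); the minimum
pathway size is configurable (`min_genes`, default 1).

The default reproduces a global fit: PCA is not refit inside each
cross-validation training fold. This mirrors the pipeline ordering the
method prescribes (activities are computed once, then evaluated), at the
cost of a mild optimism since the unsupervised projection has seen the
test samples' expression (never their labels). Users worried about this
leakage can evaluate externally via `evaluate_holdout()`, which applies
markers to a dataset that contributed nothing to selection.

### The pathway interaction network (PIN)

Two pathways are *candidate* neighbors if they share at least one gene
or if some PPI links a gene of one to a gene of the other. A candidate
edge is retained only with condition-specific support in the dataset at
hand:

* a shared gene is differentially expressed — Student's two-sample
  pooled-variance t-test, $p < \alpha$ (default 0.05, strict, no
  multiplicity correction; Welch and Benjamini–Hochberg variants are
  flags), **or**
* a cross-pathway interacting gene pair is strongly co-expressed —
  $|r| > \rho_{\min}$ (default 0.8, strict), Pearson correlation over
  all samples, both classes pooled.

The two routes are combined by OR: evidence of either kind retains the
edge. PPI endpoints need to be distinct genes belonging to the
respective pathways; membership, not exclusivity, is required, so a gene
in the overlap of both pathways can anchor an endpoint. Self-edges are
never created, and the network is unweighted — the evidence (shared
genes, DE shared genes, PPI pairs, co-expressed PPI pairs) is kept per
edge for inspection via `tidy()`.

### Marker selection

Activities feed a forward greedy feature selection scored by repeated
cross-validated classification:

1. evaluate every pathway singly; the best mean CV-AUC becomes the first
   marker;
2. evaluate every unselected PIN neighbor of the selected set appended
   to it; accept the best candidate iff it improves the mean AUC by more
   than `improvement_tol` (default 0.001, a guard against Monte-Carlo
   jitter in the CV estimate);
3. repeat until no candidate improves or the pool is empty.

The classifier is an RBF-kernel SVM (libsvm via e1071; cost $C = 1$,
$\gamma = 1/\text{n features}$ — activities are variance-comparable
after PCA, so no per-fold rescaling is applied). Performance is
five-fold stratified cross-validation: per repeat, out-of-fold decision
values are pooled into a single ROC and its AUC recorded; the mean over
repeats is the score. The AUC itself is the normalized Mann–Whitney
statistic with ties counted one-half.

Design choices in the search, each genuinely open and settled as
follows:

* **Frontier.** After step 1, candidates are neighbors of *any* selected
  pathway (`frontier = "all-selected"`). The literal narrow reading —
  only neighbors of the first marker — is available as
  `frontier = "first-only"`; the default follows the procedure's
  "repeat" logic, which grows a connected subnetwork.
* **Stratification.** Folds preserve class proportions; a plain random
  split risks single-class folds on small cohorts. Unstratified mode is
  a flag.
* **Seed policy.** Repeat $r$ seeds its fold assignment with
  `seed + r`, and fold assignment depends only on the labels — never the
  features — so all candidates within a step are compared on identical
  partitions (paired comparisons, lower-variance accept/reject
  decisions). The alternative — fresh partitions per candidate — would
  inflate `improvement_tol` crossings by unpaired noise.
* **Repeat budget.** Screening candidates at the full 100 repeats is
  expensive and unnecessary for ranking; the search screens at
  `search_repeats = 10` and re-scores the accepted set once at
  `n_repeats = 100`. `faithful = TRUE` forces 100 throughout.
* **Ties** everywhere break to the lexicographically smallest pathway
  id, making the whole trace deterministic given the seed.
* **Stopping.** The stopping rule is on the AUC score itself (the
  stated selection index); accuracy/sensitivity/specificity are
  secondary outputs users can derive from the decision values.

### Baseline and comparison utilities

`rank_genes_ttest()` provides the classical gene-biomarker baseline
(genes ranked by t-test p-value, ties by $|t|$ then id). The returned
genes run through the *same* `evaluate_feature_set()` machinery, one
feature per standardized gene row, so pathway-vs-gene comparisons differ
only in their features. `marker_gene_overlap()` reports the overlap
between the union of marker-pathway genes and an equally sized head of
the gene ranking.

## The synthetic-data generator

`simulate_dataset()` draws from a latent one-factor-per-pathway model:
pathway $p$ has factor $f_{pj} \sim N(\delta \cdot
\mathbb{1}[\text{disease}, p \text{ planted}],\, 1)$ per sample, and a
member gene is $\sqrt{\rho}\, f_{pj} + \sqrt{1-\rho}\,\varepsilon$ with
unit-variance noise, giving exact within-pathway pairwise correlation
$\rho$ and unit marginal variance. A gene in $k$ pathways averages its
factors, rescaled by $\sqrt{k}$ back to unit variance. Consecutive
pathways share a fraction of genes (default 0.2), so the two planted
pathways (defaults `PW01`, `PW02`) are adjacent in any shared-gene
network. The PPI graph is Bernoulli: denser within pathways (0.25) than
between (0.01). The factor model matches the assumption the activity
score relies on — one dominant component per pathway — which is exactly
why it is the right *validation* instrument and an easy instance: real
microarray data add probe-level noise, batch effects, heavy-tailed
intensities, correlated-but-unannotated modules and partially wrong
pathway memberships, none of which are emulated. Passing the planted
recovery tests shows the machinery recovers the structure it presumes;
it does not certify performance on real cohorts.

Default design parameters are the conditions used throughout the
package's validation: 400 genes, 30 pathways of 8–15 genes, 100 samples
per class, $\rho = 0.6$, $\delta = 1.5$. The effect size 1.5 on the
factor corresponds to a standardized activity separation of roughly 1.3
after attenuation by standardization and noise — a strong but not
trivial signal, comparable to what discriminative cancer pathways show.
`make_toy_fixture()` is the fully deterministic counterpart (documented
in `inst/extdata/toy-fixture-README.md`) whose network and selection can
be verified by hand.

## Numerical choices and degenerate inputs

* Zero-variance genes are removed at standardization (reported); a gene
  constant in both classes gets $t = 0$, $p = 1$ in the DE test.
* Missing expression values are rejected by default;
  `impute_missing = TRUE` substitutes per-gene means before
  standardization.
* PC1 is computed by SVD of the row-centered member submatrix —
  numerically preferable to forming the covariance — and validated in
  tests against an explicit eigendecomposition at $10^{-8}$.
* SVM decision values are re-oriented so larger always means more
  disease-like, independent of libsvm's internal class ordering.
* The AUC uses midranks, so heavily tied score vectors (e.g. constant
  features) give exactly 0.5.
* All simulation, fold assignment and selection randomness flows from
  explicit integer seeds; identical inputs and seeds reproduce traces
  bit-identically.

## Problem sizes in the test suite

The packaged validation runs at deliberately small scale, chosen to
exercise every code path with comfortable statistical margins: unit
oracles at up to 20 genes × 40 samples; search-level checks on 10–12
pathway simulations with 30 samples per class; recovery and null
calibration at the full default design (30 pathways, 100 per class, 20
replicates) with 10-repeat screening. A real analysis (880 pathways,
tens of thousands of candidate edges) runs the same code; the PIN
construction and greedy screening dominate and scale respectively with
the number of candidate pairs and with (selected set size) × (frontier
size) × repeats × folds.

## Known limitations

* The first principal component can misrepresent pathways with two
  anti-correlated sub-modules; no multi-component activity is offered.
* Global PCA fitting leaks unlabeled test-sample expression into the
  activity scores (see above); per-fold refitting is deliberately not
  the default to keep scores comparable with the global pipeline.
* The greedy search returns one connected panel; it does not enumerate
  alternative panels of equal performance, and with
  `improvement_tol` near the CV noise floor it can admit an occasional
  spurious neighbor.
* Edge evidence treats DE and co-expression thresholds as hard cutoffs
  (strict inequalities, uncorrected p-values by default) — by design,
  since the network definition is part of the method being implemented.
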