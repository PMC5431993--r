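---
title: "A three-stage systems-genetics pipeline: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-stage systems-genetics pipeline: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sysgen)
```

# Overview

`sysgen` implements a three-stage strategy for nominating candidate causal
genes for a complex trait (the motivating application is obesity studied in
subcutaneous adipose tissue):

1. **Discovery.** GWAS summary statistics are collapsed to gene-wide
   p-values; the nominally significant genes seed a weighted gene
   coexpression network; modules are detected, associated with the trait,
   and interrogated for hub genes, causal structure (PC algorithm + key
   driver analysis) and miRNA regulation.
2. **Replication.** The trait-associated module is tested for preservation
   in independent expression datasets via permutation Zsummary statistics.
3. **Validation.** Module genes are tested for differential expression per
   dataset (moderated t and F) and combined across datasets by Fisher's
   method and pooled standardized mean differences.

Because the original cohorts are not redistributable, the package ships a
synthetic-data generator that reproduces the statistical structure every
stage assumes. All tests and the acceptance script run on generated data
alone.

# The generative model

`simulate_modular_expression()` uses a latent-factor model: module $m$ has a
factor $e_m \sim N(0,1)$ per sample, and member gene $i$ is

$$x_i = w_i e_m + \sqrt{1 - w_i^2}\,\varepsilon_i,\qquad
  w_i \sim U(\ell_{\text{lo}}, \ell_{\text{hi}}),$$

with background genes pure noise and all rows standardized. This model was
chosen because it reproduces the module/eigengene duality a weighted
coexpression analysis assumes: the module eigengene estimates $e_m$, the
module membership $kME_i$ estimates $w_i$, and within-module correlations
are $\approx w_i w_j$. Loadings default to $U(0.5, 0.95)$ so membership
spans the hub/non-hub range.

The reference conditions are 200 samples, 1000 genes, five modules of 40
genes. The BMI-like trait is
$y = \beta_1 e_1 + \beta_2\,\mathrm{std(age)} + \varepsilon$ with
$\beta_1 = 0.6$, $\beta_2 = 0.3$, $\sigma_\varepsilon = 0.74$
(so $\mathrm{cor}(y, e_1) \approx 0.6$, a strong but not deterministic
module-trait coupling); the binary obesity label marks the top 30% of $y$,
a prevalence fixed once for stable power of group comparisons. Replicate
case/control datasets share the discovery loadings and shift every planted
module gene by $-\delta$ (default $\delta = 1$) within-group standard
deviations in the obese group. Targeting miRNAs satisfy
$\mathrm{cor}(\mathrm{miR}, x_{\text{target}}) = -\gamma$ exactly in the
population ($\gamma = 0.5$ by default). One master seed drives everything;
each component derives its own sub-stream, so adding a component never
perturbs another's draws.

What the generator deliberately does **not** emulate: platform noise models,
probe-level effects, marginal expression distributions, batch structure, or
overlapping/nested modules. Passing tests therefore demonstrate that the
machinery recovers planted structure under its own assumptions, not that it
is robust to everything real arrays produce.

# Network construction

The adjacency is $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ with $\beta$
chosen as the smallest power whose connectivity distribution attains a
signed scale-free fitting index $R^2 \ge 0.8$ (`pick_soft_threshold()`;
$\beta = 6$ is the conventional default and is used wherever a fixed power
is needed). The topological overlap measure

$$\mathrm{TOM}_{ij} =
  \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
       {\min(k_i, k_j) + 1 - a_{ij}}$$

scores two genes by direct connection and shared neighbourhoods; $1 -
\mathrm{TOM}$ is the clustering dissimilarity.

## Branch cutting

Modules are branches of the average-linkage dendrogram. The full published
"dynamic hybrid" cutting algorithm has many unstated tunables, so the
package uses a deliberately simple two-pass procedure:

1. a static cut at $0.99 \times$ the maximum merge height — in TOM
   dissimilarities background gene pairs sit near the maximum, so branches
   completing below this line are candidate modules. A candidate of at
   least `min_module_size` (default 30) genes is accepted only if its mean
   intra-branch dissimilarity is below 0.98 of the overall mean: in
   structureless data every dissimilarity is near the maximum and apparent
   branches fail this tightness check, which is what keeps pure-noise input
   entirely unassigned ("grey");
2. unassigned genes are attached to the module of maximal eigengene
   correlation when that $kME > 0.3$.

A cut at a *quantile* of the merge heights was considered and rejected: the
height distribution is dominated by the background plateau, so any high
quantile lands above the module-to-background merges and collapses the tree
into one branch. Module recovery is validated against planted labels
(adjusted Rand index), not label-for-label against any particular published
implementation.

## Module statistics

Eigengenes are first principal components of the standardized module
submatrix, unit variance, sign-aligned so members correlate positively.
Module-trait association is the partial Pearson correlation of eigengene
and trait given age (residual-on-residual), $t$-tested on $n - 3$ df; the
variance explained is reported as the squared partial correlation (the
alternative — a standardized regression coefficient — is noted but not
implemented, as the two differ only in normalization here). Gene
significance (GS) is $|\mathrm{cor}|$ with the 0/1 obesity label
(point-biserial; no rank-based option). Hub genes are either members with
$kME > 0.8$ and $GS > 0.2$ (strict inequalities) or the single member of
maximal intramodular connectivity. A caveat the tests make visible: with 40
loadings drawn from $U(0.5, 0.95)$ the top two are typically within ~0.01
of each other, while the connectivity estimate at $n = 200$ is noisier than
that gap — so the max-connectivity hub is reliably *a* top-loading gene but
not always *the* top-loading gene. The criteria-based definition is robust
to such ties.

# Causal structure and key drivers

`pc_algorithm()` implements the PC algorithm with Gaussian
partial-correlation tests (Fisher z, level $\alpha = 0.01$) in the
order-independent "stable" variant: adjacency sets are snapshotted per
conditioning level and nodes iterated in sorted id order, making the output
invariant to input row order — a property the tests assert. V-structures
are oriented from separating sets, then Meek rules 1–3 are applied to
closure.

Key driver analysis restricts the graph to the module, computes each node's
$h$-layer downstream neighbourhood size $\mu$ (directed edges only; the
conservative reading of "downstream" excludes undirected equivalence-class
edges) and directed out-degree $d$, and nominates causal regulators
($\mu > \bar\mu + \sigma_\mu$) and, among them, key drivers
($d > \bar d + 2\sigma_d$), with sample ($n-1$) standard deviations. The
neighbourhood depth is not fixed by the method's description; the default
is $h = 3$, exposed as a parameter (results at these scales are insensitive
to $h \ge 2$ because the planted DAG has three layers).

The planted causal fixture is a 33-gene layered DAG: a root feeding eight
intermediates, each intermediate with its own independent co-parent and two
downstream genes. The per-child co-parents matter twice: they create
colliders that orient every edge of the equivalence class, and they keep
the root's edges detectable under deep conditioning (if all children shared
one co-parent, conditioning on several siblings would nearly screen the
root off at realistic sample sizes).

# miRNA integration

Candidate interactions are all (miRNA, module-gene) pairs; the correlation
p-value is one-sided for negative correlation by default, because
back-calculation of the motivating study's printed interaction p-values is
consistent with one-sided and not two-sided testing (e.g. $r = -0.29$ at
$n = 199$ gives $1.6\times10^{-5}$ one-sided against a printed
$1.97\times10^{-5}$); sidedness is configurable. The
Benjamini-Hochberg universe is exactly the database-supported pairs — not
all correlated pairs — and selection requires both $r < 0$ and FDR below
the cutoff. A database p-value column, when present, is carried through but
never combined with the correlation p-value (no combination rule is
defined for it).

# Module preservation

`zsummary()` asks whether a discovery module remains dense and similarly
wired in a test dataset. Two density statistics (mean intra-module
correlation and mean soft-threshold adjacency in the test data) and two
connectivity statistics (correlation of intramodular connectivity vectors,
and of vectorized correlation matrices, between datasets) are standardized
against a permutation null in which the module label is reassigned to
random equal-size gene sets drawn from all test-network genes (a draw
identical to the observed set is redrawn). Zdensity and Zconnectivity are
the medians of their pairs and Zsummary their mean. The published statistic
of the same name aggregates a larger set of component statistics whose
composition is not documented in the motivating study; this four-statistic
composite mirrors the architecture at an implementable scale and is
validated by threshold behaviour on synthetic data (preserved modules score
$\ge 10$, destroyed modules $< 2$) rather than by value-matching another
implementation. Two behaviours worth knowing: when a large fraction of the
permutation pool itself carries the planted structure, the connectivity
null is inflated and Zconnectivity compresses toward zero (the density
component still separates cleanly); and Zsummary saturates in the loading
strength once the permutation standard deviation scales with the effect.

# Differential expression and meta-analysis

Per-dataset testing uses limma's empirical-Bayes machinery: per-gene
variances are shrunk toward a moment-matched scaled-F prior and the
moderated t (or moderated F over a contrast set, for multi-time-point
designs) uses the shrunk variance with augmented df. Effects are combined
across studies two ways:

* **Fisher's method**: $\chi^2 = -2\sum_i \ln p_i$ on $2k$ df, where $k$
  counts only the studies in which the gene was measured — per-gene
  bookkeeping, not a global constant (missing studies are dropped and the
  df reduced).
* **Pooled standardized mean difference**: Hedges-corrected $g$ per study
  with variance $(n_A+n_B)/(n_A n_B) + g^2/(2(n_A+n_B))$, pooled with
  inverse-variance weights; the DerSimonian-Laird random-effects model is
  selected per gene when Cochran's $Q$ has $p < 0.05$ *or* $I^2 > 50\%$.
  The permutation p-value re-pools after within-study label permutation,
  with the $+1$ correction $(1 + \#\{|z_b| \ge |z_{obs}|\})/(B+1)$ so no
  p-value is exactly zero.

The pooling algebra is implemented directly (it runs inside the permutation
loop and needs the per-gene model rule); tests cross-check fixed and
random-effects estimates, standard errors and $\tau^2$ against `metafor`.

# Numerical and interface choices

* All interchange formats are plain TSV; every pipeline output carries a
  hash of the configuration so intermediates are attributable and
  diffable. `run_pipeline()` writes a MANIFEST of completed stages even
  when a later stage fails.
* Dendrogram heights are rounded to 12 decimals before cutting: exact
  dissimilarity ties can leave average-linkage heights unsorted by one
  ulp, which the cut rejects.
* Degenerate inputs fail loudly and early: constant gene rows (adjacency,
  GS), singular conditioning sets (partial correlation), rank-deficient
  designs (moderated F, with the aliased columns named), zero pooled SD
  (SMD), p = 0 (Fisher combination, with a pointer to clamp upstream).
  Zero permutation SD yields an infinite Z with a warning rather than NaN.
* KNN imputation follows the classic procedure (neighbour distance over
  shared observed samples, row-mean fallback); $k = 10$ matches the
  common default since the motivating description names the method but not
  $k$.
* LD "high LD" clustering defaults to $r^2 \ge 0.80$ — the printed
  condition ($r^2 \le 0.80$) contradicts "high", so the direction is a
  parameter with $\ge$ as default.

## Problem sizes used in the test-suite

Unit and property tests run at deliberately modest scales chosen for tight
Monte-Carlo behaviour rather than realism: bundles of 200–1000 genes with
40–100-gene modules at 80–200 samples, 50–100 permutations, 99-permutation
nulls for calibration checks, and 100 random 3–5-node SEMs for the
exhaustive conditional-independence cross-check. These sizes keep every
statistical assertion inside well-separated acceptance bands (e.g. planted
module recovery at ARI $\ge 0.8$, null Fisher rejection rate within
$[0.03, 0.07]$).

# Known limitations

* The branch cutter is a two-pass simplification; heavily nested or
  overlapping modules will not be resolved the way the full dynamic-hybrid
  algorithm resolves them.
* Signed networks, biweight midcorrelation and block-wise decomposition
  for very large gene sets are out of scope.
* The PC implementation targets the moderate module scale (tens to a few
  hundred genes); no latent-confounder (FCI) variants, no edge-stability
  bootstrapping.
* Max-connectivity hub selection is noise-limited when top loadings are
  statistically tied (see above).
* Zsummary values are comparable within this implementation only; the
  published thresholds (2 and 10) transfer because the statistic is a
  permutation Z, but component composition differs from other software.
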