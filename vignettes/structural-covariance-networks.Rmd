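---
title: "Structural covariance networks: model, estimation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks: model, estimation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The scientific problem

A structural covariance network treats brain regions as nodes and the
across-subject correlation of a regional morphometric feature (cortical
thickness, gray-matter volume, surface area, mean curvature, metric
distortion, sulcal depth) as the basis for edges.  Regions whose anatomy
co-varies across a population tend to be connected or co-regulated, so the
topology of this network — and how it differs between a patient group and
matched controls — is a group-level phenotype.  `scnet` implements the
full chain from subject-by-region feature tables to group inference.  The
canonical design it serves is two groups of 36 subjects measured on the
148 cortical regions of the Destrieux parcellation (74 per hemisphere;
`destrieux_atlas()` holds the vocabulary), but every dimension is a
parameter.

## The model, stage by stage

**Covariate residualization.**  At every region, an ordinary
least-squares regression removes the linear effects of age, gender
(0/1 dummy-coded) and the subject's total feature value; the residuals
replace the raw values.  An intercept is always included — without it
residual means are nonzero and all downstream correlations are distorted.
The regression is fit *within each group* by default: fitting across
pooled groups would let a group mean difference masquerade as shared
covariance.  `residualize(..., pooled = TRUE)` provides the pooled
alternative for sensitivity analyses.  If a covariate is constant within
a group (gender sometimes is, in small strata) the design is
rank-deficient; the offending covariate is dropped with a warning, never
silently.

**Covariance shrinkage.**  With 36 subjects and 148 regions the sample
covariance is singular and its inverse meaningless.  The Ledoit–Wolf
estimator replaces it by the convex combination
$\hat\Sigma = (1-\lambda)S + \lambda\mu I$ with $\mu = \mathrm{tr}(S)/P$
and $\lambda \in [0,1]$ chosen by the analytic risk-minimizing formula
(clipped).  The scaled identity is the standard target; the estimator
is implemented from the published formulas and agrees with
scikit-learn's independent implementation to $10^{-9}$ on a fixed
fixture (frozen in the test suite).  The sample covariance uses the
$1/n$ divisor, as the shrinkage derivation assumes.

**Partial correlation.**  The association between two regions is their
correlation conditional on all remaining regions, read off the precision
matrix: $\mathrm{pcor}_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$
with $\Omega = \hat\Sigma^{-1}$.  The diagonal is set to 1 by convention.

**Binarization across a sparsity sweep.**  The association matrix is
thresholded proportionally: at sparsity $s$, the strongest
$\lfloor s \cdot N(N-1)/2 \rfloor$ region pairs become edges of an
undirected, unweighted graph.  "Strongest" ranks by absolute partial
correlation by default — negative covariance edges are conventionally
retained by magnitude in structural covariance work — with
`positive_only = TRUE` as the signed alternative.  The default sweep runs
from 5% to 35% in steps of 1% (31 graphs): below ~5% small-world
properties stop being estimable, above ~35% the graph approaches a random
network.  The edge budget uses `floor`; ties at the cut-off break
deterministically toward the lexicographically smaller region pair, so a
rerun always yields the identical graph.  Because all thresholds share
one ranking, the edge sets are nested along the sweep.

**Graph metrics.**  On each binary graph the package computes degree
$k_i$, clustering $C_i = 2e_i/(k_i(k_i-1))$ (defined as 0 when $k_i<2$),
shortest-path length $L_i$ (breadth-first distances), betweenness $BC_i$
(fractional counting over multiple geodesics, endpoints excluded), its
network-normalized form $bc_i = BC_i/\overline{BC}$, and the hub rule
$bc_i > 2$ (strict).  Two conventions deserve a note.  First, the
textbook nodal path length divides the distance sum by the number of
terms; a variant sometimes printed divides by $N$ while summing $N-1$
terms — `graph_path_length(..., paper_denominator = TRUE)` reproduces
that scaling, the default uses the number of terms.  Second, unreachable
pairs are *excluded* from $L$ rather than imputed, and their count is
always reported, so disconnectedness at low sparsity is visible rather
than absorbed.

**Small-world coefficients.**  $\gamma = C_p/C_{rand}$,
$\lambda = L_p/L_{rand}$ and $\sigma = \gamma/\lambda$, where the
reference values are means over an ensemble of degree-preserving
surrogates produced by Maslov–Sneppen double-edge swaps (the stricter
reading of "preserves the degree distribution": the exact degree
sequence is held fixed).  Ten attempted swaps per edge is the mixing
default.  Surrogates are not forced connected; $L_{rand}$ follows the
same unreachable-pair policy as the real graph.  If no surrogate contains
a triangle, $\gamma$ is reported as `Inf` with an explicit flag rather
than an error.  The conventional ensemble size is 1000; examples and
tests in this package use 10–100, which is sufficient for the Monte-Carlo
error of the ensemble means at these graph sizes (it shrinks like
$1/\sqrt{n_{rand}}$, a property the test suite checks directly).

**Group inference.**  Between-group differences in $C_p$, $L_p$ and
$bc_i$ are tested by relabeling: subjects are pooled, pseudo-groups of
the original sizes are drawn, and *the entire pipeline* — per-group
residualization, shrinkage, partial correlation, binarization, metric —
is recomputed for each of (by convention) 1000 relabelings, at every
sparsity.  The 95th percentile of the null differences is the one-tailed
critical value for an increase, the 5th for a decrease; both directions
are reported, without multiplicity correction, so on null data about 5%
of comparisons per tail flag by construction (the output says so).  The
observed difference is computed by the same closure as the permuted
ones, which excludes observed/null asymmetry by construction.
Re-residualizing inside every permutation is deliberate: pseudo-group
membership changes the per-group fits.  Nodal betweenness maps
(`betweenness_difference_map()`) are conventionally read at a single
sparsity of 11% — high enough that all regions have joined the network,
low enough to limit false-positive paths.

## The synthetic cohort generator

`cohort_spec()`/`generate_cohort()` draw two groups from a Gaussian
model: subject features are
`mean + age·slopes + gender·slopes + shift·1[group B] + z` with `z`
multivariate normal.  The generator is first-class, tested code — it is
what makes every downstream stage testable without imaging data.

Choices and what they emulate:

* **Gaussian residuals**, because the partial-correlation machinery only
  uses second moments; heavy-tailed alternatives would be a configuration
  extension, not a default.
* **Block-community covariance** (`make_block_covariance()`): equal
  variance, correlation `r_in` within and `r_out` between contiguous
  blocks, positive definiteness checked by eigendecomposition, not
  assumed.  This mimics the community structure of real cortical
  covariance at the coarsest level.  Defaults: 4 blocks, `r_in = 0.3`,
  `r_out = 0.05`, unit variance.
* **Demographics**: age uniform on 55–80 years, gender Bernoulli(0.5) —
  matched to the demographic ranges of the aging cohorts this design
  serves, and overridable.
* **`total_feature`** is the row sum of region values by default (a
  "total morphological feature value" is most naturally a total);
  `total_feature = "mean"` is the alternative reading, exposed because
  the convention varies between studies.
* **Group effects** enter as an additive mean shift and/or a separate
  covariance template for group B; both zero gives an exact null
  configuration, under which the permutation machinery must reject at
  its nominal rate (the test suite measures this).

What the generator does *not* emulate: spatial autocorrelation beyond
block structure, site/scanner effects, non-Gaussian tails, and any
vertex-level detail — passing tests demonstrate the statistical
machinery is correct and calibrated, not that real cortical data meet
the model's assumptions.

## Numerical choices and degenerate inputs

* All-zero-variance input to `ledoit_wolf()` returns the zero matrix
  with intensity 0 and a warning; the downstream inversion then fails
  with an actionable message instead of producing noise.
* A sparsity that yields zero edges is an error (below the estimable
  range), as is a graph with no reachable pairs.
* `rewire_graph()` on a graph with fewer than two edges warns and
  returns the input unchanged (no legal swap exists).
* Permutation tests refuse `n_perm < 20`: tail percentiles of a smaller
  null are meaningless.  A metric uncomputable at some sparsity inside a
  permutation is recorded as `NA`, never fabricated.
* Seeds: the generator is bit-reproducible given a seed; small-world
  ensembles derive one sub-seed per surrogate from the master seed, so
  results are reproducible and surrogates independent.

## Problem sizes used in validation

The test suite checks the graph metrics exhaustively against brute-force
enumeration on *all* 771 labeled connected graphs with up to 5 nodes,
plus fixed-seed random samples at 6 and 7 nodes (exhaustive labeled
enumeration at 7 nodes exceeds $1.8\times10^6$ graphs, far past the
point of diminishing returns for a definition-level check).  The
permutation calibration uses 200 Monte-Carlo repetitions of 200
relabelings on 40-region, 36-per-group null cohorts — scaled down from
the 148-region, 1000-permutation study design, with the nominal 5% rate
recovered within binomial error.  The acceptance script reports
small-world coefficients on the full 148-region design with a
100-surrogate ensemble.

## Limitations

* Only the Ledoit–Wolf identity-target estimator is provided (no
  graphical lasso); only binary, undirected graphs are analyzed — no
  weighted-graph metrics, efficiency, modularity or rich-club variants.
* No multiplicity correction is applied across sparsities or nodes,
  matching the convention of the study design this pipeline implements;
  the reporting notes expected false positives instead.
* No lattice-reference or minimum-spanning-tree small-world
  normalizations.
* The pipeline starts from extracted region tables; image processing,
  surface reconstruction and rendering are out of scope.

## A worked example

```{r example, fig.width = 7, fig.height = 3.5}
spec <- cohort_spec(n_subjects_per_group = 20, n_regions = 40,
                    n_blocks = 4, r_in = 0.4, r_out = 0.05, seed = 1)
cohort <- generate_cohort(spec)
fit <- scnetwork(cohort, sparsity = seq(0.05, 0.35, 0.05),
                 n_rand = 25, seed = 2)
summary(fit)
plot(fit, which = "smallworld")
```

```{r permtest}
pt <- scn_permtest(cohort, metric = "C", sparsity = c(0.1, 0.2),
                   n_perm = 100, seed = 3)
pt$table
```
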