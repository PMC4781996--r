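# scnet

Group-level **structural covariance network** analysis of regional brain
morphometry, for researchers comparing cortical network organization
between a patient group and matched controls (the motivating design:
amnestic mild cognitive impairment vs. healthy aging, 36 subjects per
group, 148 Destrieux atlas regions, six morphometric measures).

A structural covariance network has brain regions as nodes and
across-subject covariance of a regional feature (cortical thickness,
volume, area, curvature, metric distortion, sulcal depth) behind its
edges. `scnet` implements the full chain:

1. **Residualization** — at every region, OLS removal of age, gender
   (dummy-coded) and total feature value, fit per group.
2. **Ledoit–Wolf shrinkage** — Σ̂ = (1−λ)S + λμI with the analytically
   optimal λ ∈ [0,1], making the covariance invertible in the
   "small N, large P" regime (36 subjects, 148 regions).
3. **Partial correlation** — pcor_ij = −Ω_ij/√(Ω_ii Ω_jj), Ω = Σ̂⁻¹:
   association between two regions conditional on all others.
4. **Proportional thresholding** — at sparsity *s*, the strongest
   ⌊s·N(N−1)/2⌋ pairs by |pcor| become edges of a binary undirected
   graph; swept from 5% to 35% in 1% steps (31 nested graphs).
5. **Graph metrics** — degree k_i, clustering C_i = 2e_i/(k_i(k_i−1)),
   path length L_i, betweenness BC_i, normalized bc_i = BC_i/mean(BC),
   hubs by bc_i > 2.
6. **Small-world coefficients** — γ = C_p/C_rand, λ = L_p/L_rand,
   σ = γ/λ against ensembles of degree-preserving (double-edge-swap)
   rewired surrogates; σ > 1 flags small-world organization.
7. **Permutation inference** — group labels are reshuffled and the
   *entire* pipeline recomputed per relabeling; the 95th/5th percentiles
   of the null differences give one-tailed critical values for
   increases/decreases in C_p, L_p and nodal bc_i at every sparsity.

A synthetic two-group cohort generator (`cohort_spec()` /
`generate_cohort()`) with block-community covariance, covariate
confounds and controllable group effects makes every stage testable
without imaging data.

## Worked example

```r
library(scnet)

spec   <- cohort_spec(n_subjects_per_group = 36, n_regions = 148, seed = 1)
cohort <- generate_cohort(spec)
fit    <- scnetwork(cohort, sparsity = seq(0.05, 0.35, 0.01))
fit
#> Structural covariance network fit
#>   call: scnetwork(data = cohort, sparsity = seq(0.05, 0.35, 0.01))
#>   148 regions, sparsity 5%-35% (31 thresholds)
#>   group A: shrinkage intensity 0.624
#>   group B: shrinkage intensity 0.528
```

The shrinkage intensity is the weight λ placed on the identity target:
with 36 subjects and 148 regions roughly half the estimate comes from
the target, which is exactly why the raw sample covariance would be
unusable here. Small-world coefficients at the 11% nodal-analysis
sparsity, against 100 rewired surrogates:

```r
sw <- small_world(fit$groups$A$graphs[["0.1100"]], n_rand = 100, seed = 2)
sw
#> Small-world coefficients (ensemble of 100 rewired graphs)
#>   C_p = 0.1643   C_rand = 0.1279   gamma  = 1.285
#>   L_p = 2.0589   L_rand = 2.0656   lambda = 0.997
#>   sigma = 1.289  (small-world)
```

Clustering sits 28% above the degree-matched random expectation while
path length is indistinguishable from it (λ ≈ 1) — the small-world
signature. Hubs and a group comparison:

```r
head(hubs(fit, "A", sparsity = 0.11))
#> [1] "lh_GFIOper" "lh_GOTLF" "lh_GOTML" "lh_GTSL" "lh_SCM" "rh_GSP"

pt <- scn_permtest(cohort, metric = "C", sparsity = 0.11,
                   n_perm = 200, seed = 3)
pt$table
#>   metric sparsity node observed crit_low crit_high p_increase p_decrease significant
#> 1      C     0.11 <NA> -0.00101  -0.0171     0.016      0.505      0.495       FALSE
```

Both groups here were drawn from the same distribution, and the test
says so: the observed clustering difference (−0.001) sits in the middle
of the permutation null. `run_pipeline()` chains all stages for several
measures and writes TSV/JSON results plus a reproducibility manifest;
see the vignette in `vignettes/` for the model details, conventions and
design choices.

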