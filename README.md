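# tangentfc

Tangent-space analysis of functional connectome reconfiguration.

## What it does, and for whom

When a person switches cognitive states during fMRI — resting, performing
a stop signal task (SST), resting again — their functional connectome (the
region-by-region matrix of Pearson correlations between BOLD time series)
reorganizes. `tangentfc` is for neuroimaging researchers who want to
quantify that reorganization *per participant* and relate it to
behavioural or risk covariates, using the geometry appropriate to
correlation matrices rather than naive element-wise comparisons.

Full-rank connectomes live on the manifold of symmetric positive-definite
(SPD) matrices. The package implements the full Riemannian pipeline:

- **SPD calculus**: diagonal regularization `C + λI`, matrix
  log/sqrt/inverse-sqrt by symmetric eigendecomposition, the
  affine-invariant (geodesic) distance
  `d_G(A,B) = ‖log(A^{-1/2} B A^{-1/2})‖_F`, tangent projection
  `Ŝ = log(C_ref^{-1/2} S C_ref^{-1/2})` and its inverse retraction, and
  the Karcher (Riemannian) mean found by fixed-point iteration.
- **Connectivity**: the two-scan, five-segment scheme (R1.1, R1.2 |
  SST, R2.1, R2.2; 4-minute segments, calibration and transition volumes
  discarded), Pearson connectome estimation, upper-triangle
  vectorization.
- **Identifiability**: correlation-distance comparison of tangent
  connectomes across all segment pairs (the 5×5 *meta-identifiability
  matrix*), fingerprinting identification rates, and per-participant
  reconfiguration vectors — engaging (R1.2→SST), disengaging (SST→R2.1),
  within-rest (R2.1→R2.2).
- **Models**: a recent-drinking principal component, stop-signal reaction
  time (SSRT), additive multilinear regression of reconfiguration on
  covariates with the cumulative-R² sequence, two leave-one-out stability
  analyses (model-level and reference-level), and a regularization sweep
  that tracks the shrinkage of tangent-coupling variance.
- **Synthetic cohorts**: a seeded generator producing BOLD-like time
  series with subject fingerprints, task and scan effects, observation
  noise and covariate-linked reconfiguration magnitudes, calibrated to a
  published participant-characteristics table — so the whole pipeline is
  testable end to end without any imaging data.

Everything is tidyverse-native: cohort-level functions take and return
tibbles (with list-columns of matrices), fitted models have `tidy()` /
`glance()` methods, and result types have ggplot2 `autoplot()` methods.

## Worked example

```r
library(tangentfc)

cohort <- generate_cohort(synth_config(seed = 42))  # n = 54, p = 50
run <- run_pipeline(cohort, lambda = 0.001, reference_segments = "R1.1")
run
#> Functional reconfiguration pipeline run
#>   subjects: 54, regions: 50
#>   lambda = 0.001, reference = R1.1
#>   mean cross-segment identification rate: tangent 97.6%, manifold 97.8%
#>   engaging (R1.2->SST): mean reconfiguration 0.777, model R^2 0.113
#>   disengaging (SST->R2.1): mean reconfiguration 0.682, model R^2 0.691
#>   within_rest (R2.1->R2.2): mean reconfiguration 0.671, model R^2 0.416
```

The mean reconfiguration ordering — engaging > disengaging > within-rest —
says participants reorganize most when entering the task, less when
leaving it, and least between two post-task rest segments. Tangent-space
identification is perfect across the scan boundary (100% in all
cross-scan blocks on this cohort), where manifold-space comparisons are
degraded by the scan effect. Model coefficients are in natural units:

```r
tidy(run$models$engaging)
#> # A tibble: 8 × 5
#>   term            estimate std_error statistic  p_value
#>   <chr>              <dbl>     <dbl>     <dbl>    <dbl>
#> 1 (Intercept)     0.740    0.0892        8.29  1.11e-10
#> 2 sex             0.00251  0.00866       0.290 7.73e- 1
#> 3 age             0.00143  0.00330       0.433 6.67e- 1
#> 4 education       0.00164  0.00412       0.398 6.92e- 1
#> 5 ssrt           -0.000110 0.0000917    -1.20  2.36e- 1
#> 6 cesd            0.000276 0.00104       0.266 7.91e- 1
#> 7 drinking_score -0.00484  0.00278      -1.74  8.84e- 2
#> 8 fha             0.00725  0.00962       0.754 4.55e- 1
```

The drinking coefficient is negative — heavier recent drinking, smaller
engaging reconfiguration — which is the effect this seeded cohort was
generated with. `autoplot(run$meta)` draws the meta-identifiability heat
map; `compare_references(run$fc)` shows that reconfiguration estimates
barely depend on which rest segment anchors the tangent space;
`loo_model_stability()` / `loo_reference_stability()` quantify coefficient
stability; `regularization_sweep()` tracks how growing λ shrinks tangent
couplings and starves the models of variance.

A thin command-line wrapper lives at `inst/scripts/tangentfc-cli.R`
(`simulate`, `run`, `compare-refs`, `sweep` subcommands).

See the methods vignette (`vignettes/tangent-reconfiguration.Rmd`) for the
model, conventions, generator design and limitations.

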