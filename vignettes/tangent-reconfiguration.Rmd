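---
title: "Quantifying functional reconfiguration in tangent space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying functional reconfiguration in tangent space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A functional connectome (FC) is the region-by-region matrix of Pearson
correlations between parcellated BOLD time series. When a person moves
between cognitive states — resting, then performing a stop signal task
(SST), then resting again — their connectome reorganizes. *Functional
reconfiguration* quantifies that reorganization per person: how far is an
individual's connectome in one condition from their own connectome in
another? `tangentfc` implements a Riemannian-geometry pipeline for this
question, together with a seeded synthetic cohort generator so that every
stage can be exercised and validated without raw imaging data.

Full-rank correlation matrices live on the manifold of symmetric
positive-definite (SPD) matrices, where Euclidean element-wise comparisons
ignore the interrelatedness of the entries. The pipeline therefore:

1. splits each scan into five 4-minute segments
   (R1.1, R1.2 from the first resting scan; SST, R2.1, R2.2 from the
   task-then-rest scan), estimates a Pearson FC per segment;
2. regularizes every FC by adding `lambda` to the diagonal (FCs are
   singular whenever regions outnumber usable time points);
3. computes a reference matrix `C_ref` as the Riemannian (Karcher) mean of
   the first resting segment's FCs — only rest segments anchor the
   reference, so the task's intrinsic structure survives projection;
4. projects every FC onto the tangent space at the reference through the
   whitened matrix logarithm
   \deqn{\hat S = \log\!\big(C_{ref}^{-1/2}\, S\, C_{ref}^{-1/2}\big);}
5. compares tangent connectomes by the correlation distance
   `1 - cor(upper-triangles)`, giving participant-by-participant
   *identifiability matrices* for every segment pair (stacked into the
   5×5 *meta-identifiability matrix*), fingerprinting identification
   rates, and per-participant reconfiguration vectors (the diagonals of
   cross-segment blocks: R1.2→SST is *engaging*, SST→R2.1 *disengaging*,
   R2.1→R2.2 *within-rest*);
6. regresses the reconfiguration vectors on participant covariates (sex,
   age, education, SSRT, CES-D depression score, a recent-drinking
   principal component, and family-history-of-AUD status), reporting the
   additive-R² sequence as predictors enter in a declared order;
7. assesses stability by two leave-one-out schemes (refitting the model
   without one participant; rebuilding the reference without one
   participant and re-projecting everyone) and by a regularization sweep.

# The geometry

The affine-invariant Riemannian metric (AIRM) between SPD matrices,

\deqn{d_G(A,B) = \|\log(A^{-1/2}\,B\,A^{-1/2})\|_F
      = \sqrt{\textstyle\sum_i \ln^2 \lambda_i(A^{-1}B)},}

is invariant under congruence transforms `M A t(M)` and is the geodesic
distance of the SPD manifold. The Karcher mean minimizes the summed squared
geodesic distances to a set of matrices; `riemann_mean()` finds it by the
standard fixed-point iteration (average the whitened logs, retract, repeat)
starting from the arithmetic mean, with a unit step, gradient tolerance
`1e-8` and a 200-iteration cap. Non-convergence is an error carrying the
last gradient norm — the package never silently returns an uncentred
reference. All matrix functions go through symmetric eigendecomposition
with forced re-symmetrization `(X + t(X))/2` after every recomposition,
which bounds floating-point asymmetry drift across the long chains of
products the pipeline builds; eigenvalues are never clipped, so a singular
input is always surfaced to the user, who must regularize explicitly
(regularization is an analysis parameter here, not a numerical patch).

In the whitened coordinates of step 4 the AIRM inner product at the
reference is the plain Frobenius one, so Euclidean distances between
tangent images approximate geodesic distances near the reference
(first-order flatness; the test suite verifies 1% agreement within
geodesic radius 0.01). Projection also removes what the matrices used to
build the reference share — the *whitening* effect, visible as the
reference segment's diagonal block having the largest mutual distances in
the meta-identifiability matrix.

# Conventions and parameters that matter

* **Segment scheme.** Volume indices are 0-based, half-open. At TR 1.2 s
  the scans hold 400 and 610 volumes. The first `ceiling(7 / TR)`
  calibration volumes of each scan are excluded from the *first* segment
  only (R1.1 and SST are 6 volumes short at TR 1.2 s) so later segment
  boundaries stay at the nominal 4-minute marks and the printed totals are
  preserved; the 12-s post-task transition (10 volumes) is discarded
  between SST and R2.1. The alternative — shifting all boundaries by the
  calibration length — cannot coexist with five full nominal segments in
  the printed scan lengths.
* **Regularization `lambda`** (default 0.001): added to the FC diagonal
  before any manifold operation. Larger values shrink the range and
  variance of tangent couplings; `regularization_sweep()` exposes the
  default grid `1e-4 … 10`, over which the pooled tangent-element variance
  decreases monotonically.
* **Vectorization** excludes the diagonal (an FC diagonal is identically
  1; tangent matrices follow the same convention for comparability) and
  scans the upper triangle row-major; exposed as a flag.
* **Identification rate** averages the row (A→B) and column (B→A) argmin
  directions; ties count as misidentification. The direction convention is
  a package choice — symmetric summaries are standard in the
  fingerprinting literature — and only matters when rates differ between
  directions.
* **SSRT** uses the linear-interpolation (type-7) percentile; the
  percentile definition is swappable via `type`.
* **Drinking score**: first principal component of standardized AUDIT,
  drinking days, drinks/week and drinks/drinking-day, sign-fixed so the
  AUDIT loading is positive.
* **Predictors are not standardized** by default (coefficients in natural
  units); `standardize = TRUE` is available. The additive-R² sequence
  depends on the declared predictor order; the final model does not, and
  the default order is sex, age, education, SSRT, CES-D, drinking, FHA.

# The synthetic cohort generator

`generate_cohort()` emulates the two-scan rest/task/rest design: each
subject carries a latent SPD base `B_s` (shared low-rank group structure
plus a subject-specific rotation — the *fingerprint*), the task segment
displaces `B_s` along a common task direction with per-subject magnitude
`m_eng`, scan-2 segments add a common scan offset, and post-task rest
returns to base with per-subject completeness governed by `m_dis`. Time
series are multivariate normal draws from the segment covariance plus
isotropic observation noise. Covariates are calibrated to the published
participant-characteristics table (for example age ~ N(22.64, 1.62²)
clipped to 21–26, 23/54 FHA-positive, drinking days 16.17 vs 10.54 by
family-history group); the four drinking measures share a latent
propensity (loading 0.75) so their first principal component is meaningful
(~65–75% variance), as in real questionnaire batteries.

Displacement strengths are expressed as the per-coupling RMS of the
whitened tangent displacement — the same scale as finite-scan sampling
noise (~`1/sqrt(T)` ≈ 0.07 per element for 4-minute segments). The
defaults (fingerprint 0.09, task 0.07, scan 0.05, observation noise SD
0.8) put the cohort in the realistic regime: within-subject cross-segment
tangent correlation distances near 0.5–0.8, between-subject distances near
1, near-perfect fingerprinting, and task transitions clearly larger than
within-rest ones. The mean return to rest is complete
(`disengage_fraction = 1`), which makes engaging > disengaging >
within-rest a structural property of the generator rather than a tuned
outcome.

The default generating covariate effects are the two headline channels —
drinking reduces the engaging magnitude (`beta_drink_engage = 0.65` on the
log scale) and family-history-positive status reduces the disengaging
magnitude (`beta_fha_disengage = 0.6`); sex, CES-D and education effects
are available as knobs but default to zero. Two reasons: (a) these effect
sizes are the smallest giving reliable sign detectability at n = 54
(mean |t| ≈ 2.5), while keeping the log-normal magnitude spread
physiological (≈ e^±1.3); and (b) a covariate entering *both* transition
exponents (as CES-D would) can have a non-monotone observed effect,
because the correlation-distance normalization couples the two
transitions — the task-vector norm appears in the denominator of both —
so "recover the generating sign" is only well-posed for channel-separated
effects. This coupling is a genuine property of correlation-distance
reconfiguration, worth knowing when interpreting real fits.

## What the generator does and does not emulate

It reproduces the statistical structure the analysis assumes: stable
fingerprints, condition and scan effects, covariate-linked reconfiguration
magnitudes, sampling noise from finite scans. It does **not** model
hemodynamics, autocorrelated BOLD spectra, head motion, or physiological
nuisance; its scan effect is a single common direction, which understates
the subject-by-session interactions of real data. Consequently, passing
tests demonstrate that the *pipeline* recovers what it is supposed to
recover under its own assumptions — not that real fMRI satisfies those
assumptions. One visible consequence of the single-direction scan model:
a scan offset strong enough to dramatize manifold fingerprinting failure
also makes engaging reconfiguration estimates sensitive to which rest
segment anchors the reference, a trade-off real data apparently do not
exhibit as sharply.

## The observed-scale estimand for calibration checks

Finite-scan correlation-distance estimates are nonlinearly compressed
relative to the latent geometry (sampling noise inflates the denominator
of the correlation), and the engaging effect enters the distance partly
through the task-vector norm. A regression on observed reconfiguration
therefore does not target the latent-geometry coefficient, and checking
CI coverage against it would fail by construction. `mc_reconfig_refits()`
defines the honest estimand: redraw the observation noise (same subjects,
covariates and latents), re-run the full measurement chain, refit; the
mean of the per-draw coefficients is the generating effect on the observed
scale and their spread its Monte-Carlo uncertainty. The calibration test
compares each fitted CI to that estimand using a Welch–Satterthwaite
combined standard error.

# Validation problem sizes

The test suite exercises the numerics at the study scale (n = 54, p = 50)
for the fingerprinting, ordering, whitening and reference-robustness
checks; regression-recovery calibration runs 100 replicate cohorts at
n = 54 with p = 32 and 8 noise redraws per replicate (the feature count
must stay near the study scale — distance estimates over p(p-1)/2
couplings are what give the design its power — while the redraw count
only enters through the Welch-combined standard error), and type-I-error
calibration 200 null cohorts at p = 16 — sizes chosen so the full suite
completes on a laptop while keeping every check at the design's n.

# Worked example

```{r, eval = FALSE}
library(tangentfc)

cohort <- generate_cohort(synth_config(seed = 42))
run <- run_pipeline(cohort, lambda = 0.001, reference_segments = "R1.1")
run                     # identification rates, mean reconfigurations, R²

tidy(run$models$engaging)      # coefficients, SEs, p-values
glance(run$models$disengaging) # R², adjusted R², df
autoplot(run$meta)             # 5x5 meta-identifiability heat map

# stability and robustness
loo <- loo_model_stability(run$reconfig$engaging, cohort$covariates)
autoplot(loo)
compare_references(run$fc)     # reconfiguration under R1.1 / R2.2 / both
```

# Known limitations

* Only the AIRM/tangent geometry is implemented (no log-Euclidean or
  Bures–Wasserstein alternatives), matching the analysis it supports.
* The Karcher iteration uses a unit step; for extremely dispersed or
  ill-conditioned matrix sets it may fail to converge — it then errors
  rather than damping automatically.
* Correlation distance couples transitions that share a segment (the norm
  of the shared segment's tangent vector enters both), so covariate
  effects on one transition can bleed into models of the other; the
  generator's default effects are channel-separated for exactly this
  reason.
* p-values are reported unadjusted, matching standard practice for these
  models; no multiple-testing correction across transitions is applied.
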