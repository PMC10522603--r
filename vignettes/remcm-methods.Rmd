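---
title: "Receptor-enriched multifactorial causal modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-enriched multifactorial causal modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remcm)
```

## The model

`remcm` treats the brain as a dynamical system of regions of interest, each
characterized by six co-evolving, imaging-derived biological factors: gray
matter density (GM), neuronal activity (fALFF), presynaptic dopamine
(DAT-SPECT), directed and undirected white-matter microstructure (FA, MD),
and dendrite density (t1/t2 ratio). For one subject, the state of factor $m$
at region $i$ and time $t$ is $S_{m,i}(t)$, on a z-scored scale. Its rate of
change is modeled as locally linear and time-invariant:

$$
\frac{dS_{m,i}}{dt} \;=\;
\sum_{n=1}^{6}\Bigl(\alpha_0^{n\to m} + \sum_{k=1}^{15}\alpha_k^{n\to m}\,r_{k,i}\Bigr) S_{n,i}(t)
\;+\; \sum_{k=1}^{15}\alpha_k^{m}\, r_{k,i}
\;+\; \alpha_{\mathrm{prop}}^{m}\, p_{m,i}(t),
$$

where $r_{k,i}$ is the z-scored density of receptor $k$ at region $i$ and

$$
p_{m,i}(t) = \sum_{j \ne i} C_{ij}\,[S_{m,j}(t) - S_{m,i}(t)]
$$

is the net spread of factor $m$ along the symmetric anatomical connectome
$C$. The interaction coefficients $\alpha_k^{n\to m}$ quantify receptor
mediation of one factor's effect on another's progression — the scientific
quantity of interest.

The left-hand side is observed as the finite difference of successive
imaging visits, $(S(t) - S(t'))/(t - t')$, and the coefficients are
estimated by ordinary least squares, separately per subject and per target
factor. With an intercept, each factor model has
$6 + 6\times 15 + 15 + 1 + 1 = 113$ coefficients (678 per subject over the
six factors); the neuroimaging-only comparison model keeps the six direct
factor terms, the propagation term and the intercept (8 columns); the
single-receptor variant keeps one receptor's interaction and density terms
(15 columns). Predictors are standardized (mean 0, SD 1) within each model's
rows, so coefficients read as relative effect sizes; raw-scale coefficients
are recovered by back-transformation and used for parameter-recovery
checks. $R^2$ is computed against the subject-wise mean rate pooled over
regions and intervals, and stored unclipped.

Design conventions worth stating explicitly:

* **Predictor timing.** States on the right-hand side are taken at the
  interval's start visit (forward difference); `states_at = "midpoint"`
  averages the two visits instead.
* **Standardization.** All z-scoring uses the population (divide-by-$n$) SD.
  Imaging is standardized per modality, pooled across subjects, regions and
  visits, which preserves between-subject severity differences that the
  per-subject models must then explain; a per-subject option exists
  (`zscore_imaging(scope = "subject")`).
* **Degenerate columns.** Constant design columns are zeroed and flagged;
  near-collinear columns (absolute correlation above 0.9999 with an earlier
  column) are pruned with zero coefficients, so every fit reports the full
  113-vector.
* **Symmetry.** The propagation operator assumes a symmetric connectome and
  is conservative: $\sum_i p_{m,i} = 0$ exactly, which the tests verify to
  $10^{-10}$.

## Validating the receptor contribution

Two complementary tests ask whether the receptor terms earn their 105 extra
parameters. The nested F-test compares full and restricted fits on the same
rows, $F = \frac{(RSS_r - RSS_f)/(p_f - p_r)}{RSS_f/(n - p_f)}$. The
permutation test refits the full model with receptor maps shuffled across
regions (independently per receptor) and ranks the observed $R^2$ in the
null distribution with the add-one convention,
$p = (1 + \#\{R^2_{null} \ge R^2_{obs}\})/(B + 1)$, one-sided, so $p$ can
never be zero. Permutation p-values are combined across subjects with
Fisher's method. Null refits run through exactly the same design-assembly
code path with the permuted matrix injected, which guards against leakage
bugs.

Two honest caveats, both verified empirically by the calibration studies:

* The F-test is exact only under strictly exogenous predictors. With more
  than one inter-visit interval, later predictors contain earlier noise
  (the finite-difference targets and the states share visits), and the
  F-test over-rejects. The calibration study therefore uses single-interval
  designs with process noise — the error model under which the test's null
  distribution is exact. The same caveat applies to any dynamical-systems
  regression fit by OLS, including on real data.
* The map-shuffling null ignores spatial autocorrelation: a spatially
  smooth receptor map is not exchangeable with its shuffles when the
  imaging data are themselves spatially structured. Calibration is
  therefore assessed with spatially unstructured maps
  (`smoothness = 0`); autocorrelation-preserving nulls (spin tests) are out
  of scope.

## Population stability and effect summaries

Per coefficient, the across-subject mean gets a confidence interval
(t-interval by default, percentile bootstrap optionally); a mechanism is
*stable* when the interval excludes zero. Within each factor, mean absolute
coefficients of the stable set are normalized to shares, and
`effect_size_summary()` aggregates them by receptor family via a versioned
YAML map. No multiple-testing correction is applied across the 678
parameters at this stage — the confidence level is the only screen, which
is deliberate and should be kept in mind when reading the tables.

## Mechanism–symptom axes

Rates of clinical decline are the per-assessment OLS slopes of 11 scores
against examination time. Both the subject-by-678 coefficient matrix $X$ and
the subject-by-11 slope matrix $Y$ are adjusted for baseline age, education
and sex (residualized on an intercept plus covariates, then z-scored), and
the cross-covariance $C = X^\top Y/(n-1)$ is decomposed as $C = USV'$.
Covariance explained per component is $s_i^2/\sum_j s_j^2$ (a
`"linear"` convention $s_i/\sum s_j$ is available, as the printed fractions
in this literature are ambiguous between the two). Significance comes from
shuffling the subject correspondence between $X$ and $Y$; each permuted
decomposition is aligned to the observed axes by orthogonal Procrustes
rotation computed on the well-conditioned symptom side (11 columns) and
applied to both sides, with aligned singular values taken as column norms
of the rotated, singular-value-weighted loadings. Family-wise error is
controlled with the max-statistic null: each component's $s_i$ is compared
to the permutation distribution of the largest aligned singular value.
Loading stability uses subject-resampling bootstrap with the same
alignment; a loading is stable when its percentile interval excludes zero,
and bootstrap ratios (loading / replicate SD) are capped at $10^6$ with a
degeneracy flag. Per-parameter variance along a significant axis is
$U_{ij}^2 / \sum_j U_{ij}^2$ over the stable set.

## Regional receptor influence

For one receptor and factor, the single-receptor and neuroimaging-only
models are fit per subject; residuals are internally studentized
($r_i/\hat\sigma\sqrt{1-h_i}$, with leverage from the fit's QR), pooled per
region across subjects and intervals, and compared by the Wilcoxon rank-sum
of the restricted model's absolute residuals in the combined sample
(midranks for ties; larger statistic = receptor model fits better there).
Comparison is on absolute residuals because the question is one of
magnitude of misfit. Region-shuffling the receptor's map and refitting
yields the per-region null; the map stores $z = (w - \mu_0)/\sigma_0$ while
the significance flag uses the one-sided empirical add-one $p < 0.05$. The
restricted model contains no receptor terms, so its residuals are computed
once and reused across permutations.

## The synthetic cohort generator

Every inferential stage is exercised against generated cohorts with known
ground truth, emulating the statistical structure of the data this analysis
targets: ~95 regions, 6 co-evolving factors, 3–4 visits about half a year
apart, receptor maps z-scored across regions, and clinical decline carrying
a planted low-rank dependence on the model parameters.

* **Receptor maps** are multivariate normal draws over a ring lattice with
  neighbor correlation `smoothness` (default 0.3), column z-scored;
  pairwise inter-receptor correlations are kept below 0.9 by redraw.
* **Connectomes** are symmetric, zero-diagonal Bernoulli(`density`) graphs
  with gamma-distributed weights.
* **Coefficients.** Each factor has 15 nonzero population mechanisms: its
  own decay term (drawn as $-U(0.4, 0.8)$ per year, strong enough to keep
  the dynamics diagonally dominant), a positive propagation coefficient
  $U(0.005, 0.02)$, and 13 further mechanisms of magnitude $U(0.04, 0.10)$
  with random signs. Magnitudes are bounded away from zero so that
  "recovering the support" is a well-posed question. Subject-level
  deviations have a low-rank latent structure: three disjoint mechanism
  modules with $\pm 1/\sqrt{g}$ loadings (orthonormal, equal column norms),
  scaled by 0.3, plus independent jitter (SD 0.01). Disjoint equal-norm
  modules make the planted axes eigendirections of the parameter
  correlation, so column-wise z-scoring in the downstream analysis does not
  distort them. The propagation coefficient instead gets a proportional
  (30%) jitter: additive deviations on a ~0.01/yr coefficient would
  routinely flip it into explosive anti-diffusion.
* **Trajectories** start from standard-normal baseline states and are
  integrated by explicit Euler (dt = 0.01 y, an order of magnitude below
  the inter-visit scale) with i.i.d. Gaussian observation noise (SD 0.05 on
  the z-scale). A `"discrete"` mode takes one step per inter-visit interval
  so that finite differences satisfy the regression model exactly: the mode
  used by parameter-recovery studies, which isolates estimator correctness
  from integrator error. A `"process"` noise model perturbs the rates
  rather than the recorded states. A spectral guard probes the homogeneous
  dynamics over the horizon and rescales all coefficients (with a message)
  if trajectories would grow more than 50-fold.
* **Clinical records.** Slopes are built from the planted axes — strength
  1.0 and 0.6 (score units per year per SD of latent score) on two planted
  components — plus a mild covariate dependence and slope noise (SD 0.5);
  scores follow exact lines so `clinical_slopes()` recovers the planted
  slopes identically.
* **Regional influence studies** add a region-restricted interaction
  $\beta\, r_{k,i} S_{n,i}$ ($\beta = 0.5$) to a designated subset of
  regions, on top of a receptor-free base truth, so that the single-receptor
  model improves the fit only where the pathway was planted.

What the generator does *not* emulate: realistic cortical geometry and
hemispheric symmetry, scanner/site batch effects, missing imaging
modalities, and non-Gaussian or spatially correlated observation noise.
Passing the synthetic studies demonstrates that the estimators and tests do
what they claim under the model's own assumptions at realistic size and
noise — not that the model is true of any particular dataset.

## Problem sizes used by the verification studies

The shipped studies use: a reference fixture of 20 subjects × 95 regions ×
4 visits (285 design rows, 172 residual df for the full model); recovery
checks at 30 regions × 3 intervals for the 8-parameter models and
95 regions × 4 intervals for the 113-parameter models (noise $10^{-6}$);
calibration with 500 replicates (F-test on single-interval exogenous
designs; permutation tests at 40 regions with 200 permutations); axis
recovery with 50 replicates of 80 subjects; and influence studies at 30
regions (null, 15 replicates) and 95 regions (power, planted subset of 20
regions). A fixture must satisfy `regions × intervals > 113` for the full
model to be identified — 30 regions with 3 intervals cannot carry it, which
is why the reference fixture uses the study-scale region count.

## Known limitations

* OLS on finite differences is biased when observation noise enters the
  predictors (errors-in-variables); the package quantifies but does not
  correct this. Recovery is exact in the noiseless limit.
* The permutation null for receptor informativeness does not preserve
  spatial autocorrelation.
* Stability screening applies no multiplicity correction.
* Clinical slopes assume linear decline over the observation window.
* Missing imaging cells are rejected rather than imputed; missing clinical
  scores are handled per assessment by slope-on-available-visits.
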