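# remcm

Receptor-enriched multifactorial causal modeling of longitudinal
neuroimaging in R.

Neurodegenerative diseases such as Parkinson's disease reorganize the brain
across several biological dimensions at once — gray matter density, neural
activity, dopamine transporter availability, white-matter microstructure,
dendrite density — and the vulnerability of a brain region plausibly depends
on its local neurotransmitter-receptor architecture. `remcm` is for
researchers who have (i) longitudinal regional values of several
imaging-derived biological factors, (ii) a regional receptor-density atlas,
and (iii) an anatomical connectome, and who want to ask: *which
receptor-mediated interactions between biological factors drive each
subject's disease progression, and how do those mechanisms relate to
clinical decline?*

## The model

Per subject, the rate of change of factor *m* at region *i* follows a
locally linear dynamical system:

```
dS_mi/dt = Σ_n (α0^{n→m} + Σ_k α_k^{n→m} r_ki) S_ni(t)   local + receptor-mediated interactions
         + Σ_k α_k^m r_ki                                 direct receptor effects
         + α_prop^m Σ_j C_ij (S_mj − S_mi)                connectome propagation
```

with `r_ki` the z-scored density of receptor *k* at region *i*. The rate is
observed as the finite difference of successive visits and the 113
coefficients per factor (678 per subject over 6 factors) are estimated by
OLS. Around this core the package provides:

- **Validation** — nested F-tests of the full (113-column) against the
  neuroimaging-only (8-column) model, permuted-receptor-map null
  distributions for R², Fisher's combination across subjects.
- **Population stability** — confidence intervals for each mechanism across
  subjects and effect-size shares by receptor family.
- **Mechanism–symptom axes** — SVD of the cross-covariance between the 678
  coefficients and 11 clinical decline slopes (covariate-adjusted), with
  Procrustes-aligned permutation significance (max-statistic FWE) and
  bootstrap loading stability.
- **Regional influence maps** — per-region Wilcoxon rank-sum comparison of
  studentized residuals between single-receptor and neuroimaging-only
  models against permuted-map nulls.
- **A synthetic-cohort generator** with known ground truth (coefficients,
  sparse support, planted mechanism–symptom axes) for end-to-end
  verification.

## Worked example

```r
library(remcm)

# a synthetic cohort at study scale: 20 subjects, 95 regions, 6 factors,
# 15 receptors, 4 visits 0.5 y apart, with known ground truth
sim <- simulate_cohort(n_subjects = 20, seed = 42)
fit <- remcm(sim$cohort, normalize_imaging = FALSE)
summary(fit)
#> Per-factor R^2 of the full re-MCM models
#>  factor mean_r2   sd_r2 median_r2 min_r2 max_r2 n_fits
#>      GM   0.958 0.01148     0.959  0.931  0.975     20
#>   fALFF   0.956 0.00818     0.957  0.935  0.967     20
#>     DAT   0.966 0.00985     0.967  0.942  0.979     20
#>      FA   0.972 0.00579     0.972  0.956  0.981     20
#>      MD   0.941 0.01341     0.940  0.913  0.963     20
#>    t1t2   0.970 0.00750     0.971  0.957  0.981     20
```

Does receptor information earn its parameters? Compare nested models and
rank the observed R² against permuted receptor maps:

```r
restr <- remcm(sim$cohort, receptor_subset = character(0),
               normalize_imaging = FALSE)
nested_f_test(fit$fits[["S001"]][["GM"]], restr$fits[["S001"]][["GM"]])
#> F = 3.97 on (105, 172) df, p = 6.1e-16

permutation_test_r2(sim$cohort, "S001", "GM", n_perm = 199, seed = 7,
                    normalize_imaging = FALSE)
#> observed R2 = 0.947, permutation p = 0.0050
```

Which mechanisms are stable across the cohort? (On this synthetic cohort the
planted self-decay terms dominate, as they should.)

```r
stable_mechanisms(fit, level = 0.99)
#> Stable re-MCM mechanisms (t interval, level 0.99, 20 subjects)
#>   74 of 678 parameters stable; top by within-factor share:
#>  factor parameter   mean  lower  upper stable mean_abs share
#>    t1t2  fac:t1t2 -0.505 -0.562 -0.447   TRUE    0.505 0.473
#>      FA    fac:FA -0.500 -0.537 -0.463   TRUE    0.500 0.431
#>      GM    fac:GM -0.375 -0.435 -0.315   TRUE    0.375 0.404
```

Link mechanisms to clinical decline and map regional receptor influence:

```r
ax <- symptom_axes(fit, sim$cohort, n_perm = 499, n_boot = 499, seed = 7)
ax
#> Mechanism-symptom latent axes (20 subjects)
#>  component singular_value covariance_explained projection_r p_fwe
#>          1          13.25               0.3152        0.986 0.002
#>          2          11.40               0.2334        0.982 0.134
#>          3           8.85               0.1405        0.979 0.998

influence_map(sim$cohort, "M2", "MD", n_perm = 199, seed = 7,
              normalize_imaging = FALSE)
#> Receptor influence map: M2 on MD (199 permutations)
#>   7 of 95 regions significant; z range [-2.44, 3.41]
```

The first latent axis is significant (FWE-corrected permutation p = 0.002)
and carries 32% of the mechanism–symptom covariance; the projection
correlation 0.986 is the Pearson correlation between the subjects'
mechanism and symptom scores on that axis. With 20 subjects the planted
second axis sits just above the 0.05 threshold — at the generator's n = 80
both planted axes are recovered (see the methods vignette).

Real data enter through `read_cohort()` (long-format imaging CSV, receptor
TSV, connectome TSV, clinical CSV + covariates CSV); `write_cohort()` is its
exact inverse.

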