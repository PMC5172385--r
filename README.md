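# dediffwm — age de-differentiation of brain white-matter microstructure

White-matter tracts do not age independently: tract-averaged diffusion MRI
phenotypes (FA, MD and the NODDI indices ICVF, ISOVF, OD) are positively
correlated across the brain, so a general factor per measure captures much
of the between-person variance. The *de-differentiation* hypothesis says
this shared variance grows with age — tracts lose individuality as
systemic ageing processes accumulate. `dediffwm` implements the complete
statistical pipeline for testing that hypothesis in a middle-aged-to-older
cohort, together with a synthetic cohort generator with known ground
truth, so every stage is testable without access to restricted data.

The core model is a moderated nonlinear factor model. For tract *t* and
subject *n*, with age centered at 60 years (*a*):

    y[t,n] = nu[t] + alpha1[t]*age + alpha2[t]*age^2 + alpha3[t]*sex
             + lambda1[t] * (1 + lambda1' * a) * g[n]
             + lambda2[t] * (1 + lambda2' * a) * u[t,n]

where `g` is the general factor (variance fixed at 1) and `u[t]` the
tract-unique factor. `lambda1'` and `lambda2'` moderate the shared and
unique loadings with age; the communality of tract *t* at age *a* is
`h_t(a) = s_t(a) / (s_t(a) + u_t(a))` with
`s_t = lambda1[t]^2 (1+lambda1' a)^2` and
`u_t = lambda2[t]^2 (1+lambda2' a)^2`. A rising mean `h(a)` is
de-differentiation. A kernel-weighted local-SEM (LOSEM) fit provides a
non-parametric confirmation.

Around that core the package provides per-tract age/sex/hemisphere
regressions with linear-vs-quadratic comparison, Williams's t for
dependent overlapping correlations, power utilities, one-factor
measurement models with loading pruning, residual-covariance search,
factor scores and common/independent pathway comparison, a
multiple-mediator decomposition of the age–gFA association, and
bootstrapped elastic-net selection of age predictors.

## Worked example

```r
library(dediffwm)

gm     <- generating_model()                       # calibrated ground truth
cohort <- exclude_cohort(generate_cohort(gm, 5455, seed = 7))
cohort$exclusion_counts
#>     early_phase         qc_fail neuro_diagnosis         outlier        retained
#>             567            1314              59               2            3513

# one-factor model of MD across the 22 core tracts, then age moderation
base <- fit_one_factor(cohort$table, cohort$subjects, "MD", on_heywood = "warn")
base <- add_residual_covariances(cohort$table, cohort$subjects, base, max_pairs = 3)
mod  <- fit_moderated_factor(cohort$table, cohort$subjects, "MD",
                             mode = "invariant", base_fit = base)
mod
#> Age-moderated one-factor model: MD (mode = invariant, n = 3513)
#>   loading moderation  lambda1' = +0.01449 /yr (SE 0.00144)
#>   uniqueness moderation lambda2' = -0.00138 /yr (SE 0.00059)

communality_delta(mod)$delta_pp
#> [1] 19.8
```

The loading-moderation slope of +0.0145/yr means the general MD factor's
loadings grow by about 1.5% of their age-60 value per year of age; the
factor consequently explains 19.8 percentage points more tract variance
at age 75 than at age 45 (27.7% → 47.6% in this cohort) — the
de-differentiation signature. `communality_curve(mod)` returns the full
trajectory with 95% bands, and
`fit_losem(cohort$table, cohort$subjects, "MD")` reproduces the same
trajectory non-parametrically (maximum discrepancy 0.012 on 48–72 years
in the run recorded under `results/`).

The numbered drivers in `analysis/` run the remaining stages (per-tract
effects, factor models, pathway comparison, mediation, elastic-net age
prediction, de-differentiation) on the same seeded cohort and write tidy
tables under `results/`; for instance the mediation stage prints

    Age -> gFA: total beta -0.343, direct -0.080, mediated 76.6%

meaning three quarters of the age–gFA association runs through the two
NODDI factors (mostly neurite density, gICVF).

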