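# sarcopool

Sarcopenia and sarcopenic-obesity case ascertainment with multi-site
pooled analysis, for epidemiologists working with anthropometry-only
cohorts of adults aged 65 and over (the situation in most multi-country
ageing studies in low- and middle-income settings, where DXA or
bioimpedance is unavailable).

## What it computes

Body composition is predicted from simple anthropometry:

- BMI = weight / height² (kg/m²)
- %BF = 1.20·BMI + 0.23·age − 10.8·sex − 5.4  (sex: male = 1)
- ASM = 0.244·weight + 7.80·height + 6.6·sex − 0.098·age + race − 3.3
  (race constant per site: 0 white/Hispanic, +1.4 Black, −1.2 Asian)
- SMI = ASM / BMI; gait speed = 10 m / walk time

Cases are defined by stratified empirical quintiles: **low SMI** =
lowest quintile of SMI within site × sex; **slow gait** = lowest
quintile of gait speed within sex × age band × height band (pooled
across sites); **high %BF** = highest sex-specific quintile.
**Sarcopenia** = low SMI ∧ slow gait; **sarcopenic obesity** =
sarcopenia ∧ high %BF.

Missing weight is multiply imputed (normal-theory regression with
posterior draws, Rubin's-rules combination). Per site the package fits
crude prevalences with Wald 95% CIs, gender-stratified linear models of
SMI, and logistic models of both case outcomes (all adjusted for
dementia, depression, diabetes and stroke), then pools every term across
sites by fixed-effects inverse-variance meta-analysis with Cochran's Q
and Higgins I² = max(0, 100·(Q − (k−1))/Q).

A synthetic multi-site cohort generator with embedded, exactly defined
ground truth (see the methods vignette in `vignettes/`) makes the whole
pipeline testable end to end without access-restricted data.

## Worked example

```r
library(sarcopool)
prof <- uniform_site_profiles(n = 2000, k = 3)
coh  <- simulate_cohort(prof, truth_spec(), seed = 42)
d    <- derive_body_composition(as.data.frame(coh))
fl   <- flag_cases(d, derive_all_cutoffs(d))
prevalence_table(fl)
fits   <- fit_all_sites(fl, outcomes = "sarcopenia")
pooled <- build_pooled_tables(fits)
pooled[pooled$term == "sexmale", ]
```

which prints (seed 42):

```
    site            outcome    n  k      p  ci_low ci_high
1 site01         sarcopenia 2000 88 0.0440 0.03501  0.0530
2 site01 sarcopenic_obesity 2000 29 0.0145 0.00926  0.0197
3 site02         sarcopenia 2000 79 0.0395 0.03096  0.0480
...
pooled male OR 2.71 (2.00, 3.66), I2 = 47.2%
```

Each site's crude sarcopenia prevalence sits near the generator's 4%
target with its Wald interval, and the pooled male odds ratio recovers
the embedded truth of 2.8 (the CI covers it); at this deliberately small
demo size the heterogeneity estimate is noisy — at the default study
size (9 × 5,000) it concentrates near 0 under homogeneous truths.

The full pipeline — simulate/read → derive → impute → classify →
prevalence → associate → meta, with provenance — is one call:

```r
res <- run_pipeline(run_config(profiles = default_site_profiles(),
                               seed = 1, out_dir = "run1", m = 20))
```

writing `derived.csv`, `cutoffs.csv`, `flags.csv`, `prevalence.csv`,
`site_fits.csv`, `pooled.csv` and `provenance.json`.

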