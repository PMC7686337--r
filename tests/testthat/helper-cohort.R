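# Small deterministic cohort builders used across the test files.

make_cohort_df <- function(n = 12, site = "cuba", seed = 99) {
  if (n == 0) return(make_cohort_df(1, site, seed)[0, ])
  set.seed(seed)
  dict <- cohort_dictionary()$levels
  data.frame(
    pid = sprintf("%s_%03d", site, seq_len(n)),
    site = site,
    age = sample(65:90, n, TRUE),
    sex = sample(dict$sex, n, TRUE),
    height = round(runif(n, 1.40, 1.80), 3),
    weight = round(runif(n, 45, 95), 1),
    walk_time_10m = round(runif(n, 6, 25), 1),
    education = sample(dict$education, n, TRUE),
    marital = sample(dict$marital, n, TRUE),
    assets = sample(0:7, n, TRUE),
    smoking = sample(dict$smoking, n, TRUE),
    alcohol = sample(dict$alcohol, n, TRUE),
    phys_activity = sample(dict$phys_activity, n, TRUE),
    impairments = sample(dict$impairments, n, TRUE),
    dementia = rbinom(n, 1, 0.1),
    depression = rbinom(n, 1, 0.1),
    diabetes = rbinom(n, 1, 0.15),
    stroke = rbinom(n, 1, 0.05),
    stringsAsFactors = FALSE
  )
}

# cohort with derived columns and non-degenerate flags, two sites
make_flagged_cohort <- function(n_per_site = 400, seed = 5) {
  prof <- uniform_site_profiles(n = n_per_site, k = 2)
  coh <- simulate_cohort(prof, truth_spec(), seed = seed,
                         missingness = FALSE)
  d <- derive_body_composition(as.data.frame(coh))
  suppressWarnings(flag_cases(d, derive_all_cutoffs(d, min_stratum = 5)))
}
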