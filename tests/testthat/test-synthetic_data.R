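test_that("profile validation rejects bad configurations before sampling", {
  expect_error(site_profile("x", n = 0), "n must be")
  expect_error(site_profile("x", n = 10,
                            age_band_probs = c(0.5, 0.5, 0.2, 0.1)),
               "summing to 1")
  expect_error(site_profile("x", n = 10, target_prevalence = 0.3),
               "caps prevalence")
  expect_error(site_profile("x", n = 10, ethnicity = "martian"),
               "ethnicity")
  expect_error(simulate_cohort(list(), truth_spec(), 1),
               "at least one site")
  p <- site_profile("x", n = 10)
  expect_error(simulate_cohort(list(p, p), truth_spec(), 1), "duplicate")
})

test_that("identical (profiles, truth, seed) give byte-identical cohorts", {
  prof <- uniform_site_profiles(n = 300, k = 2)
  c1 <- simulate_cohort(prof, truth_spec(), seed = 5)
  c2 <- simulate_cohort(prof, truth_spec(), seed = 5)
  f1 <- tempfile(); f2 <- tempfile()
  write_cohort(c1, f1); write_cohort(c2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  c3 <- simulate_cohort(prof, truth_spec(), seed = 6)
  expect_false(identical(c1$height, c3$height))
})

test_that("generated categorical prevalences match the profile within 3 SE", {
  prof <- list(site_profile("big", n = 6000, weight_missing_rate = 0))
  coh <- simulate_cohort(prof, truth_spec(), seed = 9)
  p <- prof[[1]]
  n <- nrow(coh)
  chk <- function(observed, target) {
    se <- sqrt(target * (1 - target) / n)
    expect_lt(abs(observed - target), 3 * se + 1e-9)
  }
  chk(mean(coh$sex == "female"), p$p_female)
  chk(mean(coh$smoking == "ever"), p$smoking_ever)
  chk(mean(coh$alcohol == "moderate"), p$alcohol_moderate)
  chk(mean(coh$phys_activity == "low"), p$activity_low)
  for (lev in names(p$education_probs)) {
    chk(mean(coh$education == lev), p$education_probs[[lev]])
  }
  for (lev in names(p$impairment_probs)) {
    chk(mean(coh$impairments == lev), p$impairment_probs[[lev]])
  }
  for (b in names(p$age_band_probs)) {
    chk(mean(age_band(coh$age) == b), p$age_band_probs[[b]])
  }
})

test_that("weight missingness hits its target rate and leans on age (MAR)", {
  prof <- list(site_profile("m", n = 10000, weight_missing_rate = 0.30,
                            mar = c(age = 0.06, male = 0, height = 0)))
  coh <- simulate_cohort(prof, truth_spec(), seed = 12)
  miss <- is.na(coh$weight)
  expect_lt(abs(mean(miss) - 0.30), 0.01)
  old <- coh$age >= 80
  young <- coh$age < 70
  expect_gt(mean(miss[old]), mean(miss[young]))
  # all other fields untouched by the mechanism
  full <- simulate_cohort(prof, truth_spec(), seed = 12,
                          missingness = FALSE)
  expect_identical(coh$height, full$height)
  expect_identical(coh$walk_time_10m, full$walk_time_10m)
})

test_that("missingness boundary cases: rate 0 removes nothing, rate 1 empties the site", {
  p0 <- list(site_profile("a", n = 200, weight_missing_rate = 0),
             site_profile("b", n = 200, weight_missing_rate = 1))
  coh <- simulate_cohort(p0, truth_spec(), seed = 3)
  expect_true(all(!is.na(coh$weight[coh$site == "a"])))
  expect_true(all(is.na(coh$weight[coh$site == "b"])))
  expect_error(apply_missingness(coh, p0, 1), "complete in weight")
})

test_that("gait speed falls with age and rises with height on average", {
  prof <- uniform_site_profiles(n = 4000, k = 1)
  coh <- simulate_cohort(prof, truth_spec(), seed = 14)
  sp <- 10 / coh$walk_time_10m
  young <- coh$age < 72
  old <- coh$age >= 80
  expect_gt(mean(sp[young]), mean(sp[old]))
  for (s in c("female", "male")) {
    idx <- coh$sex == s
    tall <- idx & coh$height > quantile(coh$height[idx], 2 / 3)
    short <- idx & coh$height < quantile(coh$height[idx], 1 / 3)
    expect_gt(mean(sp[tall]), mean(sp[short]))
  }
})

test_that("site-specific low-SMI cut-offs land in plausible ranges", {
  prof <- default_site_profiles(n_scale = 0.8)
  coh <- simulate_cohort(prof, truth_spec(), seed = 16,
                         missingness = FALSE)
  d <- derive_body_composition(as.data.frame(coh),
                               ethnicity_map_from_profiles(prof))
  cuts <- suppressWarnings(as.data.frame(
    derive_cutoffs(d, "low_smi", min_stratum = 10)))
  w <- cuts$threshold[cuts$sex == "female"]
  m <- cuts$threshold[cuts$sex == "male"]
  expect_true(all(w > 0.48 & w < 0.60))
  expect_true(all(m > 0.86 & m < 0.99))
  # spread across sites, as expected from differing builds
  expect_gt(diff(range(w)), 0.005)
})

test_that("the embedded sarcopenia coupling yields the designed prevalence scale", {
  prof <- uniform_site_profiles(n = 4000, k = 2)
  coh <- simulate_cohort(prof, truth_spec(), seed = 18)
  gen <- attr(coh, "generator")
  expect_lt(abs(gen$diagnostics$case_rate - 0.04), 0.01)
  d <- derive_body_composition(as.data.frame(coh))
  fl <- suppressWarnings(flag_cases(d, derive_all_cutoffs(d)))
  expect_lt(abs(mean(fl$sarcopenia) - 0.04), 0.012)
  # males more affected than females by design
  expect_gt(mean(fl$sarcopenia[fl$sex == "male"]),
            mean(fl$sarcopenia[fl$sex == "female"]))
})

test_that("infeasible target prevalence is refused with an envelope message", {
  prof <- list(site_profile("x", n = 2000, target_prevalence = 0.17))
  expect_error(simulate_cohort(prof, truth_spec(), seed = 1),
               "feasible envelope")
})
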