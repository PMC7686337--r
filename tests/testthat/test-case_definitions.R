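test_that("the quantile estimator interpolates between order statistics", {
  df <- make_cohort_df(10, site = "cuba")
  df$sex <- "female"
  d <- derive_body_composition(df)
  d$smi <- 1:10
  ct <- suppressWarnings(derive_cutoffs(d, "low_smi", min_stratum = 5))
  expect_equal(ct$threshold, 2.8)    # 1 + 0.2 * 9
  expect_equal(ct$level, 0.2)
})

test_that("all-equal values give the common threshold and the inclusive rule flags everyone", {
  df <- make_cohort_df(30, site = "cuba")
  df$sex <- "female"
  d <- derive_body_composition(df)
  d$smi <- 0.6
  cuts <- suppressWarnings(derive_all_cutoffs(d, min_stratum = 5))
  expect_equal(cuts$low_smi$threshold, 0.6)
  fl <- flag_cases(d, cuts)
  expect_true(all(fl$low_smm))       # ties pathology, documented behaviour
})

test_that("strata are independent: permuting men leaves the women's threshold unchanged", {
  df <- make_cohort_df(60, site = "cuba", seed = 3)
  df$sex <- rep(c("female", "male"), 30)
  d <- derive_body_composition(df)
  ct1 <- suppressWarnings(derive_cutoffs(d, "low_smi", min_stratum = 5))
  men <- which(d$sex == "male")
  d2 <- d
  d2$smi[men] <- d$smi[rev(men)] * 1.7 + 0.1
  ct2 <- suppressWarnings(derive_cutoffs(d2, "low_smi", min_stratum = 5))
  w1 <- ct1$threshold[ct1$sex == "female"]
  w2 <- ct2$threshold[ct2$sex == "female"]
  expect_identical(w1, w2)
})

test_that("boundary rule is inclusive on the flagged side", {
  fl <- make_flagged_cohort(200)
  cuts <- suppressWarnings(derive_all_cutoffs(fl, min_stratum = 5))
  th <- cuts$low_smi$threshold[1]
  at <- which(fl$site == cuts$low_smi$site[1] &
                fl$sex == cuts$low_smi$sex[1] &
                abs(fl$smi - th) < 1e-12)
  # force one record exactly at the threshold
  fl$smi[which(fl$site == cuts$low_smi$site[1] &
                 fl$sex == cuts$low_smi$sex[1])[1]] <- th
  out <- flag_cases(fl, cuts)
  idx <- which(abs(out$smi - th) < 1e-12 &
                 out$site == cuts$low_smi$site[1] &
                 out$sex == cuts$low_smi$sex[1])
  expect_true(all(out$low_smm[idx]))
})

test_that("missing ingredients propagate to missing flags, and composites nest", {
  prof <- uniform_site_profiles(n = 500, k = 2)
  coh <- simulate_cohort(prof, truth_spec(), seed = 11,
                         missingness = FALSE)
  df <- as.data.frame(coh)
  df$weight[1:25] <- NA
  df$walk_time_10m[26:40] <- NA
  d <- derive_body_composition(df)
  fl <- suppressWarnings(flag_cases(d, derive_all_cutoffs(d)))
  expect_true(all(is.na(fl$low_smm[1:25])))
  expect_true(all(is.na(fl$sarcopenia[1:40])))
  expect_true(all(is.na(fl$sarcopenic_obesity[1:25])))
  ok <- !is.na(fl$sarcopenia) & !is.na(fl$sarcopenic_obesity)
  expect_true(all(fl$sarcopenia[ok] >= fl$sarcopenic_obesity[ok]))
  expect_true(all(fl$low_smm[ok] >= fl$sarcopenia[ok]))
})

test_that("vectorised flags equal a per-record brute-force re-evaluation", {
  fl <- make_flagged_cohort(100, seed = 21)
  cuts <- suppressWarnings(derive_all_cutoffs(fl, min_stratum = 2))
  out <- flag_cases(fl, cuts)
  gait <- as.data.frame(cuts$slow_gait)
  smi_t <- as.data.frame(cuts$low_smi)
  pbf_t <- as.data.frame(cuts$high_pbf)
  hb <- height_band(fl$height, fl$sex,
                    breaks = attr(cuts$slow_gait, "height_breaks"))
  for (i in seq_len(nrow(fl))) {
    r <- fl[i, ]
    t_smi <- smi_t$threshold[smi_t$site == r$site & smi_t$sex == r$sex]
    t_g <- gait$threshold[gait$sex == r$sex &
                            gait$age_band == age_band(r$age) &
                            gait$height_band == hb[i]]
    t_p <- pbf_t$threshold[pbf_t$sex == r$sex]
    expect_identical(out$low_smm[i], r$smi <= t_smi)
    expect_identical(out$slow_gait[i], r$gait_speed <= t_g)
    expect_identical(out$high_pbf[i], r$pbf >= t_p)
    expect_identical(out$sarcopenia[i],
                     (r$smi <= t_smi) && (r$gait_speed <= t_g))
  }
})

test_that("a record in a stratum without a cut-off raises an error", {
  fl <- make_flagged_cohort(100, seed = 2)
  cuts <- suppressWarnings(derive_all_cutoffs(fl, min_stratum = 2))
  fl$site[1] <- "atlantis"
  expect_error(flag_cases(fl, cuts), "atlantis")
})

test_that("small strata are flagged but still get a threshold", {
  df <- make_cohort_df(30, site = "cuba")
  df$sex <- c(rep("female", 27), rep("male", 3))
  d <- derive_body_composition(df)
  expect_warning(ct <- derive_cutoffs(d, "low_smi", min_stratum = 20),
                 "below minimum")
  expect_true(ct$flagged[ct$sex == "male"])
  expect_false(ct$flagged[ct$sex == "female"])
  expect_true(is.finite(ct$threshold[ct$sex == "male"]))
})

test_that("case_group maps flags to the three descriptive groups", {
  fl <- make_flagged_cohort(300, seed = 8)
  g <- case_group(fl)
  expect_setequal(unique(g[!is.na(g)]),
                  c("no_sarcopenia", "sarcopenia_only",
                    "sarcopenic_obesity"))
  expect_true(all(g[fl$sarcopenic_obesity %in% TRUE] ==
                    "sarcopenic_obesity"))
})
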