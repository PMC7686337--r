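make_mar_cohort <- function(n = 800, miss = 0.3, seed = 4) {
  prof <- uniform_site_profiles(n = n, k = 1,
                                weight_missing_rate = miss)
  full <- simulate_cohort(prof, truth_spec(), seed = seed,
                          missingness = FALSE)
  masked <- apply_missingness(full, prof, seed = seed + 1)
  list(full = as.data.frame(full), masked = as.data.frame(masked))
}

test_that("imputation preserves observed cells and fills every missing weight", {
  cc <- make_mar_cohort()
  imp <- impute_weight(cc$masked, m = 5, seed = 1)
  obs <- !is.na(cc$masked$weight)
  for (tab in imp$tables) {
    expect_identical(tab$weight[obs], cc$masked$weight[obs])
    expect_true(all(!is.na(tab$weight)))
    expect_identical(tab[, setdiff(names(tab), "weight")],
                     cc$masked[, setdiff(names(tab), "weight")])
  }
  expect_equal(sum(imp$imputed), sum(!obs))
})

test_that("the imputation set is deterministic given the seed", {
  cc <- make_mar_cohort(n = 300)
  i1 <- impute_weight(cc$masked, m = 4, seed = 7)
  i2 <- impute_weight(cc$masked, m = 4, seed = 7)
  expect_identical(i1$tables, i2$tables)
  i3 <- impute_weight(cc$masked, m = 4, seed = 8)
  expect_false(identical(i1$tables[[1]]$weight, i3$tables[[1]]$weight))
})

test_that("no missing weight returns m identical copies with a warning", {
  cc <- make_mar_cohort(n = 200, miss = 0)
  expect_warning(imp <- impute_weight(cc$masked, m = 3, seed = 1),
                 "no missing")
  expect_identical(imp$tables[[1]], imp$tables[[3]])
})

test_that("too few complete cases fails with a diagnostic", {
  df <- make_cohort_df(25)
  df$weight[1:20] <- NA
  expect_error(impute_weight(df, m = 2, seed = 1), "complete cases")
})

test_that("records missing an auxiliary are left unimputed and reported", {
  cc <- make_mar_cohort(n = 300)
  miss_idx <- which(is.na(cc$masked$weight))[1]
  cc$masked$walk_time_10m[miss_idx] <- NA
  expect_warning(imp <- impute_weight(cc$masked, m = 3, seed = 2),
                 "unimputed")
  expect_equal(imp$unimputed_pids, cc$masked$pid[miss_idx])
  expect_true(all(is.na(sapply(imp$tables,
                               function(t) t$weight[miss_idx]))))
})

test_that("imputed weights recover the masked truth on MAR data", {
  cc <- make_mar_cohort(n = 5000, miss = 0.3, seed = 10)
  masked_idx <- is.na(cc$masked$weight)
  truth_mean <- mean(cc$full$weight[masked_idx])
  imp <- impute_weight(cc$masked, m = 10, seed = 3)
  draws <- sapply(imp$tables, function(t) mean(t$weight[masked_idx]))
  se <- sd(cc$full$weight[masked_idx]) / sqrt(sum(masked_idx))
  expect_lt(abs(mean(draws) - truth_mean), 2 * se + 2 * sd(draws))
})

test_that("Rubin pooling reproduces the hand example and its invariants", {
  p <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$W, 1)
  expect_equal(p$B, 2)
  expect_equal(p$T, 4)
  # equal estimates: B = 0, T = W, normal CI
  p0 <- pool_rubin(c(2, 2, 2), c(1, 2, 3))
  expect_equal(p0$B, 0)
  expect_equal(p0$T, p0$W)
  expect_equal(p0$df, Inf)
  # permutation invariance
  set.seed(1)
  est <- rnorm(6); v <- runif(6, 0.5, 2)
  o <- sample(6)
  expect_equal(pool_rubin(est, v)$T, pool_rubin(est[o], v[o])$T)
  expect_error(pool_rubin(c(1, 2), 1), "length mismatch")
  # T >= W always
  expect_gte(pool_rubin(est, v)$T, pool_rubin(est, v)$W)
})

test_that("total variance trends from W + (1+1/m)B toward W + B as m grows", {
  set.seed(42)
  tv <- sapply(c(5, 20, 50), function(m) {
    mean(replicate(40, {
      est <- rnorm(m, 0, 1)
      pool_rubin(est, rep(1, m))$T - (1 + var(est))
    }))
  })
  # the (1/m)B inflation shrinks with m
  expect_true(tv[1] > tv[3])
})
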