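# one-site data with a single binary covariate embedded in the cohort layout
two_by_two_cohort <- function(a, b, c, d) {
  # exposed cases / exposed non-cases / unexposed cases / unexposed non-cases
  n <- a + b + c + d
  df <- make_cohort_df(n, site = "s1", seed = 1)
  df$sex <- rep(c("male", "female"), c(a + b, c + d))
  df$sarcopenia <- c(rep(c(TRUE, FALSE), c(a, b)),
                     rep(c(TRUE, FALSE), c(c, d)))
  df
}

test_that("logistic fit equals the 2x2 cross-product odds ratio", {
  df <- two_by_two_cohort(20, 80, 10, 90)
  spec <- list(outcome = "sarcopenia", covariates = "sex",
               family = "binomial")
  fit <- fit_logistic_case(df, "s1", spec, min_cases = 5)
  expect_equal(exp(fit$estimate), (20 * 90) / (80 * 10),
               tolerance = 1e-6)
  expect_equal(fit$se, sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90),
               tolerance = 1e-6)
  expect_false(fit$flagged)
})

test_that("a covariate level with no cases triggers the separation flag", {
  df <- two_by_two_cohort(30, 70, 0, 100)
  spec <- list(outcome = "sarcopenia", covariates = "sex",
               family = "binomial")
  expect_warning(fit <- fit_logistic_case(df, "s1", spec, min_cases = 5),
                 "separation")
  expect_true(all(fit$flagged))
})

test_that("too few cases fails the precondition", {
  df <- two_by_two_cohort(3, 97, 2, 98)
  expect_error(
    fit_logistic_case(df, "s1",
                      list(outcome = "sarcopenia", covariates = "sex")),
    ">= 10 cases")
})

test_that("OLS matches an independent normal-equations solve", {
  fl <- make_flagged_cohort(300, seed = 31)
  s <- fl$site[1]
  fit <- fit_linear_smi(fl, s, "female")
  spec <- model_spec("smi")
  mf <- fl[fl$site == s & fl$sex == "female", ]
  dict <- cohort_dictionary()$levels
  for (v in names(dict)) if (v %in% names(mf)) {
    mf[[v]] <- factor(mf[[v]], levels = dict[[v]])
  }
  X <- model.matrix(reformulate(spec$covariates), droplevels(mf))
  beta <- solve(crossprod(X), crossprod(X, mf$smi))
  expect_equal(fit$estimate, unname(beta[-1, 1]), tolerance = 1e-8)
})

test_that("row duplication keeps coefficients and rescales OLS SEs exactly", {
  fl <- make_flagged_cohort(200, seed = 37)
  s <- fl$site[1]
  f1 <- fit_linear_smi(fl, s, "female")
  fl2 <- rbind(fl, fl)
  fl2$pid <- make.unique(fl2$pid)
  f2 <- fit_linear_smi(fl2, s, "female")
  expect_equal(f2$estimate, f1$estimate, tolerance = 1e-10)
  n <- f1$n[1]; p <- length(f1$estimate) + 1
  expect_equal(f2$se / f1$se,
               rep(sqrt((n - p) / (2 * n - p)) , length(f1$se)),
               tolerance = 1e-10)
})

test_that("reference coding: exponentiated coefficients are ORs vs the declared reference", {
  fl <- make_flagged_cohort(600, seed = 41)
  fit <- suppressWarnings(
    fit_logistic_case(fl, fl$site[1], model_spec("sarcopenia"),
                      min_cases = 2))
  expect_true(any(grepl("^educationincomplete_primary", fit$term)))
  expect_false(any(grepl("educationnone", fit$term)))  # reference absorbed
  expect_true(any(fit$term == "sexmale"))
})

test_that("the sarcopenic-obesity model excludes %BF by construction", {
  expect_false("pbf" %in% model_spec("sarcopenic_obesity")$covariates)
  expect_true("pbf" %in% model_spec("sarcopenia")$covariates)
  expect_false("sex" %in% model_spec("smi")$covariates)
})

test_that("Rubin pooling of identical fits reduces to the single fit", {
  fl <- make_flagged_cohort(400, seed = 43)
  imp <- list(tables = list(fl, fl, fl), m = 3)
  class(imp) <- "imputation_set"
  fit_fun <- function(tab) fit_linear_smi(tab, tab$site[1], "female")
  pooled <- fit_over_imputations(imp, fit_fun)
  single <- fit_fun(fl)
  expect_equal(pooled$estimate, single$estimate, tolerance = 1e-12)
  expect_equal(pooled$se, single$se, tolerance = 1e-9)
  expect_true(all(pooled$B == 0))
  # pooled SE is never below the mean within-imputation SE
  expect_true(all(pooled$se >= sqrt(pooled$W) - 1e-12))
})
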