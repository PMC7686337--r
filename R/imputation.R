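# Multiple imputation of missing weight by normal-theory linear regression
# with posterior draws, and Rubin's-rules combination of downstream
# estimates.
#
# "Proper" imputation: for each of the m imputations the residual variance is
# drawn from its scaled inverse-chi-squared posterior and the coefficient
# vector from its conditional normal posterior (noninformative prior), then
# each missing weight is drawn from the predictive normal. This matches the
# semantics of regression-based single-variable MI in the major statistical
# packages, as opposed to stochastic regression with fixed coefficients.

#' Auxiliary variables of the weight-imputation model
#'
#' Age, height, gender, education, marital status, number of assets, physical
#' activity, alcohol drinking, smoking, 10-m walk time and the four disease
#' flags. Categoricals enter as reference-coded indicator sets (reference =
#' first dictionary level).
#'
#' @return character vector of column names.
#' @export
default_imputation_auxiliaries <- function() {
  c("age", "height", "sex", "education", "marital", "assets",
    "phys_activity", "alcohol", "smoking", "walk_time_10m",
    "dementia", "depression", "stroke", "diabetes")
}

aux_model_frame <- function(table, auxiliaries) {
  df <- as.data.frame(table)[, auxiliaries, drop = FALSE]
  dict <- cohort_dictionary()$levels
  for (v in names(df)) {
    if (v %in% names(dict)) df[[v]] <- factor(df[[v]], levels = dict[[v]])
    if (v == "sex") df[[v]] <- factor(df[[v]], levels = dict$sex)
  }
  df
}

#' Multiple imputation of missing weight
#'
#' Fits a linear regression of weight on the auxiliary set among complete
#' cases, then for each imputation draws residual variance and coefficients
#' from their joint posterior and each missing weight from the predictive
#' normal. Records missing an auxiliary are left unimputed and reported.
#' Imputed weights are never truncated; draws outside (25, 250) kg are
#' counted in the diagnostics.
#'
#' @param table cohort data.frame with a `weight` column.
#' @param m number of imputations (>= 2).
#' @param seed integer seed; the whole set is deterministic given the seed.
#' @param auxiliaries predictor columns
#'   (default [default_imputation_auxiliaries()]).
#' @return An `imputation_set`: list with `tables` (m completed data.frames),
#'   `imputed` (logical vector marking originally missing weights), `m`,
#'   `seed`, `auxiliaries`, `unimputed_pids` (rows missing an auxiliary) and
#'   `diagnostics` (per-imputation R^2 of the imputation model and count of
#'   implausible draws).
#' @export
impute_weight <- function(table, m = 50, seed = 1,
                          auxiliaries = default_imputation_auxiliaries()) {
  stopifnot(m >= 2)
  df <- as.data.frame(table)
  miss <- is.na(df$weight)
  if (!any(miss)) {
    warning("no missing weight: returning m identical copies")
    return(structure(list(tables = replicate(m, df, simplify = FALSE),
                          imputed = miss, m = m, seed = seed,
                          auxiliaries = auxiliaries,
                          unimputed_pids = character(0),
                          diagnostics = NULL),
                     class = "imputation_set"))
  }
  aux <- aux_model_frame(df, auxiliaries)
  aux_complete <- stats::complete.cases(aux)
  target <- miss & aux_complete            # rows we can impute
  unimputed <- miss & !aux_complete
  if (any(unimputed)) {
    warning(sum(unimputed),
            " record(s) missing an auxiliary left unimputed")
  }
  donors <- !miss & aux_complete
  # design matrix over aux-complete rows only (model.matrix drops NA rows)
  X <- stats::model.matrix(~ ., data = aux[aux_complete, , drop = FALSE])
  donor_pos <- which(!miss[aux_complete])
  target_pos <- which(miss[aux_complete])
  n_cc <- sum(donors)
  p <- ncol(X)
  if (n_cc < p + 2) {
    stop("too few complete cases (", n_cc, ") for ", p, " predictors")
  }
  Xd <- X[donor_pos, , drop = FALSE]
  # drop aliased columns (empty factor levels among donors)
  qrX <- qr(Xd)
  keep_cols <- qrX$pivot[seq_len(qrX$rank)]
  Xd <- Xd[, keep_cols, drop = FALSE]
  Xm <- X[target_pos, , drop = FALSE][, keep_cols, drop = FALSE]
  y <- df$weight[donors]
  XtX_inv <- chol2inv(chol(crossprod(Xd)))
  beta_hat <- XtX_inv %*% crossprod(Xd, y)
  resid <- y - Xd %*% beta_hat
  df_res <- n_cc - ncol(Xd)
  s2 <- sum(resid^2) / df_res
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  R <- chol(XtX_inv)                        # t(R) %*% R = (X'X)^-1
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  tables <- vector("list", m)
  flagged_draws <- integer(m)
  for (j in seq_len(m)) {
    sigma2_star <- df_res * s2 / stats::rchisq(1, df_res)
    beta_star <- beta_hat +
      sqrt(sigma2_star) * drop(t(R) %*% stats::rnorm(ncol(Xd)))
    draws <- drop(Xm %*% beta_star) +
      stats::rnorm(nrow(Xm), 0, sqrt(sigma2_star))
    completed <- df
    completed$weight[target] <- draws
    flagged_draws[j] <- sum(draws < 25 | draws > 250)
    tables[[j]] <- completed
  }
  structure(list(tables = tables, imputed = target, m = m, seed = seed,
                 auxiliaries = auxiliaries,
                 unimputed_pids = df$pid[unimputed],
                 diagnostics = list(r2 = r2,
                                    flagged_draws = flagged_draws,
                                    n_complete_cases = n_cc,
                                    n_imputed = sum(target))),
            class = "imputation_set")
}

# run a seeded block without disturbing the caller's RNG state
.Random.seed_guard <- function(seed) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("Imputation set: m = %d, %d imputed weight(s), seed = %s\n",
              x$m, sum(x$imputed), format(x$seed)))
  invisible(x)
}

#' Rubin's-rules pooling of m completed-data estimates
#'
#' Pooled estimate = mean of the m estimates; within-imputation variance
#' W = mean of the variances; between-imputation variance B = sample variance
#' of the estimates; total T = W + (1 + 1/m) B. Degrees of freedom follow the
#' large-sample formula (m - 1)(1 + W / ((1 + 1/m) B))^2; when B = 0 the CI
#' uses the infinite-df normal limit.
#'
#' @param estimates m completed-data point estimates.
#' @param variances m completed-data (squared-SE) variances, all positive.
#' @param conf confidence level for the CI.
#' @return list(estimate, W, B, T, se, df, ci_low, ci_high, m).
#' @export
pool_rubin <- function(estimates, variances, conf = 0.95) {
  m <- length(estimates)
  if (length(variances) != m) stop("length mismatch between estimates and variances")
  stopifnot(m >= 2, all(variances > 0))
  est <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  if (B > 0) {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    q <- stats::qt(1 - (1 - conf) / 2, df)
  } else {
    df <- Inf
    q <- stats::qnorm(1 - (1 - conf) / 2)
  }
  se <- sqrt(Tv)
  list(estimate = est, W = W, B = B, T = Tv, se = se, df = df,
       ci_low = est - q * se, ci_high = est + q * se, m = m)
}
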