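# Per-site multivariable models: OLS of SMI per gender, ML logistic of
# sarcopenia / sarcopenic obesity, with the conventional covariate sets and
# disease adjustments, plus Rubin pooling over imputation sets.

#' Model specification for the association models
#'
#' Covariates: age in single years; education (ref none); marital status
#' (ref never); number of assets as a numeric 0-7 count; %BF (omitted for the
#' sarcopenic-obesity model); physical activity (ref low); alcohol group
#' (ref none_or_heavy); smoking (ref never); limiting impairments (ref none);
#' sex (ref female; logistic models only, since linear models are
#' gender-stratified); adjusted for dementia, depression, diabetes and
#' stroke.
#'
#' @param outcome "smi", "sarcopenia" or "sarcopenic_obesity".
#' @return list with elements outcome, covariates (character), family.
#' @export
model_spec <- function(outcome = c("smi", "sarcopenia",
                                   "sarcopenic_obesity")) {
  outcome <- match.arg(outcome)
  base <- c("age", "education", "marital", "assets", "pbf",
            "phys_activity", "alcohol", "smoking", "impairments",
            "dementia", "depression", "diabetes", "stroke")
  covs <- switch(outcome,
    smi = base,
    sarcopenia = c("sex", base),
    sarcopenic_obesity = c("sex", setdiff(base, "pbf"))
  )
  list(outcome = outcome, covariates = covs,
       family = if (outcome == "smi") "gaussian" else "binomial")
}

model_frame <- function(table, spec) {
  dict <- cohort_dictionary()$levels
  df <- as.data.frame(table)[, c(spec$outcome, spec$covariates),
                             drop = FALSE]
  for (v in spec$covariates) {
    if (v %in% names(dict)) df[[v]] <- factor(df[[v]], levels = dict[[v]])
  }
  if (spec$outcome %in% c("sarcopenia", "sarcopenic_obesity")) {
    df[[spec$outcome]] <- as.numeric(df[[spec$outcome]])
  }
  df[stats::complete.cases(df), , drop = FALSE]
}

fit_rows <- function(fit, site, stratum, outcome, n, flagged, note) {
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)
  keep <- terms != "(Intercept)"
  est <- sm[keep, 1]
  se <- sm[keep, 2]
  # term-level degeneracy (sparse categories blowing up one dummy) flags
  # just that term, not the whole fit
  term_bad <- !is.finite(est) | !is.finite(se) | abs(est) > 10 | se > 10
  data.frame(site = site, stratum = stratum, outcome = outcome,
             term = terms[keep], estimate = est, se = se, n = n,
             flagged = flagged | term_bad,
             note = ifelse(term_bad & note == "", "degenerate term", note),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gender-stratified linear regression of SMI in one site
#'
#' Ordinary least squares with reference-coded categoricals and conventional
#' standard errors, on complete cases within the site x gender stratum.
#' Rank-deficient terms (empty categories) are dropped with a warning and
#' recorded; a constant outcome yields a flagged degenerate fit.
#'
#' @param table derived cohort table.
#' @param site site label.
#' @param gender "female" or "male".
#' @param spec model spec (default `model_spec("smi")`).
#' @param min_n minimum complete-case n (default number of terms + 5).
#' @return long-format data.frame (site, stratum, outcome, term, estimate,
#'   se, n, flagged, note).
#' @export
fit_linear_smi <- function(table, site, gender,
                           spec = model_spec("smi"), min_n = NULL) {
  df <- table[table$site == site & table$sex == gender, , drop = FALSE]
  mf <- model_frame(df, spec)
  p <- length(spec$covariates)
  if (is.null(min_n)) min_n <- p + 5
  if (nrow(mf) < min_n) {
    stop("site ", site, " gender ", gender, ": only ", nrow(mf),
         " complete cases for ", p, " covariate terms")
  }
  mf <- droplevels(mf)
  form <- stats::reformulate(intersect(spec$covariates, names(mf)),
                             response = spec$outcome)
  fit <- stats::lm(form, data = mf)
  aliased <- is.na(stats::coef(fit))
  note <- ""
  flagged <- FALSE
  if (any(aliased)) {
    note <- paste("dropped:", paste(names(stats::coef(fit))[aliased],
                                    collapse = ", "))
    warning("site ", site, " gender ", gender,
            ": rank-deficient fit; ", note)
  }
  if (stats::var(mf[[spec$outcome]]) == 0) {
    flagged <- TRUE
    note <- paste(note, "constant outcome")
  }
  fit_rows(fit, site, gender, spec$outcome, nrow(mf), flagged, note)
}

#' Logistic regression of a case outcome in one site
#'
#' Maximum-likelihood logistic fit (IRLS, log-likelihood tolerance 1e-8,
#' up to 100 iterations) of sarcopenia or sarcopenic obesity on the
#' conventional covariate set; coefficients are on the log-odds scale.
#' Quasi-complete separation and non-convergence are detected and flag the
#' fit (flagged fits are excluded from pooling downstream).
#'
#' @param table flagged cohort table.
#' @param site site label.
#' @param spec model spec (`model_spec("sarcopenia")` or
#'   `model_spec("sarcopenic_obesity")`).
#' @param min_cases minimum count in the rarer outcome class (default 10).
#' @return long-format data.frame as [fit_linear_smi()].
#' @export
fit_logistic_case <- function(table, site,
                              spec = model_spec("sarcopenia"),
                              min_cases = 10) {
  df <- table[table$site == site, , drop = FALSE]
  mf <- model_frame(df, spec)
  y <- mf[[spec$outcome]]
  if (length(unique(y)) < 2L || min(table(y)) < min_cases) {
    stop("site ", site, ": outcome ", spec$outcome,
         " needs both classes with >= ", min_cases, " cases")
  }
  mf <- droplevels(mf)
  form <- stats::reformulate(intersect(spec$covariates, names(mf)),
                             response = spec$outcome)
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = mf,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  )
  mu <- stats::fitted(fit)
  separated <- any(mu < 1e-8 & mf[[spec$outcome]] == 0) &&
    any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  flagged <- separated || !fit$converged
  note <- paste0(if (separated) "separation " else "",
                 if (!fit$converged) "non-convergence" else "")
  if (flagged) {
    warning("site ", site, " outcome ", spec$outcome, ": ", note)
  }
  fit_rows(fit, site, "all", spec$outcome, nrow(mf), flagged, trimws(note))
}

#' Fit all association models for every site (and gender for SMI)
#'
#' @param table flagged cohort table with derived columns.
#' @param outcomes outcomes to fit.
#' @param min_cases minimum cases for logistic fits.
#' @return combined long-format site-fit data.frame; sites/strata whose fit
#'   fails its preconditions are skipped with a message.
#' @export
fit_all_sites <- function(table,
                          outcomes = c("smi", "sarcopenia",
                                       "sarcopenic_obesity"),
                          min_cases = 10) {
  out <- list()
  for (s in sort(unique(table$site))) {
    if ("smi" %in% outcomes) {
      for (g in c("female", "male")) {
        res <- tryCatch(fit_linear_smi(table, s, g),
                        error = function(e) {
                          message("skipping smi fit ", s, "/", g, ": ",
                                  conditionMessage(e))
                          NULL
                        })
        if (!is.null(res)) out[[length(out) + 1L]] <- res
      }
    }
    for (oc in intersect(outcomes, c("sarcopenia", "sarcopenic_obesity"))) {
      res <- tryCatch(
        suppressWarnings(
          fit_logistic_case(table, s, model_spec(oc), min_cases)),
        error = function(e) {
          message("skipping ", oc, " fit ", s, ": ", conditionMessage(e))
          NULL
        })
      if (!is.null(res)) out[[length(out) + 1L]] <- res
    }
  }
  if (length(out) == 0L) stop("no model could be fitted")
  do.call(rbind, out)
}

#' Rubin-pool model fits over an imputation set
#'
#' Applies a fitting function to each completed dataset and combines the m
#' fits term by term with [pool_rubin()] (coefficients stay on the linear /
#' log-odds scale; the pooled SE is sqrt of the Rubin total variance). A term
#' flagged in any imputation is flagged in the pooled result.
#'
#' @param imputation_set result of [impute_weight()].
#' @param fit_fun function(completed_table) -> long-format site-fit
#'   data.frame (typically wrapping derivation, flagging and one of the fit
#'   operations).
#' @param on_error "skip" drops failing imputations with a warning (the
#'   remaining m' >= 2 are pooled); "abort" re-raises.
#' @return pooled long-format site-fit data.frame with columns W and B added.
#' @export
fit_over_imputations <- function(imputation_set, fit_fun,
                                 on_error = c("skip", "abort")) {
  on_error <- match.arg(on_error)
  fits <- list()
  for (j in seq_len(imputation_set$m)) {
    res <- tryCatch(fit_fun(imputation_set$tables[[j]]),
                    error = function(e) {
                      if (on_error == "abort") stop(e)
                      warning("imputation ", j, " failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) fits[[length(fits) + 1L]] <- res
  }
  if (length(fits) < 2L) stop("fewer than 2 successful imputation fits")
  pool_fit_list(fits)
}

# Rubin-combine a list of long-format fit tables term by term
pool_fit_list <- function(fits) {
  all_rows <- do.call(rbind, lapply(seq_along(fits), function(j) {
    cbind(fits[[j]], .imp = j)
  }))
  key <- unique(all_rows[, c("site", "stratum", "outcome", "term")])
  out <- lapply(seq_len(nrow(key)), function(i) {
    sel <- all_rows$site == key$site[i] &
      all_rows$stratum == key$stratum[i] &
      all_rows$outcome == key$outcome[i] & all_rows$term == key$term[i]
    sub <- all_rows[sel, , drop = FALSE]
    if (nrow(sub) < 2L) {
      # term estimable in a single imputation only (e.g. sparse site):
      # passed through flagged, never silently averaged
      return(data.frame(site = key$site[i], stratum = key$stratum[i],
                        outcome = key$outcome[i], term = key$term[i],
                        estimate = sub$estimate, se = sub$se, n = sub$n,
                        flagged = TRUE, note = "single-imputation term",
                        W = sub$se^2, B = NA_real_,
                        stringsAsFactors = FALSE))
    }
    pooled <- pool_rubin(sub$estimate, sub$se^2)
    data.frame(site = key$site[i], stratum = key$stratum[i],
               outcome = key$outcome[i], term = key$term[i],
               estimate = pooled$estimate, se = pooled$se,
               n = round(mean(sub$n)), flagged = any(sub$flagged),
               note = paste(unique(sub$note[sub$note != ""]),
                            collapse = "; "),
               W = pooled$W, B = pooled$B,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
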