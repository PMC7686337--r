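# Crude per-site prevalence with Wald 95% confidence intervals, optionally
# combined over multiply-imputed datasets on the proportion scale.

#' Crude prevalence of an outcome in one site
#'
#' p = k/n over records with a non-missing flag; Wald interval
#' p +/- 1.96 sqrt(p(1-p)/n), clipped to \[0, 1\]. The Wald form is the
#' default because it round-trips conventionally published bounds exactly;
#' Wilson and Clopper-Pearson intervals are available for real use. Boundary
#' counts (k = 0 or k = n) collapse the Wald interval and are flagged with a
#' warning.
#'
#' @param table flagged cohort table (see [flag_cases()]).
#' @param site site label.
#' @param outcome "sarcopenia" or "sarcopenic_obesity".
#' @param method "wald" (default), "wilson" or "exact".
#' @return data.frame row: site, outcome, n, k, p, ci_low, ci_high, method.
#' @export
estimate_prevalence <- function(table, site, outcome = "sarcopenia",
                                method = c("wald", "wilson", "exact")) {
  method <- match.arg(method)
  flag <- table[[outcome]][table$site == site]
  flag <- flag[!is.na(flag)]
  n <- length(flag)
  if (n == 0L) stop("no records with computable ", outcome, " flag in site ",
                    site)
  k <- sum(flag)
  p <- k / n
  ci <- prevalence_ci(k, n, method)
  if (method == "wald" && (k == 0L || k == n)) {
    warning("boundary count (k = ", k, ", n = ", n,
            "): Wald interval degenerate")
  }
  data.frame(site = site, outcome = outcome, n = n, k = k, p = p,
             ci_low = ci[1], ci_high = ci[2], method = method,
             stringsAsFactors = FALSE)
}

prevalence_ci <- function(k, n, method = "wald", level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  switch(method,
    wald = {
      half <- z * sqrt(p * (1 - p) / n)
      c(max(0, p - half), min(1, p + half))
    },
    wilson = {
      centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      c(max(0, centre - half), min(1, centre + half))
    },
    exact = {
      lo <- if (k == 0) 0 else stats::qbeta((1 - level) / 2, k, n - k + 1)
      hi <- if (k == n) 1 else stats::qbeta(1 - (1 - level) / 2, k + 1, n - k)
      c(lo, hi)
    },
    stop("unknown method: ", method)
  )
}

#' Per-site prevalence table for all sites and both outcomes
#'
#' @inheritParams estimate_prevalence
#' @return data.frame, one row per site x outcome.
#' @export
prevalence_table <- function(table, method = "wald") {
  sites <- sort(unique(table$site))
  out <- lapply(sites, function(s) {
    rbind(estimate_prevalence(table, s, "sarcopenia", method),
          estimate_prevalence(table, s, "sarcopenic_obesity", method))
  })
  do.call(rbind, out)
}

#' Prevalence combined over an imputation set
#'
#' Case definitions and cut-offs are recomputed within each completed
#' dataset; the m prevalences and their Wald variances are combined with
#' Rubin's rules on the proportion scale, and the CI uses the pooled total
#' variance (t reference distribution), clipped to \[0, 1\].
#'
#' @param completed_flagged list of m flagged cohort tables (one per
#'   completed dataset).
#' @param site site label.
#' @param outcome "sarcopenia" or "sarcopenic_obesity".
#' @return data.frame row as [estimate_prevalence()], with method
#'   "wald_rubin" and columns W, B for the variance components.
#' @export
prevalence_over_imputations <- function(completed_flagged, site,
                                        outcome = "sarcopenia") {
  per <- lapply(completed_flagged, function(tab) {
    estimate_prevalence(tab, site, outcome, method = "wald")
  })
  p <- vapply(per, function(r) r$p, numeric(1))
  n <- vapply(per, function(r) r$n, numeric(1))
  v <- pmax(p * (1 - p) / n, 1e-12)   # Wald variance; floored at boundary
  pooled <- pool_rubin(p, v)
  data.frame(site = site, outcome = outcome, n = round(mean(n)),
             k = round(mean(p * n)), p = pooled$estimate,
             ci_low = max(0, pooled$ci_low),
             ci_high = min(1, pooled$ci_high),
             method = "wald_rubin", W = pooled$W, B = pooled$B,
             stringsAsFactors = FALSE)
}
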