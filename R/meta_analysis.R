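# Fixed-effects inverse-variance meta-analysis with Cochran's Q and
# Higgins I2. Logistic terms are pooled on the log-odds scale and reported
# exponentiated; pooling odds ratios directly is never done.

#' Fixed-effects inverse-variance pooling
#'
#' Weights w_i = 1/se_i^2; pooled estimate = sum(w * theta)/sum(w); pooled
#' SE = 1/sqrt(sum(w)); 95% CI = estimate +/- 1.96 SE. With a single estimate
#' the value is passed through with a warning and no heterogeneity
#' statistics.
#'
#' @param estimates numeric vector of per-site estimates (linear or log-odds
#'   scale).
#' @param ses positive standard errors, same length.
#' @return list with estimate, se, ci_low, ci_high, k, and the
#'   [heterogeneity()] statistics (Q, i2, p, class; NA when k = 1).
#' @export
pool_fixed <- function(estimates, ses) {
  stopifnot(length(estimates) == length(ses))
  if (any(!is.finite(estimates)) || any(!is.finite(ses)) || any(ses <= 0)) {
    stop("estimates must be finite and ses positive")
  }
  k <- length(estimates)
  if (k == 1L) {
    warning("single estimate: pass-through, no heterogeneity statistics")
    return(list(estimate = estimates, se = ses,
                ci_low = estimates - 1.96 * ses,
                ci_high = estimates + 1.96 * ses,
                k = 1L, Q = NA_real_, i2 = NA_real_, p = NA_real_,
                class = NA_character_))
  }
  w <- 1 / ses^2
  est <- sum(w * estimates) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- heterogeneity(estimates, ses, pooled = est)
  list(estimate = est, se = se,
       ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
       k = k, Q = het$Q, i2 = het$i2, p = het$p, class = het$class)
}

#' Cochran's Q and Higgins I2
#'
#' Q = sum(w_i (theta_i - pooled)^2) with inverse-variance weights;
#' I2 = max(0, 100 (Q - (k-1))/Q); p from the chi-square distribution with
#' k - 1 degrees of freedom. Heterogeneity class: low if I2 < 50%, moderate
#' if 50 <= I2 < 75, high if I2 >= 75.
#'
#' @param estimates per-site estimates.
#' @param ses their standard errors.
#' @param pooled fixed-effects pooled estimate; recomputed when `NULL`.
#' @return list(Q, i2, p, class).
#' @export
heterogeneity <- function(estimates, ses, pooled = NULL) {
  k <- length(estimates)
  stopifnot(k >= 2L, length(ses) == k)
  w <- 1 / ses^2
  if (is.null(pooled)) pooled <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - pooled)^2)
  i2 <- if (Q > 0) max(0, 100 * (Q - (k - 1)) / Q) else 0
  p <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  cls <- if (i2 < 50) "low" else if (i2 < 75) "moderate" else "high"
  list(Q = Q, i2 = i2, p = p, class = cls)
}

#' Pool per-site model fits term by term
#'
#' Takes long-format site fits (see [fit_linear_smi()] /
#' [fit_logistic_case()]), excludes flagged fits, and produces one pooled row
#' per outcome x stratum x term. Logistic outcomes are pooled on the log-odds
#' scale; their pooled estimate and CI are additionally reported
#' exponentiated (`or`, `or_low`, `or_high`). Terms present in fewer than two
#' sites are passed through with `pooled = FALSE`.
#'
#' @param site_fits data.frame with columns site, stratum, outcome, term,
#'   estimate, se, n, flagged.
#' @return data.frame of pooled estimates with heterogeneity statistics.
#' @export
build_pooled_tables <- function(site_fits) {
  df <- site_fits[!site_fits$flagged & is.finite(site_fits$se) &
                    site_fits$se > 0, , drop = FALSE]
  if (nrow(df) < nrow(site_fits)) {
    message(nrow(site_fits) - nrow(df),
            " flagged/degenerate site-fit row(s) excluded from pooling")
  }
  key <- unique(df[, c("outcome", "stratum", "term")])
  out <- lapply(seq_len(nrow(key)), function(i) {
    sel <- df$outcome == key$outcome[i] & df$stratum == key$stratum[i] &
      df$term == key$term[i]
    sub <- df[sel, , drop = FALSE]
    row <- data.frame(outcome = key$outcome[i], stratum = key$stratum[i],
                      term = key$term[i], k = nrow(sub),
                      stringsAsFactors = FALSE)
    if (nrow(sub) >= 2L) {
      p <- pool_fixed(sub$estimate, sub$se)
      row$pooled <- TRUE
      row[c("estimate", "se", "ci_low", "ci_high", "Q", "i2", "q_p")] <-
        p[c("estimate", "se", "ci_low", "ci_high", "Q", "i2", "p")]
      row$het_class <- p$class
    } else {
      row$pooled <- FALSE
      row$estimate <- sub$estimate
      row$se <- sub$se
      row$ci_low <- sub$estimate - 1.96 * sub$se
      row$ci_high <- sub$estimate + 1.96 * sub$se
      row[c("Q", "i2", "q_p")] <- NA_real_
      row$het_class <- NA_character_
    }
    logistic <- key$outcome[i] %in% c("sarcopenia", "sarcopenic_obesity")
    row$or <- if (logistic) exp(row$estimate) else NA_real_
    row$or_low <- if (logistic) exp(row$ci_low) else NA_real_
    row$or_high <- if (logistic) exp(row$ci_high) else NA_real_
    row
  })
  do.call(rbind, out)
}

#' Render a pooled table in the conventional publication layout
#'
#' Linear coefficients to 3 decimals with CI; odds ratios to 2 decimals with
#' CI; I2 as a percentage to 1 decimal with the Q p-value.
#'
#' @param pooled data.frame from [build_pooled_tables()].
#' @return character vector of formatted lines.
#' @export
format_pooled_table <- function(pooled) {
  apply(pooled, 1, function(r) {
    logistic <- r[["outcome"]] %in% c("sarcopenia", "sarcopenic_obesity")
    est <- if (logistic) {
      sprintf("%.2f (%.2f, %.2f)", as.numeric(r[["or"]]),
              as.numeric(r[["or_low"]]), as.numeric(r[["or_high"]]))
    } else {
      sprintf("%.3f (%.3f, %.3f)", as.numeric(r[["estimate"]]),
              as.numeric(r[["ci_low"]]), as.numeric(r[["ci_high"]]))
    }
    het <- if (!is.na(r[["i2"]])) {
      sprintf("I2 = %.1f%% (p = %.3f)", as.numeric(r[["i2"]]),
              as.numeric(r[["q_p"]]))
    } else "I2 = -"
    sprintf("%-20s %-8s %-24s %s  %s", r[["outcome"]], r[["stratum"]],
            r[["term"]], est, het)
  })
}
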