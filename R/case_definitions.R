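# Stratified quintile cut-offs and case flags.
#
# Definitions:
#   low_smi   : SMI <= sex-specific 20th percentile, computed per site
#               (site x sex strata; country-specific cut-offs apply to SMI
#               only, since it is the indicator most affected by population
#               differences in body build).
#   slow_gait : gait speed <= 20th percentile within sex x age band x height
#               band strata, pooled across sites.
#   high_pbf  : %BF >= sex-specific 80th percentile, pooled across sites.
# Composites: sarcopenia = low_smm AND slow_gait;
#             sarcopenic_obesity = sarcopenia AND high_pbf.
# Boundary rule is inclusive on the flagged side ("lowest quintile" includes
# its boundary). Quantiles use linear interpolation between order statistics
# (type 7) by default; the estimator is configurable because different
# statistical packages default differently.

#' Age bands used for gait-speed stratification
#'
#' 65-69, 70-74, 75-79, 80+.
#'
#' @param age numeric years.
#' @return character vector of band labels.
#' @export
age_band <- function(age) {
  as.character(cut(age, breaks = c(65, 70, 75, 80, Inf),
                   labels = c("65-69", "70-74", "75-79", "80+"),
                   right = FALSE, include.lowest = TRUE))
}

#' Within-sex height tertile bands
#'
#' Tertiles of height within each sex on the pooled sample, used to stratify
#' the gait-speed cut-offs. Break points can be supplied to band a new table
#' on a reference sample's tertiles.
#'
#' @param height metres.
#' @param sex "female"/"male" vector.
#' @param breaks optional named list `list(female = c(q1, q2), male = ...)`
#'   of precomputed tertile breaks; computed from the data when `NULL`.
#' @param qtype quantile estimator type (see [stats::quantile()]).
#' @return character vector "short"/"medium"/"tall" with attribute `breaks`.
#' @export
height_band <- function(height, sex, breaks = NULL, qtype = 7) {
  out <- rep(NA_character_, length(height))
  computed <- list()
  for (s in c("female", "male")) {
    idx <- which(sex == s & !is.na(height))
    if (length(idx) == 0L) next
    br <- if (!is.null(breaks)) breaks[[s]] else {
      stats::quantile(height[idx], c(1, 2) / 3, type = qtype, names = FALSE)
    }
    computed[[s]] <- br
    out[idx] <- c("short", "medium", "tall")[
      1L + (height[idx] > br[1]) + (height[idx] > br[2])]
  }
  attr(out, "breaks") <- computed
  out
}

definition_spec <- function(definition) {
  switch(definition,
    low_smi   = list(var = "smi", level = 0.20,
                     strata = c("site", "sex")),
    slow_gait = list(var = "gait_speed", level = 0.20,
                     strata = c("sex", "age_band", "height_band")),
    high_pbf  = list(var = "pbf", level = 0.80,
                     strata = c("sex")),
    stop("unknown definition: ", definition)
  )
}

#' Derive stratified quintile cut-offs
#'
#' Empirical quantile of the definition's variable within each stratum:
#' 20th percentile of SMI within site x sex; 20th percentile of gait speed
#' within sex x age band x height band (pooled across sites); 80th percentile
#' of %BF within sex (pooled). Missing values are excluded from the quantile
#' computation. Strata smaller than `min_stratum` still get a threshold but
#' are flagged.
#'
#' @param table cohort table with derived columns (see
#'   [derive_body_composition()]).
#' @param definition one of "low_smi", "slow_gait", "high_pbf".
#' @param min_stratum minimum non-missing stratum size before flagging.
#' @param qtype quantile estimator type (default 7, linear interpolation).
#' @param pool_sites if `FALSE`, gait and %BF cut-offs are additionally
#'   stratified by site instead of pooled.
#' @return A `cutoff_table` data.frame: definition, stratum columns,
#'   threshold, n, level, flagged; height tertile breaks (when used) are kept
#'   in attribute `height_breaks`.
#' @export
derive_cutoffs <- function(table, definition, min_stratum = 20, qtype = 7,
                           pool_sites = TRUE) {
  spec <- definition_spec(definition)
  strata <- spec$strata
  if (!pool_sites && !("site" %in% strata)) strata <- c("site", strata)
  df <- as.data.frame(table)
  height_breaks <- NULL
  if ("age_band" %in% strata && is.null(df$age_band)) {
    df$age_band <- age_band(df$age)
  }
  if ("height_band" %in% strata && is.null(df$height_band)) {
    hb <- height_band(df$height, df$sex, qtype = qtype)
    height_breaks <- attr(hb, "breaks")
    df$height_band <- hb
  }
  ok <- !is.na(df[[spec$var]])
  for (s in strata) ok <- ok & !is.na(df[[s]])
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0L) stop("no non-missing values for ", definition)
  key <- interaction(df[strata], drop = TRUE, sep = "\r")
  out <- lapply(levels(key), function(k) {
    idx <- key == k
    vals <- df[[spec$var]][idx]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    row <- as.data.frame(as.list(parts), stringsAsFactors = FALSE)
    names(row) <- strata
    row$threshold <- stats::quantile(vals, spec$level, type = qtype,
                                     names = FALSE)
    row$n <- length(vals)
    row$level <- spec$level
    row$flagged <- length(vals) < min_stratum
    row
  })
  out <- do.call(rbind, out)
  out <- cbind(definition = definition, out, stringsAsFactors = FALSE)
  if (any(out$flagged)) {
    warning(sum(out$flagged), " ", definition,
            " stratum/strata below minimum size ", min_stratum)
  }
  structure(out,
            strata = strata,
            qtype = qtype,
            height_breaks = height_breaks,
            class = c("cutoff_table", "data.frame"))
}

# look up per-record thresholds from a cutoff table; error on missing stratum
lookup_threshold <- function(df, cutoffs) {
  strata <- attr(cutoffs, "strata")
  key <- do.call(paste, c(df[strata], sep = "\r"))
  ckey <- do.call(paste, c(as.data.frame(cutoffs)[strata], sep = "\r"))
  idx <- match(key, ckey)
  complete_stratum <- rep(TRUE, nrow(df))
  for (s in strata) complete_stratum <- complete_stratum & !is.na(df[[s]])
  unmatched <- is.na(idx) & complete_stratum
  if (any(unmatched)) {
    stop("record(s) in stratum absent from ",
         cutoffs$definition[1], " cut-off table: ",
         paste(unique(gsub("\r", " x ", key[unmatched], fixed = TRUE)),
               collapse = "; "))
  }
  cutoffs$threshold[idx]
}

#' Flag cases against a set of cut-off tables
#'
#' Applies the inclusive boundary rule: low_smm iff SMI <= its site x sex
#' threshold; slow_gait iff gait speed <= its sex x age band x height band
#' threshold; high_pbf iff %BF >= its sex threshold. Composites:
#' sarcopenia = low_smm AND slow_gait; sarcopenic_obesity = sarcopenia AND
#' high_pbf. Any missing ingredient makes the corresponding flags missing.
#'
#' @param table cohort table with derived columns.
#' @param cutoffs named list with elements `low_smi`, `slow_gait`, `high_pbf`
#'   as returned by [derive_cutoffs()].
#' @return the table with logical columns low_smm, slow_gait, high_pbf,
#'   sarcopenia, sarcopenic_obesity appended.
#' @export
flag_cases <- function(table, cutoffs) {
  stopifnot(all(c("low_smi", "slow_gait", "high_pbf") %in% names(cutoffs)))
  df <- as.data.frame(table)
  if (is.null(df$age_band)) df$age_band <- age_band(df$age)
  if (is.null(df$height_band)) {
    df$height_band <- height_band(
      df$height, df$sex,
      breaks = attr(cutoffs$slow_gait, "height_breaks"),
      qtype = attr(cutoffs$slow_gait, "qtype") %||% 7
    )
  }
  low_smm   <- df$smi <= lookup_threshold(df, cutoffs$low_smi)
  slow_gait <- df$gait_speed <= lookup_threshold(df, cutoffs$slow_gait)
  high_pbf  <- df$pbf >= lookup_threshold(df, cutoffs$high_pbf)
  sarc <- low_smm & slow_gait
  sarc[is.na(low_smm) | is.na(slow_gait)] <- NA
  so <- sarc & high_pbf
  so[is.na(sarc) | is.na(high_pbf)] <- NA
  table$low_smm <- low_smm
  table$slow_gait <- slow_gait
  table$high_pbf <- high_pbf
  table$sarcopenia <- sarc
  table$sarcopenic_obesity <- so
  table
}

#' Derive all three cut-off tables at once
#'
#' @inheritParams derive_cutoffs
#' @return named list of `cutoff_table`s (low_smi, slow_gait, high_pbf).
#' @export
derive_all_cutoffs <- function(table, min_stratum = 20, qtype = 7,
                               pool_sites = TRUE) {
  list(
    low_smi   = derive_cutoffs(table, "low_smi", min_stratum, qtype,
                               pool_sites = TRUE),
    slow_gait = derive_cutoffs(table, "slow_gait", min_stratum, qtype,
                               pool_sites = pool_sites),
    high_pbf  = derive_cutoffs(table, "high_pbf", min_stratum, qtype,
                               pool_sites = pool_sites)
  )
}

#' Case-status grouping for descriptive tables
#'
#' @param table flagged cohort table (see [flag_cases()]).
#' @return character vector: "no_sarcopenia", "sarcopenia_only",
#'   "sarcopenic_obesity", or NA when flags are missing.
#' @export
case_group <- function(table) {
  out <- rep(NA_character_, nrow(table))
  out[table$sarcopenia %in% FALSE] <- "no_sarcopenia"
  out[table$sarcopenia %in% TRUE &
        table$sarcopenic_obesity %in% FALSE] <- "sarcopenia_only"
  out[table$sarcopenic_obesity %in% TRUE] <- "sarcopenic_obesity"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
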