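# End-to-end orchestration: simulate/read -> derive -> (impute) ->
# classify -> prevalence -> associate -> meta, with provenance.

#' Pipeline run configuration
#'
#' @param input path to a cohort CSV, or `NULL` to simulate.
#' @param profiles site profiles (required when simulating; also supplies
#'   the site -> ethnicity map and the missingness mechanism).
#' @param truth [truth_spec()] for simulation.
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir output directory (created if absent).
#' @param m number of imputations when the trigger fires (m < 2 disables
#'   imputation).
#' @param impute_threshold weight-missingness fraction above which a site
#'   triggers imputation (default 0.10).
#' @param impute_sites explicit site list overriding the threshold rule
#'   (`NULL` = use threshold).
#' @param cutoff_scope "per_imputation" recomputes quintile cut-offs within
#'   each completed dataset; "complete_case" derives them once from the
#'   observed records and applies them to every completed dataset.
#' @param min_stratum,qtype,min_cases tuning passed to the respective
#'   stages.
#' @return validated `run_config` list.
#' @export
run_config <- function(input = NULL, profiles = NULL,
                       truth = truth_spec(), seed = 1,
                       out_dir = tempfile("sarcopool_run_"), m = 20,
                       impute_threshold = 0.10, impute_sites = NULL,
                       cutoff_scope = c("per_imputation", "complete_case"),
                       min_stratum = 20, qtype = 7, min_cases = 10) {
  cutoff_scope <- match.arg(cutoff_scope)
  if (is.null(input) && is.null(profiles)) {
    stop("either an input path or simulation profiles must be given")
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("input file not found: ", input)
  }
  as.list(environment())
}

#' Site -> ethnicity map implied by a profile list
#'
#' @param profiles list of [site_profile()]s (`NULL` gives the default map).
#' @return named character vector site -> ethnicity.
#' @export
ethnicity_map_from_profiles <- function(profiles) {
  if (is.null(profiles)) return(default_ethnicity_map())
  eth <- vapply(profiles, function(p) p$ethnicity, character(1))
  names(eth) <- vapply(profiles, function(p) p$site, character(1))
  eth
}

#' Sites whose weight missingness triggers multiple imputation
#'
#' Threshold rule (default: missing fraction > 0.10) with an explicit
#' site-list override.
#'
#' @param table cohort data.frame.
#' @param threshold missing-weight fraction above which a site qualifies.
#' @param sites explicit site list; when non-`NULL` it takes precedence.
#' @return character vector of site labels (possibly empty).
#' @export
imputation_trigger <- function(table, threshold = 0.10, sites = NULL) {
  if (!is.null(sites)) return(intersect(sites, unique(table$site)))
  rates <- tapply(is.na(table$weight), table$site, mean)
  names(rates)[rates > threshold]
}

write_stage <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = ",",
                     row.names = FALSE, na = "", quote = FALSE,
                     fileEncoding = "UTF-8")
  path
}

cutoffs_long <- function(cutoffs) {
  do.call(rbind, lapply(cutoffs, function(ct) {
    df <- as.data.frame(ct)
    for (col in c("site", "sex", "age_band", "height_band")) {
      if (is.null(df[[col]])) df[[col]] <- NA_character_
    }
    df[, c("definition", "site", "sex", "age_band", "height_band",
           "threshold", "n", "level", "flagged")]
  }))
}

#' Run the full analysis pipeline
#'
#' Stages: load or simulate the cohort; derive body composition; decide
#' which sites need weight imputation; derive cut-offs and case flags
#' (within each completed dataset on the multiple-imputation path); per-site
#' prevalence; per-site association models; fixed-effects meta-analysis.
#' Writes seven artifacts to `config$out_dir`: derived.csv, cutoffs.csv,
#' flags.csv, prevalence.csv, site_fits.csv, pooled.csv, provenance.json.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results (cohort, cutoffs,
#'   flags, prevalence, site_fits, pooled, provenance, paths).
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) {
    message(sprintf("[sarcopool %5.1fs] ",
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            ...)
  }

  log_stage("stage input")
  cohort <- if (!is.null(config$input)) {
    read_cohort(config$input)
  } else {
    simulate_cohort(config$profiles, config$truth, seed = config$seed)
  }
  eth_map <- ethnicity_map_from_profiles(config$profiles)

  log_stage("stage derive (", nrow(cohort), " records)")
  derived <- derive_body_composition(as.data.frame(cohort), eth_map)

  impute_sites <- imputation_trigger(derived, config$impute_threshold,
                                     config$impute_sites)
  use_mi <- length(impute_sites) > 0L && any(is.na(derived$weight)) &&
    config$m >= 2
  n_missing_weight <- sum(is.na(derived$weight))

  classify_one <- function(tab, cutoffs = NULL) {
    if (is.null(cutoffs)) {
      cutoffs <- derive_all_cutoffs(tab, config$min_stratum, config$qtype)
    }
    list(cutoffs = cutoffs, flags = flag_cases(tab, cutoffs))
  }

  if (use_mi) {
    log_stage("stage impute: m = ", config$m, " for site(s) ",
              paste(impute_sites, collapse = ", "))
    imp <- impute_weight(cohort, m = config$m, seed = config$seed + 1L)
    cc_cutoffs <- if (config$cutoff_scope == "complete_case") {
      suppressWarnings(derive_all_cutoffs(
        derived[!is.na(derived$weight), , drop = FALSE],
        config$min_stratum, config$qtype))
    } else NULL
    log_stage("stage classify/prevalence/associate over imputations")
    completed <- lapply(imp$tables, function(tab) {
      d <- derive_body_composition(tab, eth_map)
      suppressWarnings(classify_one(d, cc_cutoffs))
    })
    flagged_sets <- lapply(completed, `[[`, "flags")
    cutoffs <- completed[[1]]$cutoffs
    flags <- flagged_sets[[1]]
    prevalence <- do.call(rbind, unlist(lapply(
      sort(unique(derived$site)), function(s) {
        lapply(c("sarcopenia", "sarcopenic_obesity"), function(oc) {
          prevalence_over_imputations(flagged_sets, s, oc)
        })
      }), recursive = FALSE))
    fit_list <- lapply(flagged_sets, function(tab) {
      suppressMessages(fit_all_sites(tab, min_cases = config$min_cases))
    })
    site_fits <- pool_fit_list(fit_list)
  } else {
    log_stage("stage classify (complete case; ", n_missing_weight,
              " record(s) without weight)")
    cls <- suppressWarnings(classify_one(derived))
    cutoffs <- cls$cutoffs
    flags <- cls$flags
    log_stage("stage prevalence")
    prevalence <- prevalence_table(flags)
    log_stage("stage associate")
    site_fits <- suppressMessages(
      fit_all_sites(flags, min_cases = config$min_cases))
  }

  log_stage("stage meta")
  pooled <- suppressMessages(build_pooled_tables(site_fits))

  provenance <- list(
    package_version = as.character(utils::packageVersion("sarcopool")),
    seed = config$seed,
    input = if (is.null(config$input)) "simulated" else config$input,
    imputation = list(triggered = use_mi, sites = impute_sites,
                      m = if (use_mi) config$m else 0L,
                      threshold = config$impute_threshold,
                      cutoff_scope = config$cutoff_scope,
                      n_missing_weight = n_missing_weight,
                      n_excluded_complete_case =
                        if (use_mi) 0L else n_missing_weight),
    row_counts = list(cohort = nrow(cohort),
                      rejected = nrow(cohort_rejects(cohort)),
                      flags = nrow(flags),
                      site_fits = nrow(site_fits),
                      pooled = nrow(pooled)),
    settings = list(min_stratum = config$min_stratum, qtype = config$qtype,
                    min_cases = config$min_cases),
    truth = if (is.null(config$input)) unclass(config$truth) else NULL,
    profiles = if (is.null(config$input)) {
      lapply(config$profiles, unclass)
    } else NULL
  )

  paths <- c(
    derived = write_stage(derived, file.path(config$out_dir,
                                             "derived.csv")),
    cutoffs = write_stage(cutoffs_long(cutoffs),
                          file.path(config$out_dir, "cutoffs.csv")),
    flags = write_stage(flags, file.path(config$out_dir, "flags.csv")),
    prevalence = write_stage(prevalence,
                             file.path(config$out_dir, "prevalence.csv")),
    site_fits = write_stage(site_fits,
                            file.path(config$out_dir, "site_fits.csv")),
    pooled = write_stage(pooled, file.path(config$out_dir, "pooled.csv")),
    provenance = {
      p <- file.path(config$out_dir, "provenance.json")
      jsonlite::write_json(provenance, p, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      p
    }
  )
  log_stage("done: ", config$out_dir)
  invisible(list(cohort = cohort, cutoffs = cutoffs, flags = flags,
                 prevalence = prevalence, site_fits = site_fits,
                 pooled = pooled, provenance = provenance, paths = paths))
}
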