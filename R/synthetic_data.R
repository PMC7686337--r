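# Synthetic multi-site cohort generator with embedded ground truth.
#
# Ground truth is induced, not labelled: covariate effects shape the
# continuous generators (height, body-mass index, gait speed) and case
# status emerges downstream from the stratified quintile definitions, so
# parameter-recovery experiments exercise the real case-definition code
# path.
#
# Mechanism (documented in detail in the methods vignette):
#  * Height and BMI are drawn independently within sex; weight = BMI * h^2.
#    SMI is then a deterministic function of (height, BMI, age, sex), and
#    because %BF pins BMI given age and sex, the probability of falling in
#    the lowest SMI quintile given the model covariates z,
#    pL(z) = P(height < h*(BMI, age, sex, site)), is available in closed
#    form: height is the only unobserved quantity given z.
#  * The sarcopenia target propensity is pi(z) = plogis(alpha + eta(z)) with
#    eta the TruthSpec log-odds effects; the per-site intercept alpha is
#    solved so that the mean of min(pi, pL) equals the profile's target
#    prevalence.
#  * The slow-gait flag is allocated conditional on low-SMI status so that
#    P(sarcopenia | z) = pL(z) * min(1, pi(z)/pL(z)) = min(pi(z), pL(z)),
#    while keeping the slow-gait mass at 20% within every
#    sex x age band x height band stratum. Gait speeds are then drawn
#    rank-faithfully within stratum (a common stratum base level times a
#    lognormal spread), so that the empirical quintile reproduces the
#    allocation and speeds still fall with age and rise with height across
#    strata.

#' Construct and validate one site profile
#'
#' All distributional knobs of the generator for one site. Category
#' probability vectors must sum to one; rates live in \[0, 1\].
#'
#' @param site site label.
#' @param n target sample size (>= 1).
#' @param ethnicity ethnicity constant set for the ASM equation.
#' @param age_band_probs probabilities of the 65-69/70-74/75-79/80+ bands.
#' @param p_female proportion female.
#' @param height_mean,height_sd named (female, male) height moments, metres.
#' @param bmi_meanlog,bmi_sdlog named (female, male) log-BMI moments.
#' @param bmi_age_slope additive log-BMI trend per year of age beyond 70.
#' @param gait named vector: b0 (log speed at reference), b_age (per year),
#'   b_height (per metre), b_male, sigma (lognormal spread within stratum).
#' @param education_probs,marital_probs,impairment_probs named probability
#'   vectors over the dictionary levels.
#' @param assets_p per-item probability of owning each of the 7 assets
#'   (modulated by the latent socio-economic factor).
#' @param smoking_ever,alcohol_moderate,activity_low scalar prevalences.
#' @param disease_probs named (dementia, depression, diabetes, stroke).
#' @param weight_missing_rate target missing-weight fraction.
#' @param mar named missing-at-random log-odds slopes (age, male, height)
#'   for the weight-missingness mechanism.
#' @param gait_missing_rate missing-completely-at-random walk-time fraction.
#' @param target_prevalence target crude sarcopenia prevalence (< 0.18; the
#'   quintile construction caps attainable prevalence at 20%).
#' @return validated `site_profile` list.
#' @export
site_profile <- function(site, n,
                         ethnicity = "white_hispanic",
                         age_band_probs = c(0.32, 0.28, 0.22, 0.18),
                         p_female = 0.60,
                         height_mean = c(female = 1.503, male = 1.620),
                         height_sd = c(female = 0.055, male = 0.060),
                         bmi_meanlog = c(female = log(18.4),
                                         male = log(23.0)),
                         bmi_sdlog = c(female = 0.16, male = 0.15),
                         bmi_age_slope = -0.002,
                         gait = c(b0 = log(0.95), b_age = 0.018,
                                  b_height = 0.9, b_male = 0.05,
                                  sigma = 0.35),
                         education_probs = c(none = 0.15,
                                             incomplete_primary = 0.30,
                                             primary = 0.30,
                                             secondary = 0.15,
                                             tertiary = 0.10),
                         marital_probs = c(never = 0.07,
                                           married_cohab = 0.50,
                                           widowed = 0.33,
                                           divorced_sep = 0.10),
                         assets_p = 0.80,
                         smoking_ever = 0.15,
                         alcohol_moderate = 0.07,
                         activity_low = 0.35,
                         impairment_probs = c(none = 0.40, one_two = 0.44,
                                              three_plus = 0.16),
                         disease_probs = c(dementia = 0.08,
                                           depression = 0.12,
                                           diabetes = 0.15, stroke = 0.07),
                         weight_missing_rate = 0.02,
                         mar = c(age = 0.04, male = -0.2, height = 0),
                         gait_missing_rate = 0,
                         target_prevalence = 0.04) {
  p <- as.list(environment())
  chk_probs <- function(x, k, what) {
    if (length(x) != k || any(!is.finite(x)) || any(x < 0) ||
        abs(sum(x) - 1) > 1e-8) {
      stop("profile '", site, "': ", what,
           " must be ", k, " non-negative probabilities summing to 1")
    }
  }
  if (!is.character(site) || nchar(site) == 0) stop("site label required")
  if (!is.numeric(n) || n < 1) stop("profile '", site, "': n must be >= 1")
  chk_probs(age_band_probs, 4, "age_band_probs")
  chk_probs(education_probs, 5, "education_probs")
  chk_probs(marital_probs, 4, "marital_probs")
  chk_probs(impairment_probs, 3, "impairment_probs")
  rates <- c(p_female, assets_p, smoking_ever, alcohol_moderate,
             activity_low, disease_probs, weight_missing_rate,
             gait_missing_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("profile '", site, "': all rates must lie in [0, 1]")
  }
  if (any(height_sd <= 0) || any(bmi_sdlog <= 0) || gait[["sigma"]] <= 0) {
    stop("profile '", site, "': noise SDs must be positive")
  }
  if (target_prevalence <= 0 || target_prevalence >= 0.18) {
    stop("profile '", site, "': target_prevalence must lie in (0, 0.18); ",
         "the quintile case definition caps prevalence at 20%")
  }
  asm_race_constant(ethnicity)   # validates the label
  p$n <- as.integer(n)
  dict <- cohort_dictionary()$levels
  names(p$age_band_probs) <- c("65-69", "70-74", "75-79", "80+")
  names(p$education_probs) <- dict$education
  names(p$marital_probs) <- dict$marital
  names(p$impairment_probs) <- dict$impairments
  for (v in c("female", "male")) {
    stopifnot(v %in% names(p$height_mean), v %in% names(p$height_sd),
              v %in% names(p$bmi_meanlog), v %in% names(p$bmi_sdlog))
  }
  structure(p, class = "site_profile")
}

#' Embedded ground truth for the synthetic cohort
#'
#' Log-odds effects on the sarcopenia propensity (odds-ratio scale for
#' convenience) plus optional linear SMI shifts per covariate. The %BF and
#' age defaults track the structural gradients that the body-composition
#' equations themselves impose on the low-SMI probability, which keeps the
#' target propensity inside its feasible envelope (see the methods
#' vignette); the male odds ratio is a free effect carried by the gait
#' channel.
#'
#' @param or_male sarcopenia odds ratio, men vs women.
#' @param or_pbf sarcopenia odds ratio per percentage point of %BF.
#' @param or_age sarcopenia odds ratio per year of age.
#' @param smi_effects named list of additive SMI effects realised through
#'   height shifts: `assets` (per asset count) and/or `education` (per
#'   ordinal education step 0-4).
#' @return `truth_spec` list with effects on the log-odds scale.
#' @export
truth_spec <- function(or_male = 2.8, or_pbf = 1.08, or_age = 1.14,
                       smi_effects = list()) {
  stopifnot(is.finite(or_male), is.finite(or_pbf), is.finite(or_age),
            or_male > 0, or_pbf > 0, or_age > 0)
  ok <- names(smi_effects) %in% c("assets", "education")
  if (length(smi_effects) > 0 && !all(ok)) {
    stop("smi_effects supports 'assets' and 'education'")
  }
  structure(list(log_or_male = log(or_male), log_or_pbf = log(or_pbf),
                 log_or_age = log(or_age), smi_effects = smi_effects),
            class = "truth_spec")
}

sample_age <- function(band, n) {
  lo <- c(`65-69` = 65, `70-74` = 70, `75-79` = 75)[band]
  age <- ifelse(is.na(lo), 80 + pmin(stats::rgeom(n, 0.25), 17),
                lo + floor(stats::runif(n, 0, 5)))
  as.numeric(age)
}

# height threshold h* below which SMI(h; BMI, age, sex) <= cutoff
smi_height_threshold <- function(cutoff, bmi, age, sex01, race) {
  B <- 6.6 * sex01 - 0.098 * age + race - 3.3
  b <- 7.8 / bmi
  c0 <- B / bmi - cutoff
  disc <- b^2 - 4 * 0.244 * c0
  disc[disc < 0] <- NA_real_
  (-b + sqrt(disc)) / (2 * 0.244)
}

solve_rate_intercept <- function(lp, target, cap = NULL) {
  f <- function(a) {
    p <- stats::plogis(a + lp)
    if (!is.null(cap)) p <- pmin(p, cap)
    mean(p) - target
  }
  stats::uniroot(f, c(-40, 20), tol = 1e-10)$root
}

#' Simulate a multi-site cohort with embedded ground truth
#'
#' Generates a complete, validated cohort of `sum(n)` records, then (by
#' default) applies the per-site missing-at-random weight mechanism.
#' Identical (profiles, truth, seed) yield an identical table.
#'
#' @param profiles list of [site_profile()]s with distinct site labels.
#' @param truth [truth_spec()] ground truth.
#' @param seed integer seed; recorded in the provenance attribute.
#' @param missingness apply the weight/gait missingness mechanisms
#'   (`FALSE` returns the complete cohort).
#' @return A `cohort` table (raw columns only). Attribute `generator` holds
#'   provenance: seed, truth, per-site solved propensity intercepts,
#'   realised low-SMI cut-offs and coupling diagnostics (clamp fraction of
#'   the propensity against its feasibility envelope, realised case rate).
#' @export
simulate_cohort <- function(profiles, truth = truth_spec(), seed = 1,
                            missingness = TRUE) {
  if (inherits(profiles, "site_profile")) profiles <- list(profiles)
  if (length(profiles) < 1L) stop("at least one site profile is required")
  for (p in profiles) {
    if (!inherits(p, "site_profile")) {
      stop("profiles must be built with site_profile()")
    }
  }
  sites <- vapply(profiles, function(p) p$site, character(1))
  if (anyDuplicated(sites)) stop("duplicate site labels in profiles")
  if (!inherits(truth, "truth_spec")) stop("truth must be a truth_spec()")
  names(profiles) <- sites
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  dict <- cohort_dictionary()$levels

  parts <- lapply(profiles, function(p) {
    n <- p$n
    band <- sample(names(p$age_band_probs), n, TRUE, p$age_band_probs)
    age <- sample_age(band, n)
    sex <- ifelse(stats::runif(n) < p$p_female, "female", "male")
    ses <- stats::rnorm(n)
    edu_lat <- stats::pnorm(0.8 * ses + 0.6 * stats::rnorm(n))
    education <- dict$education[
      1L + findInterval(edu_lat, cumsum(p$education_probs)[-5])]
    assets <- stats::rbinom(n, 7,
                            stats::plogis(stats::qlogis(p$assets_p) +
                                            0.7 * ses))
    marital <- sample(dict$marital, n, TRUE, p$marital_probs)
    smoking <- ifelse(stats::runif(n) < p$smoking_ever, "ever", "never")
    alcohol <- ifelse(stats::runif(n) < p$alcohol_moderate,
                      "moderate", "none_or_heavy")
    phys_activity <- ifelse(stats::runif(n) < p$activity_low,
                            "low", "high")
    impairments <- sample(dict$impairments, n, TRUE, p$impairment_probs)
    dementia <- stats::rbinom(n, 1, p$disease_probs[["dementia"]])
    depression <- stats::rbinom(n, 1, p$disease_probs[["depression"]])
    diabetes <- stats::rbinom(n, 1, p$disease_probs[["diabetes"]])
    stroke <- stats::rbinom(n, 1, p$disease_probs[["stroke"]])

    # truth SMI effects enter through height, scaled by the structural
    # gradient dSMI/dheight evaluated at the profile's typical build
    shift <- numeric(n)
    kappa <- 0.488 * unname(p$height_mean[sex]) +
      7.8 / exp(unname(p$bmi_meanlog[sex]))
    if (!is.null(truth$smi_effects$assets)) {
      shift <- shift + truth$smi_effects$assets * assets / kappa
    }
    if (!is.null(truth$smi_effects$education)) {
      edu_idx <- match(education, dict$education) - 1
      shift <- shift + truth$smi_effects$education * edu_idx / kappa
    }
    h_mu <- unname(p$height_mean[sex]) + shift
    height <- stats::rnorm(n, h_mu, unname(p$height_sd[sex]))
    height <- pmin(pmax(height, 1.05), 2.15)
    bmi <- exp(stats::rnorm(n,
                            unname(p$bmi_meanlog[sex]) +
                              p$bmi_age_slope * (age - 70),
                            unname(p$bmi_sdlog[sex])))
    weight <- pmin(pmax(bmi * height^2, 25.5), 249)
    data.frame(site = p$site, age = age, sex = sex, height = height,
               h_mu = h_mu, h_sd = unname(p$height_sd[sex]),
               weight = weight, education = education, marital = marital,
               assets = assets, smoking = smoking, alcohol = alcohol,
               phys_activity = phys_activity, impairments = impairments,
               dementia = dementia, depression = depression,
               diabetes = diabetes, stroke = stroke,
               race = asm_race_constant(p$ethnicity),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  rownames(df) <- NULL
  n_all <- nrow(df)
  male <- as.numeric(df$sex == "male")
  bmi_real <- df$weight / df$height^2
  asm <- suppressWarnings(
    compute_asm(df$weight, df$height, df$age, male,
                c("white_hispanic", "black", "asian")[
                  match(df$race, c(0, 1.4, -1.2))]))
  smi <- asm / bmi_real
  pbf <- suppressWarnings(compute_pbf(bmi_real, df$age, male))

  # realised low-SMI flag and its closed-form conditional probability
  strat <- interaction(df$site, df$sex, drop = TRUE)
  cutoff <- stats::ave(smi, strat,
                       FUN = function(v) stats::quantile(v, 0.2, type = 7))
  L <- smi <= cutoff
  h_star <- smi_height_threshold(cutoff, bmi_real, df$age, male, df$race)
  h_star[is.na(h_star)] <- -Inf

  # Height-band decomposition. Sarcopenia requires low SMI *and* slow
  # gait, and slow gait carries at most 20% mass within each sex x age
  # band x height band stratum; because low SMI concentrates among the
  # short, the case probability must be spread across height bands in
  # proportion to each band's capacity min(pL_b, tau) or old short strata
  # would overflow their slow-gait quota. All terms are closed-form in the
  # height prior (height is the only unobserved variable given the model
  # covariates).
  gband <- age_band(df$age)
  hband <- height_band(df$height, df$sex)
  brk <- attr(hband, "breaks")
  gstrat <- interaction(df$sex, gband, hband, drop = TRUE)
  band_cap <- 0.18   # per-band designed mass; leaves slack under the 20%
                     # slow-gait quota for the quota fill and trim noise
  t1 <- vapply(brk, `[`, numeric(1), 1)[df$sex]
  t2 <- vapply(brk, `[`, numeric(1), 2)[df$sex]
  F_h <- function(x) stats::pnorm(x, df$h_mu, df$h_sd)
  p_b <- cbind(F_h(t1), F_h(t2) - F_h(t1), 1 - F_h(t2))
  pL_b <- cbind(
    F_h(pmin(h_star, t1)),
    F_h(pmin(pmax(h_star, t1), t2)) - F_h(t1),
    pmax(0, F_h(h_star) - F_h(t2))
  ) / pmax(p_b, 1e-12)
  pL_b[] <- pmin(pmax(pL_b, 0), 1)
  # Per-band envelope and floor. The envelope caps the designed mass
  # under the 20% slow-gait quota; the floor reflects that when a band's
  # low-SMI share exceeds 80%, part of the quota must fall on low-SMI
  # people, so some cases are unavoidable there.
  l_b <- pmin(pmax(pL_b - 0.76, 0), 0.199)
  e_b <- pmax(pmin(pL_b, band_cap), l_b)

  # Water-filling allocation of the propensity pi over height bands:
  # x_b = clamp(lambda, l_b, e_b) with a common level lambda per person
  # such that sum_b p_b x_b = pi; solved by bisection (the sum is
  # monotone in lambda). x_b is the band-conditional case probability.
  waterfill <- function(pi_i, p_b, e_b, l_b) {
    n <- length(pi_i)
    q1 <- p_b[, 1]; q2 <- p_b[, 2]; q3 <- p_b[, 3]
    l1 <- l_b[, 1]; l2 <- l_b[, 2]; l3 <- l_b[, 3]
    e1 <- e_b[, 1]; e2 <- e_b[, 2]; e3 <- e_b[, 3]
    floor_i <- q1 * l1 + q2 * l2 + q3 * l3
    env_i <- q1 * e1 + q2 * e2 + q3 * e3
    pi_i <- pmin(pmax(pi_i, floor_i), env_i)
    lo <- numeric(n)
    hi <- rep(band_cap, n)
    for (it in 1:22) {
      lam <- (lo + hi) / 2
      tot <- q1 * pmin(pmax(lam, l1), e1) + q2 * pmin(pmax(lam, l2), e2) +
        q3 * pmin(pmax(lam, l3), e3)
      below <- tot < pi_i
      lo[below] <- lam[below]
      hi[!below] <- lam[!below]
    }
    lam <- (lo + hi) / 2
    cbind(pmin(pmax(lam, l1), e1), pmin(pmax(lam, l2), e2),
          pmin(pmax(lam, l3), e3))
  }
  # The requested odds ratios are defined as estimands of the logistic
  # model the pipeline fits. Because the case probability is clipped to
  # the feasibility envelope, raw propensity coefficients would be
  # attenuated in the fitted model; the generator therefore calibrates
  # them so that the population logistic projection of the designed case
  # probabilities onto (male, age, %BF) equals the requested effects.
  envelope <- rowSums(p_b * e_b)
  targets <- c(truth$log_or_male, truth$log_or_age, truth$log_or_pbf)
  target_prev <- vapply(profiles, function(p) p$target_prevalence,
                        numeric(1))
  for (s in sites) {
    idx <- which(df$site == s)
    max_prev <- mean(envelope[idx])
    if (target_prev[[s]] > 0.9 * max_prev) {
      stop("profile '", s, "': target_prevalence ", target_prev[[s]],
           " exceeds the feasible envelope (about ",
           round(0.9 * max_prev, 3),
           ") implied by the stratified quintile definitions")
    }
  }
  age_c <- df$age - 70
  beta <- targets
  alpha <- stats::qlogis(target_prev[sites])
  names(alpha) <- sites
  site_idx <- split(seq_len(n_all), df$site)
  proj_X <- cbind(1, male, age_c, pbf)
  err <- rep(Inf, 3)
  proj <- rep(NA_real_, 3)
  proj_start <- NULL
  for (iter in 1:60) {
    lp <- beta[1] * male + beta[2] * age_c + beta[3] * pbf
    pi_target <- stats::plogis(alpha[df$site] + lp)
    x_b <- waterfill(pi_target, p_b, e_b, l_b)
    designed <- rowSums(p_b * x_b)
    # joint fixed point: per-site intercepts match the target prevalences
    # while the logistic projection of the designed probabilities matches
    # the requested effects
    prev_err <- vapply(sites, function(s) {
      stats::qlogis(target_prev[[s]]) -
        stats::qlogis(max(1e-6, mean(designed[site_idx[[s]]])))
    }, numeric(1))
    # settle the site intercepts before spending projection fits
    if (max(abs(prev_err)) > 0.03) {
      alpha <- alpha + prev_err
      next
    }
    proj_fit <- suppressWarnings(stats::glm.fit(
      proj_X, designed, family = stats::quasibinomial(),
      start = proj_start,
      control = stats::glm.control(epsilon = 1e-8, maxit = 8)))
    proj_start <- proj_fit$coefficients
    proj <- proj_fit$coefficients[2:4]
    # only the male effect is calibrated to its projection; the age and
    # %BF requests shape the free propensity component while their fitted
    # values also absorb the structural floor component
    err <- targets[1] - proj[1]
    if (abs(err) < 0.004 && max(abs(prev_err)) < 0.02) break
    alpha <- alpha + prev_err
    beta[1] <- beta[1] + 1.2 * err
  }
  if (max(abs(err)) >= 0.02) {   # male-effect calibration tolerance
    warning("truth calibration did not fully converge; achieved ",
            "projected effects ", paste(round(proj, 3), collapse = ", "),
            " vs requested ", paste(round(targets, 3), collapse = ", "))
  }
  pL <- rowSums(p_b * pL_b)
  band_idx <- match(as.character(hband), c("short", "medium", "tall"))
  sel <- cbind(seq_len(n_all), band_idx)
  gamma <- pmin(1, pmax(0, x_b[sel] / pmax(pL_b[sel], 1e-12)))

  # slow-gait allocation: cases among the low-SMI; the remaining quota is
  # filled with an exact-count draw from the non-low-SMI pool so that the
  # realised slow-gait mass sits at the 20% quintile boundary and the
  # empirical cut-off reproduces the designed allocation
  G <- logical(n_all)
  G[L] <- stats::runif(sum(L)) < gamma[L]
  for (g in levels(gstrat)) {
    idx <- which(gstrat == g)
    quota <- round(0.2 * length(idx))
    pool <- idx[!L[idx]]
    k <- min(length(pool), max(0, quota - sum(G[idx])))
    if (k > 0) G[sample(pool, k)] <- TRUE
  }

  # rank-faithful gait speeds: common base per stratum, lognormal spread
  gp <- colMeans(do.call(rbind, lapply(profiles, function(p) p$gait)))
  u <- ifelse(G, 0.2 * stats::runif(n_all),
              0.2 + 0.8 * stats::runif(n_all))
  base <- stats::ave(seq_len(n_all), gstrat, FUN = function(i) {
    rep(exp(gp[["b0"]] + gp[["b_height"]] * (mean(df$height[i]) - 1.60) -
              gp[["b_age"]] * (mean(df$age[i]) - 70) +
              gp[["b_male"]] * (df$sex[i[1]] == "male")),
        length(i))
  })
  speed <- base * exp(gp[["sigma"]] * stats::qnorm(u))
  walk_time <- 10 / speed

  out <- data.frame(
    pid = sprintf("%s_%05d", df$site, stats::ave(seq_len(n_all), df$site,
                                                 FUN = seq_along)),
    site = df$site, age = df$age, sex = df$sex,
    height = round(df$height, 4), weight = round(df$weight, 2),
    walk_time_10m = round(walk_time, 2),
    education = df$education, marital = df$marital, assets = df$assets,
    smoking = df$smoking, alcohol = df$alcohol,
    phys_activity = df$phys_activity, impairments = df$impairments,
    dementia = df$dementia, depression = df$depression,
    diabetes = df$diabetes, stroke = df$stroke,
    stringsAsFactors = FALSE
  )
  if (missingness) {
    out <- apply_missingness_impl(out, profiles)
    for (p in profiles) {
      if (p$gait_missing_rate > 0) {
        idx <- which(out$site == p$site)
        drop <- idx[stats::runif(length(idx)) < p$gait_missing_rate]
        out$walk_time_10m[drop] <- NA_real_
      }
    }
  }
  cohort <- as_cohort(out, sites = sites,
                      provenance = sprintf("simulate_cohort(seed = %d)",
                                           seed))
  if (nrow(cohort_rejects(cohort)) > 0L) {
    stop("internal error: generated cohort failed validation")
  }
  cutoff_tab <- unique(data.frame(site = df$site, sex = df$sex,
                                  low_smi_cutoff = cutoff,
                                  stringsAsFactors = FALSE))
  attr(cohort, "generator") <- list(
    seed = seed, truth = truth, alpha = alpha,
    sites = sites, n = vapply(profiles, function(p) p$n, integer(1)),
    low_smi_cutoffs = cutoff_tab[order(cutoff_tab$site, cutoff_tab$sex), ],
    diagnostics = list(
      clamp_fraction = mean(designed < pi_target - 1e-6),
      clamp_mass = mean(pi_target - designed),
      calibrated_beta = beta,
      projected_effects = proj,
      case_rate = mean(L & G),
      target_prevalence = vapply(profiles,
                                 function(p) p$target_prevalence,
                                 numeric(1))
    )
  )
  cohort
}

apply_missingness_impl <- function(df, profiles) {
  for (p in profiles) {
    rate <- p$weight_missing_rate
    if (rate <= 0) next
    idx <- which(df$site == p$site)
    if (rate >= 1) {
      df$weight[idx] <- NA_real_
      next
    }
    lp <- p$mar[["age"]] * (df$age[idx] - 75) +
      p$mar[["male"]] * (df$sex[idx] == "male") +
      p$mar[["height"]] * (df$height[idx] - 1.6)
    a0 <- solve_rate_intercept(lp, rate)
    drop <- stats::runif(length(idx)) < stats::plogis(a0 + lp)
    df$weight[idx][drop] <- NA_real_
  }
  df
}

#' Apply the missing-at-random weight mechanism to a complete cohort
#'
#' Sets weight to missing with probability logistic in (age, sex, height)
#' per the site profile's MAR slopes; the intercept is solved so the
#' expected missing fraction equals the profile's rate. All other fields are
#' untouched.
#'
#' @param table cohort complete in weight.
#' @param profiles list of [site_profile()]s covering the table's sites.
#' @param seed integer seed.
#' @return the table with weight set missing per the mechanism.
#' @export
apply_missingness <- function(table, profiles, seed = 1) {
  if (inherits(profiles, "site_profile")) profiles <- list(profiles)
  if (any(is.na(table$weight))) stop("table must be complete in weight")
  names(profiles) <- vapply(profiles, function(p) p$site, character(1))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  df <- apply_missingness_impl(as.data.frame(table), profiles)
  as_cohort(df, provenance = attr(table, "provenance"))
}

#' Nine homogeneous site profiles for recovery experiments
#'
#' Identical anthropometric and covariate distributions in every site (the
#' condition for homogeneous-truth pooling experiments: between-site
#' variability then reflects sampling error only).
#'
#' @param n per-site sample size.
#' @param k number of sites.
#' @param target_prevalence common target sarcopenia prevalence.
#' @param ... further arguments passed to every [site_profile()].
#' @return list of `site_profile`s labelled site01..site0k.
#' @export
uniform_site_profiles <- function(n = 5000, k = 9,
                                  target_prevalence = 0.04,
                                  weight_missing_rate = 0, ...) {
  lapply(seq_len(k), function(i) {
    site_profile(sprintf("site%02d", i), n = n,
                 target_prevalence = target_prevalence,
                 weight_missing_rate = weight_missing_rate, ...)
  })
}

#' Default nine-site profiles
#'
#' Loosely calibrated to the marginal structure of a nine-site ageing cohort
#' across Latin America, the Caribbean and China: site-specific sample
#' sizes, age structures, builds (so that the site-specific low-SMI
#' cut-offs spread over a realistic range), covariate prevalences, and
#' weight missingness concentrated in two sites (Cuba and Puerto Rico
#' style), where the missing-at-random mechanism leans on age.
#'
#' @param n_scale multiplies every site's sample size (use < 1 for quick
#'   demos).
#' @return named list of nine `site_profile`s.
#' @export
default_site_profiles <- function(n_scale = 1) {
  spec <- list(
    cuba = list(n = 1913, age = c(0.31, 0.29, 0.22, 0.18),
                hf = 1.500, hm = 1.650, bf = 19.0, bm = 23.5,
                edu = c(0.02, 0.20, 0.32, 0.27, 0.19), prev = 0.030,
                miss = 0.28, eth = "white_hispanic"),
    dominican_republic = list(n = 1085, age = c(0.32, 0.30, 0.20, 0.18),
                hf = 1.480, hm = 1.630, bf = 18.3, bm = 23.0,
                edu = c(0.19, 0.50, 0.19, 0.08, 0.04), prev = 0.030,
                miss = 0.02, eth = "white_hispanic"),
    peru_urban = list(n = 832, age = c(0.29, 0.28, 0.22, 0.21),
                hf = 1.475, hm = 1.625, bf = 18.0, bm = 22.8,
                edu = c(0.02, 0.06, 0.31, 0.38, 0.23), prev = 0.040,
                miss = 0.02, eth = "white_hispanic"),
    peru_rural = list(n = 410, age = c(0.36, 0.27, 0.19, 0.18),
                hf = 1.465, hm = 1.615, bf = 17.8, bm = 22.5,
                edu = c(0.12, 0.24, 0.52, 0.08, 0.04), prev = 0.048,
                miss = 0.02, eth = "white_hispanic"),
    mexico_urban = list(n = 684, age = c(0.28, 0.35, 0.20, 0.17),
                hf = 1.470, hm = 1.620, bf = 18.0, bm = 22.8,
                edu = c(0.18, 0.37, 0.24, 0.11, 0.10), prev = 0.040,
                miss = 0.02, eth = "white_hispanic"),
    mexico_rural = list(n = 634, age = c(0.33, 0.28, 0.21, 0.18),
                hf = 1.460, hm = 1.610, bf = 17.7, bm = 22.4,
                edu = c(0.32, 0.50, 0.12, 0.04, 0.02), prev = 0.040,
                miss = 0.02, eth = "white_hispanic"),
    china_urban = list(n = 692, age = c(0.34, 0.33, 0.22, 0.11),
                hf = 1.510, hm = 1.655, bf = 19.2, bm = 23.6,
                edu = c(0.20, 0.14, 0.23, 0.31, 0.12), prev = 0.042,
                miss = 0.02, eth = "asian"),
    china_rural = list(n = 692, age = c(0.46, 0.31, 0.17, 0.06),
                hf = 1.505, hm = 1.650, bf = 19.0, bm = 23.4,
                edu = c(0.53, 0.12, 0.28, 0.06, 0.01), prev = 0.030,
                miss = 0.02, eth = "asian"),
    puerto_rico = list(n = 907, age = c(0.25, 0.28, 0.27, 0.20),
                hf = 1.495, hm = 1.645, bf = 18.8, bm = 23.3,
                edu = c(0.02, 0.17, 0.18, 0.40, 0.23), prev = 0.040,
                miss = 0.30, eth = "white_hispanic")
  )
  profiles <- lapply(names(spec), function(s) {
    d <- spec[[s]]
    edu <- d$edu
    names(edu) <- cohort_dictionary()$levels$education
    site_profile(
      s, n = max(1, round(d$n * n_scale)),
      ethnicity = d$eth,
      age_band_probs = d$age / sum(d$age),
      height_mean = c(female = d$hf, male = d$hm),
      bmi_meanlog = c(female = log(d$bf), male = log(d$bm)),
      education_probs = edu / sum(edu),
      weight_missing_rate = d$miss,
      target_prevalence = d$prev
    )
  })
  names(profiles) <- names(spec)
  profiles
}
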