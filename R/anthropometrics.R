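# Derived body-composition quantities: BMI, %BF, ASM, SMI, gait speed.
#
# %BF uses the validated adult anthropometric prediction equation
#   %BF = 1.20*BMI + 0.23*age - 10.8*sex - 5.4        (sex: male = 1)
# ASM uses the published anthropometric skeletal-muscle equation
#   ASM = 0.244*weight + 7.80*height + 6.6*sex - 0.098*age + race - 3.3
# with race an additive constant: 0 white/Hispanic, +1.4 Black, -1.2 Asian.
# All five operations are pure and vectorised; missing inputs propagate to
# missing outputs. Out-of-range derived values are flagged via warnings,
# never clipped or dropped, so that downstream quantile cut-offs see exactly
# the data the equations produce.

asm_race_constant <- function(ethnicity) {
  race <- c(white_hispanic = 0, black = 1.4, asian = -1.2)
  bad <- !(ethnicity %in% names(race))
  if (any(bad)) stop("unknown ethnicity: ",
                     paste(unique(ethnicity[bad]), collapse = ", "))
  unname(race[ethnicity])
}

#' Body mass index
#'
#' @param weight kilograms (missing propagates).
#' @param height metres.
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(weight, height) {
  weight / height^2
}

#' Predicted percent body fat
#'
#' Population prediction equation from BMI, age and sex. Values outside the
#' physiologic band \[3, 75\]% are flagged with a warning but returned as-is.
#'
#' @param bmi kg/m^2 (missing propagates).
#' @param age years.
#' @param sex 0 = female, 1 = male (also accepts "female"/"male").
#' @return percent body fat.
#' @export
compute_pbf <- function(bmi, age, sex) {
  sex <- sex_code(sex)
  pbf <- 1.20 * bmi + 0.23 * age - 10.8 * sex - 5.4
  out_of_range <- !is.na(pbf) & (pbf < 3 | pbf > 75)
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " predicted %BF value(s) outside [3, 75]; kept unclipped")
  }
  pbf
}

#' Predicted appendicular skeletal muscle mass
#'
#' Anthropometric prediction equation from weight, height, sex, age and an
#' ethnicity constant assigned at site level. Negative or > 60 kg predictions
#' are flagged with a warning but returned as-is.
#'
#' @param weight kilograms (missing propagates).
#' @param height metres.
#' @param age years.
#' @param sex 0 = female, 1 = male (also accepts "female"/"male").
#' @param ethnicity one of "white_hispanic", "black", "asian" (recycled).
#' @return ASM in kg.
#' @export
compute_asm <- function(weight, height, age, sex,
                        ethnicity = "white_hispanic") {
  sex <- sex_code(sex)
  race <- asm_race_constant(ethnicity)
  asm <- 0.244 * weight + 7.80 * height + 6.6 * sex - 0.098 * age +
    race - 3.3
  out_of_range <- !is.na(asm) & (asm < 0 | asm > 60)
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " predicted ASM value(s) negative or > 60 kg; kept unclipped")
  }
  asm
}

#' Skeletal muscle mass index
#'
#' ASM divided by BMI; lower values indicate relatively low muscle mass.
#'
#' @param asm kg (missing propagates).
#' @param bmi kg/m^2, must be positive where present.
#' @return SMI (index).
#' @export
compute_smi <- function(asm, bmi) {
  if (any(!is.na(bmi) & bmi <= 0)) stop("bmi must be positive")
  asm / bmi
}

#' Gait speed over a 10-metre walk
#'
#' @param walk_time_10m seconds; missing or non-positive times yield missing
#'   speed (non-positive with a warning).
#' @return speed in m/s.
#' @export
compute_gait_speed <- function(walk_time_10m) {
  bad <- !is.na(walk_time_10m) & walk_time_10m <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive walk time(s); gait speed set missing")
    walk_time_10m[bad] <- NA_real_
  }
  10 / walk_time_10m
}

# map "female"/"male" or 0/1 to the 0/1 coding used by the equations
sex_code <- function(sex) {
  if (is.character(sex) || is.factor(sex)) {
    sex <- as.character(sex)
    ok <- sex %in% c("female", "male") | is.na(sex)
    if (!all(ok)) stop("sex must be 'female'/'male' or 0/1")
    as.numeric(sex == "male")
  } else {
    if (any(!is.na(sex) & !(sex %in% c(0, 1)))) {
      stop("sex must be 'female'/'male' or 0/1")
    }
    as.numeric(sex)
  }
}

#' Add derived body-composition columns to a cohort table
#'
#' Appends bmi, pbf, asm, smi and gait_speed. A record has missing body
#' composition iff weight or height is missing; gait speed is missing iff
#' walk time is missing or non-positive.
#'
#' @param table cohort data.frame.
#' @param ethnicity_map named character vector site -> ethnicity; sites not
#'   listed default to "white_hispanic".
#' @return the table with the five derived columns appended.
#' @export
derive_body_composition <- function(table,
                                    ethnicity_map = default_ethnicity_map()) {
  eth <- unname(ethnicity_map[table$site])
  eth[is.na(eth)] <- "white_hispanic"
  weight <- table$weight
  bad <- !is.na(weight) & weight <= 0
  if (any(bad)) {
    # possible for untruncated imputation draws; physically impossible, so
    # the record's derived values are set missing rather than computed
    warning(sum(bad), " non-positive weight value(s); derived body ",
            "composition set missing")
    weight[bad] <- NA_real_
  }
  table$bmi <- compute_bmi(weight, table$height)
  table$pbf <- suppressWarnings(
    compute_pbf(table$bmi, table$age, table$sex)
  )
  table$asm <- suppressWarnings(
    compute_asm(weight, table$height, table$age, table$sex, eth)
  )
  table$smi <- compute_smi(table$asm, table$bmi)
  table$gait_speed <- suppressWarnings(
    compute_gait_speed(table$walk_time_10m)
  )
  table
}

#' Default site -> ethnicity assignment for the ASM equation
#'
#' Latin American and Caribbean sites use the white/Hispanic constant (0);
#' the two China sites use the Asian constant.
#'
#' @return named character vector.
#' @export
default_ethnicity_map <- function() {
  sites <- default_sites()
  eth <- ifelse(sites %in% c("china_urban", "china_rural"),
                "asian", "white_hispanic")
  names(eth) <- sites
  eth
}
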