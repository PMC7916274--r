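#' Canonical design-matrix columns
#'
#' The ordered predictor columns used by every model in the package.
#' Reference levels (absorbed into the intercept): never smoker, female,
#' age 45--54, rural, primary education or below, unpartnered, not poor,
#' uninsured, west region, normal BMI, never drinker. The eight `it*`
#' columns are the smoking-by-age interactions: it1/it2 pair current light
#' smokers with ages 55--64 / 65+, it3/it4 current heavy smokers, it5/it6
#' former smokers who quit within 5 years, it7/it8 former smokers who quit
#' 5+ years ago.
#'
#' @return Character vector of column names in canonical order.
#' @export
design_columns <- function() {
  c("smk_current_light", "smk_current_heavy", "smk_former_lt5",
    "smk_former_ge5", "sex_male", "age_55_64", "age_65_plus", "res_urban",
    "edu_middle_plus", "marital_partnered", "poverty_yes", "insured_yes",
    "region_middle", "region_east", "bmi_underweight", "bmi_overweight",
    "drinker_yes",
    paste0("it", 1:8))
}

# Names of the columns zeroed by the never-smoker counterfactual.
smoking_design_columns <- function() {
  c("smk_current_light", "smk_current_heavy", "smk_former_lt5",
    "smk_former_ge5", paste0("it", 1:8))
}

#' Build the model design matrix from derived covariates
#'
#' Indicator (dummy) coding of the derived covariates plus the eight
#' smoking-by-age interaction products, in the canonical order of
#' [design_columns()]. The intercept is not materialized; model-fitting
#' functions add it.
#'
#' @param cov Derived covariates from [derive_covariates()] (or the
#'   equivalent columns).
#' @return A `data.frame` with `person_id`, `wave_year`, and the columns of
#'   [design_columns()], all indicators 0/1.
#' @export
build_design <- function(cov) {
  s <- as.character(cov$smoking_status)
  a <- as.character(cov$age_group)
  d <- data.frame(person_id = cov$person_id, wave_year = cov$wave_year)
  d$smk_current_light <- as.numeric(s == "current_light")
  d$smk_current_heavy <- as.numeric(s == "current_heavy")
  d$smk_former_lt5 <- as.numeric(s == "former_quit_lt5")
  d$smk_former_ge5 <- as.numeric(s == "former_quit_ge5")
  d$sex_male <- as.numeric(cov$sex == "male")
  d$age_55_64 <- as.numeric(a == "55_64")
  d$age_65_plus <- as.numeric(a == "65_plus")
  d$res_urban <- as.numeric(cov$residency == "urban")
  d$edu_middle_plus <- as.numeric(cov$education == "middle_or_above")
  d$marital_partnered <- as.numeric(cov$marital == "partnered")
  d$poverty_yes <- as.numeric(cov$poverty)
  d$insured_yes <- as.numeric(cov$insurance == "yes")
  d$region_middle <- as.numeric(cov$region == "middle")
  d$region_east <- as.numeric(cov$region == "east")
  d$bmi_underweight <- as.numeric(cov$bmi_class == "underweight")
  d$bmi_overweight <- as.numeric(cov$bmi_class == "overweight")
  d$drinker_yes <- as.numeric(cov$drinker)
  smk <- cbind(d$smk_current_light, d$smk_current_heavy,
               d$smk_former_lt5, d$smk_former_ge5)
  age <- cbind(d$age_55_64, d$age_65_plus)
  k <- 0
  for (j in 1:4) {
    for (m in 1:2) {
      k <- k + 1
      d[[paste0("it", k)]] <- smk[, j] * age[, m]
    }
  }
  d[, c("person_id", "wave_year", design_columns())]
}

# Extract the numeric predictor matrix (with intercept) from a design
# data.frame, in canonical column order.
design_matrix <- function(design, cols = design_columns()) {
  miss <- setdiff(cols, names(design))
  if (length(miss))
    stop("design is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(design[, cols, drop = FALSE])
  cbind("(Intercept)" = 1, X)
}
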