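#' Smoking index
#'
#' Lifetime smoking intensity: cigarettes smoked per day multiplied by the
#' number of years smoked. The index is the basis for splitting current
#' smokers into light (< 200) and heavy (>= 200) categories.
#'
#' @param cigs_per_day Cigarettes smoked per day (non-negative, finite).
#' @param years_smoked Years of smoking (non-negative, finite).
#' @return Numeric vector, `cigs_per_day * years_smoked`.
#' @examples
#' smoking_index(10, 30) # 300
#' @export
smoking_index <- function(cigs_per_day, years_smoked) {
  if (any(!is.finite(cigs_per_day)) || any(!is.finite(years_smoked)))
    stop("smoking_index: arguments must be finite", call. = FALSE)
  if (any(cigs_per_day < 0) || any(years_smoked < 0))
    stop("smoking_index: arguments must be non-negative", call. = FALSE)
  cigs_per_day * years_smoked
}

#' Smoking status levels
#'
#' Canonical ordering of the five-level smoking status factor.
#' @return Character vector of level names.
#' @export
smoking_levels <- function() {
  c("never", "current_light", "current_heavy",
    "former_quit_lt5", "former_quit_ge5")
}

#' Classify smoking status
#'
#' Five-level classification from smoking history. Never smokers are those
#' who have not smoked 100 cigarettes in their lifetime. Current smokers are
#' split at a smoking index of 200 (index of exactly 200 is classed heavy,
#' closing the boundary with the more conservative class); former smokers
#' are split at 5 years since quitting.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param ever_smoked_100 Logical; smoked at least 100 cigarettes ever.
#' @param currently_smokes Logical; smokes at present.
#' @param cigs_per_day,years_smoked Smoking intensity (see [smoking_index()]).
#' @param years_since_quit Years since quitting (0 for current/never).
#' @return Factor with levels [smoking_levels()].
#' @export
classify_smoking_status <- function(ever_smoked_100, currently_smokes,
                                    cigs_per_day, years_smoked,
                                    years_since_quit) {
  n <- max(lengths(list(ever_smoked_100, currently_smokes, cigs_per_day,
                        years_smoked, years_since_quit)))
  ever <- rep_len(as.logical(ever_smoked_100), n)
  cur <- rep_len(as.logical(currently_smokes), n)
  cigs <- rep_len(cigs_per_day, n)
  yrs <- rep_len(years_smoked, n)
  quit <- rep_len(years_since_quit, n)
  if (any(cur & !ever))
    stop("classify_smoking_status: currently_smokes requires ever_smoked_100",
         call. = FALSE)
  if (any(quit > 0 & (cur | !ever)))
    stop("classify_smoking_status: years_since_quit > 0 requires a former smoker",
         call. = FALSE)
  idx <- smoking_index(cigs, yrs)
  out <- rep("never", n)
  out[ever & cur & idx < 200] <- "current_light"
  out[ever & cur & idx >= 200] <- "current_heavy"
  out[ever & !cur & quit < 5] <- "former_quit_lt5"
  out[ever & !cur & quit >= 5] <- "former_quit_ge5"
  factor(out, levels = smoking_levels())
}

#' Classify poverty status
#'
#' Poverty is flagged when at least two of four deprivation indicators hold:
#' traditional cooking fuel, non-flushable toilet, no running water, and
#' ownership of fewer than two household assets.
#'
#' @param fuel Logical; cooking fuel is traditional (crop residue, wood).
#' @param toilet Logical; toilet is not flushable.
#' @param water Logical; residence has no running water.
#' @param asset_count Non-negative integer count of owned assets.
#' @return Logical vector.
#' @export
classify_poverty <- function(fuel, toilet, water, asset_count) {
  if (any(asset_count < 0))
    stop("classify_poverty: asset_count must be non-negative", call. = FALSE)
  hits <- as.numeric(fuel) + as.numeric(toilet) + as.numeric(water) +
    as.numeric(asset_count < 2)
  hits >= 2
}

#' Classify body-mass-index status
#'
#' BMI = weight (kg) / height (m)^2, classed against the Chinese normal
#' range 18.5--23.9 kg/m^2: below 18.5 underweight, above 23.9 overweight.
#'
#' @param weight_kg Body weight in kilograms (> 0).
#' @param height_m Height in meters (> 0).
#' @return Factor with levels `normal`, `underweight`, `overweight`.
#' @export
classify_bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0))
    stop("classify_bmi: weight and height must be positive", call. = FALSE)
  bmi <- weight_kg / height_m^2
  out <- ifelse(bmi < 18.5, "underweight",
                ifelse(bmi > 23.9, "overweight", "normal"))
  factor(out, levels = c("normal", "underweight", "overweight"))
}

#' Classify drinking status
#'
#' A drinker consumes any alcoholic beverage more than once a month
#' (strictly more than 1 drinking occasion per month).
#'
#' @param drink_freq_per_month Drinking occasions per month (>= 0).
#' @return Logical vector.
#' @export
classify_drinker <- function(drink_freq_per_month) {
  if (any(!is.finite(drink_freq_per_month)) || any(drink_freq_per_month < 0))
    stop("classify_drinker: frequency must be finite and non-negative",
         call. = FALSE)
  drink_freq_per_month > 1
}

#' Deflate a nominal amount to constant 2015 dollars
#'
#' Applies the medical-care component of the consumer price index to bring a
#' wave-year amount to 2015 price levels, then converts to dollars with a
#' fixed exchange rate.
#'
#' @param amount Nominal currency amount(s).
#' @param year Calendar year of the amount (must be a key of `cpi_medical`).
#' @param cpi_medical Named list/vector mapping year to medical-care CPI.
#'   Must contain `year` and 2015.
#' @param fx_rate Local-currency units per dollar (> 0). Default 1.
#' @return Amount in constant 2015 dollars.
#' @export
adjust_to_2015 <- function(amount, year, cpi_medical, fx_rate = 1) {
  cpi <- unlist(cpi_medical)
  yr <- as.character(year)
  if (!all(c(yr, "2015") %in% names(cpi)))
    stop("adjust_to_2015: cpi_medical must contain year ", year, " and 2015",
         call. = FALSE)
  if (fx_rate <= 0)
    stop("adjust_to_2015: fx_rate must be positive", call. = FALSE)
  amount * (cpi[["2015"]] / cpi[[yr]]) / fx_rate
}

# Required columns of a raw person-wave panel.
panel_columns <- function() {
  c("person_id", "wave_year", "sex", "age", "residency", "education",
    "marital", "insurance", "region", "cooking_fuel_traditional",
    "toilet_not_flushable", "no_running_water", "asset_count", "weight_kg",
    "height_m", "drink_freq_per_month", "ever_smoked_100", "currently_smokes",
    "cigs_per_day", "years_smoked", "years_since_quit",
    "used_outpatient_1m", "outpatient_exp_1m",
    "used_inpatient_12m", "inpatient_exp_12m",
    "used_selfmed_1m", "selfmed_exp_1m", "sampling_weight")
}

validate_panel <- function(panel) {
  miss <- setdiff(panel_columns(), names(panel))
  if (length(miss))
    stop("panel is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (svc in c("outpatient", "inpatient", "selfmed")) {
    use <- panel[[grep(paste0("^used_", svc), names(panel), value = TRUE)]]
    exp <- panel[[grep(paste0("^", svc, "_exp"), names(panel), value = TRUE)]]
    if (isTRUE(any(exp > 0 & !use, na.rm = TRUE)))
      stop("panel invariant violated: positive ", svc,
           " expenditure without a use flag", call. = FALSE)
  }
  if (isTRUE(any(panel$currently_smokes & !panel$ever_smoked_100,
                 na.rm = TRUE)))
    stop("panel invariant violated: current smoker without ever_smoked_100",
         call. = FALSE)
  invisible(panel)
}

#' Read a person-wave panel from CSV
#'
#' One row per person-wave; header names follow the raw record schema (see
#' [derive_covariates()] for the downstream coding). Validates the two-part
#' invariants (positive spending implies a use flag; current smokers have
#' smoked 100+ cigarettes).
#'
#' @param path Path to a UTF-8 CSV file with "." as decimal separator.
#' @return A `data.frame`, one row per person-wave.
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("cooking_fuel_traditional", "toilet_not_flushable",
                "no_running_water", "ever_smoked_100", "currently_smokes",
                "used_outpatient_1m", "used_inpatient_12m", "used_selfmed_1m"))
    panel[[col]] <- as.logical(panel[[col]])
  validate_panel(panel)
}

#' Deflate panel expenditures to constant 2015 dollars
#'
#' Applies [adjust_to_2015()] to the three expenditure columns of a raw
#' panel, using each row's wave year.
#'
#' @param panel Raw person-wave panel.
#' @param deflation List with elements `cpi_medical` (named year->index) and
#'   `fx_rate` (currency per dollar).
#' @return Panel with expenditure columns in 2015 dollars.
#' @export
deflate_panel <- function(panel, deflation) {
  cpi <- deflation$cpi_medical
  fx <- if (is.null(deflation$fx_rate)) 1 else deflation$fx_rate
  for (col in c("outpatient_exp_1m", "inpatient_exp_12m", "selfmed_exp_1m")) {
    for (yr in unique(panel$wave_year)) {
      sel <- panel$wave_year == yr
      panel[[col]][sel] <- adjust_to_2015(panel[[col]][sel], yr, cpi, fx)
    }
  }
  panel
}

#' Derive analysis covariates from a raw panel
#'
#' Deterministic variable construction: five-level smoking status, age group
#' (45--54 / 55--64 / 65+), poverty (two or more of four deprivation
#' indicators), BMI class, drinker flag, and pass-through categorical
#' fields. Rows with age below 45, and rows with any missing covariate
#' field (complete-case analysis), are dropped; the counts of dropped rows
#' are attached as attribute `drop_log`.
#'
#' @param panel Raw person-wave panel (see [read_panel()]).
#' @return A `data.frame` of derived covariates, one row per retained
#'   person-wave, with attribute `drop_log`.
#' @export
derive_covariates <- function(panel) {
  validate_panel(panel)
  n0 <- nrow(panel)
  covar_cols <- setdiff(panel_columns(),
                        c("used_outpatient_1m", "outpatient_exp_1m",
                          "used_inpatient_12m", "inpatient_exp_12m",
                          "used_selfmed_1m", "selfmed_exp_1m"))
  cc <- stats::complete.cases(panel[, covar_cols])
  panel <- panel[cc, , drop = FALSE]
  n1 <- nrow(panel)
  keep <- panel$age >= 45
  panel <- panel[keep, , drop = FALSE]
  cov <- data.frame(
    person_id = panel$person_id,
    wave_year = panel$wave_year,
    smoking_status = classify_smoking_status(
      panel$ever_smoked_100, panel$currently_smokes, panel$cigs_per_day,
      panel$years_smoked, panel$years_since_quit),
    age_group = cut(panel$age, breaks = c(45, 55, 65, Inf), right = FALSE,
                    labels = c("45_54", "55_64", "65_plus")),
    sex = factor(panel$sex, levels = c("female", "male")),
    residency = factor(panel$residency, levels = c("rural", "urban")),
    education = factor(panel$education,
                       levels = c("primary_or_below", "middle_or_above")),
    marital = factor(panel$marital, levels = c("unpartnered", "partnered")),
    poverty = classify_poverty(panel$cooking_fuel_traditional,
                               panel$toilet_not_flushable,
                               panel$no_running_water, panel$asset_count),
    insurance = factor(panel$insurance, levels = c("no", "yes")),
    region = factor(panel$region, levels = c("west", "middle", "east")),
    bmi_class = classify_bmi(panel$weight_kg, panel$height_m),
    drinker = classify_drinker(panel$drink_freq_per_month),
    sampling_weight = panel$sampling_weight,
    stringsAsFactors = FALSE
  )
  attr(cov, "drop_log") <- list(incomplete_covariates = n0 - n1,
                                age_lt_45 = n1 - nrow(cov))
  cov
}
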