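#' National aggregation parameters
#'
#' Validates (and optionally reads from a YAML file) the parameters needed
#' to scale survey-level SAFs to national smoking-attributable medical
#' expenditures: average price and utilization per service (PV/QV outpatient
#' per month, PH/QH inpatient per year, PM/QM self-medication per month),
#' the 45+ population, the official all-age total health expenditure and the
#' 45+ share of it, and smoker counts for per-smoker figures.
#'
#' @param x Named list, or path to a YAML file whose keys mirror the field
#'   names (`PV`, `QV`, `PH`, `QH`, `PM`, `QM`, `POP`,
#'   `official_the_all_ages`, `share_45plus`, `n_smokers_45plus`, optional
#'   `n_smokers_by_service`).
#' @return List of class `national_params`.
#' @export
national_params <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  req <- c("POP", "official_the_all_ages", "share_45plus")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("national_params: missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (x$share_45plus < 0 || x$share_45plus > 1)
    stop("national_params: share_45plus must be in [0, 1]", call. = FALSE)
  num <- intersect(c("PV", "QV", "PH", "QH", "PM", "QM", "POP",
                     "official_the_all_ages", "n_smokers_45plus"), names(x))
  if (any(unlist(x[num]) < 0))
    stop("national_params: magnitudes must be non-negative", call. = FALSE)
  if (!is.null(x$QM) && (x$QM < 0 || x$QM > 1))
    stop("national_params: QM is a proportion in [0, 1]", call. = FALSE)
  structure(x, class = "national_params")
}

#' Survey estimates of the national price/utilization parameters
#'
#' Computes the per-service averages entering the national aggregation from
#' a (deflated) person-wave panel: PV = mean spend per outpatient use
#' occasion, QV = mean monthly outpatient use per person, PH = mean spend
#' per hospitalization, QH = mean annual hospitalization count, PM = mean
#' monthly self-medication spend among those with positive spend, QM =
#' share with positive monthly self-medication spend. Use flags stand in
#' for single visit counts, the granularity the record schema carries.
#'
#' @param panel Person-wave panel with expenditures in 2015 dollars.
#' @return Named list `PV`, `QV`, `PH`, `QH`, `PM`, `QM`.
#' @export
estimate_service_params <- function(panel) {
  validate_panel(panel)
  if (!any(panel$selfmed_exp_1m > 0))
    stop("estimate_service_params: no positive self-medication records",
         call. = FALSE)
  if (!any(panel$used_outpatient_1m) || !any(panel$used_inpatient_12m))
    stop("estimate_service_params: a service has no users", call. = FALSE)
  list(
    PV = mean(panel$outpatient_exp_1m[panel$used_outpatient_1m]),
    QV = mean(panel$used_outpatient_1m),
    PH = mean(panel$inpatient_exp_12m[panel$used_inpatient_12m]),
    QH = mean(panel$used_inpatient_12m),
    PM = mean(panel$selfmed_exp_1m[panel$selfmed_exp_1m > 0]),
    QM = mean(panel$selfmed_exp_1m > 0)
  )
}

#' National total health expenditure implied by survey averages
#'
#' The three service-level totals of the national aggregation identity:
#' outpatient `PV x QV x 12 x POP`, inpatient `PH x QH x POP`,
#' self-medication `PM x QM x 12 x POP`, each optionally scaled by a
#' calibration factor applied to the price terms.
#'
#' @param params A [national_params()] (must carry PV..QM and POP).
#' @param factor Calibration factor multiplying PV, PH, PM (default 1).
#' @return Named numeric vector (`outpatient`, `inpatient`, `selfmed`).
#' @export
national_the <- function(params, factor = 1) {
  for (f in c("PV", "QV", "PH", "QH", "PM", "QM"))
    if (is.null(params[[f]]))
      stop("national_the: params lacks ", f, call. = FALSE)
  c(outpatient = factor * params$PV * params$QV * 12 * params$POP,
    inpatient = factor * params$PH * params$QH * params$POP,
    selfmed = factor * params$PM * params$QM * 12 * params$POP)
}

#' Survey-to-official calibration factor
#'
#' Self-reported survey expenditures under- or over-state actual national
#' spending; the calibration factor rescales the survey-based price
#' parameters so the implied national total matches the official figure for
#' the 45+ population (official all-age total times the 45+ share). The
#' default direction divides official by survey, giving a factor above 1
#' when the survey understates spending; `direction = "survey_over_official"`
#' inverts it.
#'
#' @param survey_national_estimate National total implied by raw survey
#'   averages (sum of [national_the()] with factor 1).
#' @param official_the_all_ages Official all-age national health
#'   expenditure.
#' @param share_45plus Share of national spending by ages 45+.
#' @param direction `"official_over_survey"` (default) or
#'   `"survey_over_official"`.
#' @return Dimensionless calibration factor.
#' @export
calibration_factor <- function(survey_national_estimate,
                               official_the_all_ages, share_45plus,
                               direction = c("official_over_survey",
                                             "survey_over_official")) {
  direction <- match.arg(direction)
  if (survey_national_estimate <= 0)
    stop("calibration_factor: survey estimate must be positive",
         call. = FALSE)
  if (official_the_all_ages <= 0 || share_45plus <= 0)
    stop("calibration_factor: official figure and share must be positive",
         call. = FALSE)
  official_45plus <- official_the_all_ages * share_45plus
  if (direction == "official_over_survey")
    official_45plus / survey_national_estimate
  else
    survey_national_estimate / official_45plus
}

#' National smoking-attributable medical expenditures
#'
#' Applies the aggregation identity `SAME = sum(THE x SAF)` per service:
#' calibrated national total expenditure per service times that service's
#' SAF, plus an overall row summing the three services (whose implied SAF
#' is the THE-weighted average).
#'
#' @param saf SAF table from [compute_saf()] (or any `data.frame` with
#'   `service`, `stratum`, `saf` rows for the three services).
#' @param params A [national_params()] carrying PV..QM and POP.
#' @param factor Calibration factor from [calibration_factor()] (default 1).
#' @param stratum Which stratum of `saf` to aggregate (default `"all"`).
#' @return `data.frame` with `service`, `stratum`, `the_estimate`, `saf`,
#'   `same`, `per_smoker` (NA unless smoker counts are in `params`), and
#'   `calibration_factor`.
#' @export
compute_same <- function(saf, params, factor = 1, stratum = "all") {
  services <- c("outpatient", "inpatient", "selfmed")
  rows <- saf[saf$stratum == stratum & saf$service %in% services, ]
  if (!setequal(rows$service, services))
    stop("compute_same: saf table lacks a service row for stratum '",
         stratum, "'", call. = FALSE)
  the <- national_the(params, factor)
  saf_v <- stats::setNames(rows$saf, rows$service)[services]
  same_v <- the[services] * saf_v

  n_by_svc <- params$n_smokers_by_service
  per_smoker <- vapply(services, function(s) {
    n <- if (!is.null(n_by_svc) && !is.null(n_by_svc[[s]])) n_by_svc[[s]]
         else params$n_smokers_45plus
    if (is.null(n)) NA_real_ else per_smoker_same(same_v[[s]], n)
  }, numeric(1))
  per_smoker_all <- if (is.null(params$n_smokers_45plus)) NA_real_
                    else per_smoker_same(sum(same_v), params$n_smokers_45plus)

  data.frame(
    service = c(services, "overall"), stratum = stratum,
    the_estimate = c(unname(the[services]), sum(the[services])),
    saf = c(unname(saf_v), sum(same_v) / sum(the[services])),
    same = c(unname(same_v), sum(same_v)),
    per_smoker = c(unname(per_smoker), per_smoker_all),
    calibration_factor = factor, stringsAsFactors = FALSE)
}

#' Smoking-attributable expenditure per smoker
#'
#' @param same_total Smoking-attributable expenditure total.
#' @param n_smokers Number of smokers in the corresponding population
#'   (service-specific denominators may be used per service).
#' @return `same_total / n_smokers`.
#' @export
per_smoker_same <- function(same_total, n_smokers) {
  if (any(n_smokers <= 0))
    stop("per_smoker_same: n_smokers must be positive", call. = FALSE)
  same_total / n_smokers
}
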