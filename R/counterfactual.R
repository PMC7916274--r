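#' Combine the two fitted equations into expected per-person-wave costs
#'
#' The two-part prediction: probability of any use from the random-effects
#' logit, times the expected expenditure given use from the log-cost
#' regression, back-transformed to the currency scale.
#'
#' The use probability is either averaged over the estimated random-intercept
#' distribution `N(0, sigma_alpha^2)` by Gauss-Hermite quadrature
#' (`integration = "population_average"`, the default) or evaluated at
#' `alpha = 0` (`"zero_intercept"`). The log-scale prediction is
#' retransformed with Duan's smearing factor (mean of exponentiated
#' composite residuals, distribution-robust; the default) or the lognormal
#' normal-theory factor `exp((sigma_alpha^2 + sigma_u^2)/2)`.
#'
#' @param use_fit Converged `refit` from [fit_re_logit()].
#' @param cost_fit Converged `refit` from [fit_re_gls()].
#' @param design Design `data.frame` with the same predictor columns the
#'   fits were estimated on.
#' @param retransform `"smearing"` or `"normal_theory"`.
#' @param integration `"population_average"` or `"zero_intercept"`.
#' @param scenario Label stored in the output (`"factual"` or
#'   `"hypothetical"`).
#' @param nodes Quadrature nodes for the population-average integral.
#' @return `data.frame` with `person_id`, `wave_year`, `p_use`,
#'   `cond_cost`, `expected_cost` (`= p_use * cond_cost`), `scenario`.
#' @export
predict_two_part <- function(use_fit, cost_fit, design,
                             retransform = c("smearing", "normal_theory"),
                             integration = c("population_average",
                                             "zero_intercept"),
                             scenario = "factual", nodes = 40) {
  retransform <- match.arg(retransform)
  integration <- match.arg(integration)
  stopifnot(inherits(use_fit, "refit"), inherits(cost_fit, "refit"))
  if (!isTRUE(use_fit$converged) || !isTRUE(cost_fit$converged))
    stop("predict_two_part: both fits must have converged", call. = FALSE)
  cols <- setdiff(names(use_fit$coefficients), "(Intercept)")
  if (!identical(cols, setdiff(names(cost_fit$coefficients), "(Intercept)")))
    stop("predict_two_part: use and cost fits have different designs",
         call. = FALSE)
  if (length(setdiff(cols, names(design))))
    stop("predict_two_part: design does not match the fitted design",
         call. = FALSE)
  X <- design_matrix(design, cols)

  eta_u <- drop(X %*% use_fit$coefficients)
  p_use <- if (integration == "population_average")
    gh_mean_plogis(eta_u, use_fit$sigma_alpha, nodes)
  else
    stats::plogis(eta_u)

  R <- if (retransform == "smearing") {
    if (is.null(cost_fit$residuals))
      stop("predict_two_part: cost fit carries no residuals for smearing",
           call. = FALSE)
    mean(exp(cost_fit$residuals))
  } else {
    exp((cost_fit$sigma_alpha^2 + cost_fit$sigma_u^2) / 2)
  }
  cond_cost <- exp(drop(X %*% cost_fit$coefficients)) * R

  data.frame(person_id = design$person_id, wave_year = design$wave_year,
             p_use = p_use, cond_cost = cond_cost,
             expected_cost = p_use * cond_cost,
             scenario = scenario, stringsAsFactors = FALSE)
}

#' Never-smoker counterfactual design
#'
#' Returns the design with all four smoking-level dummies and all eight
#' smoking-by-age interaction columns set to zero, i.e. every person-wave
#' replayed as a never smoker. Rows of actual never smokers are unchanged;
#' the operation is idempotent.
#'
#' @param design Design `data.frame` from [build_design()].
#' @return Design `data.frame` of the same shape.
#' @export
make_counterfactual <- function(design) {
  for (col in smoking_design_columns()) {
    if (!col %in% names(design))
      stop("make_counterfactual: design lacks column ", col, call. = FALSE)
    design[[col]] <- 0
  }
  design
}

#' Smoking-attributable fraction from factual and counterfactual predictions
#'
#' Sums expected costs within stratum and service under the factual and the
#' never-smoker scenarios; the SAF is the difference over the factual
#' total. An `overall` service row pools the services after annualizing
#' each recall window; an `all` stratum row covers the full sample.
#'
#' @param factual,hypothetical Row-aligned prediction tables; either a
#'   single [predict_two_part()] result carrying a `service` column, or a
#'   named list of per-service prediction tables.
#' @param strata Optional `data.frame` of grouping columns (e.g. sex,
#'   residency), one row per person-wave of each service table.
#' @return `data.frame` with `service`, `stratum`, `factual_total`,
#'   `hypothetical_total`, `saf`.
#' @export
compute_saf <- function(factual, hypothetical, strata = NULL) {
  as_service_list <- function(x) {
    if (is.data.frame(x)) {
      if (!"service" %in% names(x))
        stop("compute_saf: single-table input needs a 'service' column",
             call. = FALSE)
      split(x, x$service)
    } else x
  }
  fl <- as_service_list(factual)
  hl <- as_service_list(hypothetical)
  if (!setequal(names(fl), names(hl)))
    stop("compute_saf: factual and hypothetical services differ",
         call. = FALSE)
  ann <- service_annualization()

  strat_labels <- function(tab) {
    labs <- list(all = rep(TRUE, nrow(tab)))
    if (!is.null(strata)) {
      if (nrow(strata) != nrow(tab))
        stop("compute_saf: strata rows must align with prediction rows",
             call. = FALSE)
      for (v in names(strata)) {
        for (lev in unique(as.character(strata[[v]])))
          labs[[paste0(v, "=", lev)]] <- as.character(strata[[v]]) == lev
      }
    }
    labs
  }

  out <- list()
  overall_f <- overall_h <- list()
  for (s in names(fl)) {
    f <- fl[[s]]; h <- hl[[s]]
    if (nrow(f) != nrow(h) ||
        !identical(f$person_id, h$person_id) ||
        !identical(f$wave_year, h$wave_year))
      stop("compute_saf: factual and hypothetical tables are not row-aligned",
           call. = FALSE)
    labs <- strat_labels(f)
    for (lab in names(labs)) {
      sel <- labs[[lab]]
      ft <- sum(f$expected_cost[sel])
      ht <- sum(h$expected_cost[sel])
      if (ft == 0)
        stop("compute_saf: factual total is zero for ", s, " / ", lab,
             " (SAF undefined)", call. = FALSE)
      out[[length(out) + 1]] <- data.frame(
        service = s, stratum = lab, factual_total = ft,
        hypothetical_total = ht, saf = (ft - ht) / ft,
        stringsAsFactors = FALSE)
      a <- unname(ann[s])
      overall_f[[lab]] <- (overall_f[[lab]] %||% 0) + a * ft
      overall_h[[lab]] <- (overall_h[[lab]] %||% 0) + a * ht
    }
  }
  for (lab in names(overall_f)) {
    ft <- overall_f[[lab]]; ht <- overall_h[[lab]]
    out[[length(out) + 1]] <- data.frame(
      service = "overall", stratum = lab, factual_total = ft,
      hypothetical_total = ht, saf = (ft - ht) / ft,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
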