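#' Weighted descriptive statistics by wave
#'
#' Sampling-weighted proportion (percent) of each level of every derived
#' categorical covariate, separately per wave.
#'
#' @param panel Raw person-wave panel with positive `sampling_weight`.
#' @return Long `data.frame`: `wave_year`, `variable`, `level`, `pct`.
#' @export
weighted_descriptives <- function(panel) {
  if (any(panel$sampling_weight <= 0) || any(!is.finite(panel$sampling_weight)))
    stop("weighted_descriptives: sampling weights must be positive",
         call. = FALSE)
  cov <- derive_covariates(panel)
  vars <- c("smoking_status", "age_group", "sex", "residency", "education",
            "marital", "poverty", "insurance", "region", "bmi_class",
            "drinker")
  out <- list()
  for (v in vars) {
    lev <- as.character(cov[[v]])
    agg <- stats::aggregate(cov$sampling_weight,
                            by = list(wave_year = cov$wave_year, level = lev),
                            FUN = sum)
    tot <- stats::aggregate(cov$sampling_weight,
                            by = list(wave_year = cov$wave_year), FUN = sum)
    agg$pct <- 100 * agg$x / tot$x[match(agg$wave_year, tot$wave_year)]
    out[[v]] <- data.frame(wave_year = agg$wave_year, variable = v,
                           level = agg$level, pct = agg$pct,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$variable, res$wave_year, res$level), ]
  rownames(res) <- NULL
  res
}

#' Fit the two-part model for one service
#'
#' Fits the use equation (random-effects logit on any use) on all
#' person-waves and the cost equation (random-effects GLS on log
#' expenditure) on the person-waves with positive spending.
#'
#' @param panel Raw panel restricted to analysis rows (age 45+), row-aligned
#'   with `design`.
#' @param design Design `data.frame` from [build_design()].
#' @param service `"outpatient"`, `"inpatient"`, or `"selfmed"`.
#' @param quadrature_nodes Adaptive quadrature points for the logit.
#' @return List with `use` and `cost` `refit` objects and `n_users`.
#' @export
fit_two_part <- function(panel, design, service, quadrature_nodes = 15) {
  sc <- service_columns(service)
  y <- panel[[sc$use]]
  exp <- panel[[sc$exp]]
  ok <- !is.na(y)                      # complete-case per service equation
  pos <- !is.na(exp) & exp > 0
  list(service = service,
       use = fit_re_logit(design[ok, , drop = FALSE], y[ok],
                          quadrature_nodes = quadrature_nodes),
       cost = fit_re_gls(design[pos, , drop = FALSE], exp[pos]),
       n_users = sum(pos),
       n_missing = sum(!ok) + sum(is.na(exp) & !is.na(y)))
}

#' Run the full estimation pipeline
#'
#' Simulates (or reads) a panel, derives covariates and the design matrix,
#' fits the six models (use and cost per service), predicts factual and
#' never-smoker counterfactual expected costs, computes SAF overall and by
#' strata, calibrates survey averages to the official national total, and
#' aggregates to national SAME. Optionally writes all tables plus a
#' machine-readable run manifest to a directory.
#'
#' @param config Named list with elements:
#'   \describe{
#'     \item{input}{a [sim_config()] or a CSV path for [read_panel()].}
#'     \item{deflation}{optional list (`cpi_medical`, `fx_rate`) applied to
#'       expenditure columns.}
#'     \item{quadrature_nodes}{logit quadrature points (default 15).}
#'     \item{retransform}{`"smearing"` (default) or `"normal_theory"`.}
#'     \item{integration}{`"population_average"` (default) or
#'       `"zero_intercept"`.}
#'     \item{strata}{character vector of covariate columns for subgroup SAF
#'       (default `c("sex", "residency")`).}
#'     \item{national}{path to a national-parameters YAML, or a list, or
#'       `NULL` to skip the SAME stage.}
#'     \item{out_dir}{optional output directory.}
#'   }
#' @return (Invisibly) a list with `panel`, `truth` (if simulated), `fits`,
#'   `saf`, `same`, `descriptives`, `service_params`,
#'   `calibration_factor`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(
    list(quadrature_nodes = 15, retransform = "smearing",
         integration = "population_average", strata = c("sex", "residency"),
         national = NULL, deflation = NULL, out_dir = NULL),
    config)
  truth <- NULL
  if (inherits(cfg$input, "sim_config")) {
    sim <- simulate_panel(cfg$input)
    panel <- sim$panel
    truth <- sim$truth
  } else {
    panel <- read_panel(cfg$input)
  }
  if (!is.null(cfg$deflation)) panel <- deflate_panel(panel, cfg$deflation)

  cov <- derive_covariates(panel)
  key <- function(df) paste(df$person_id, df$wave_year)
  panel_a <- panel[key(panel) %in% key(cov), , drop = FALSE]
  design <- build_design(cov)
  drop_log <- attr(cov, "drop_log")

  services <- c("outpatient", "inpatient", "selfmed")
  fits <- lapply(services, function(s)
    fit_two_part(panel_a, design, s, cfg$quadrature_nodes))
  names(fits) <- services

  cf_design <- make_counterfactual(design)
  factual <- lapply(fits, function(f)
    predict_two_part(f$use, f$cost, design, retransform = cfg$retransform,
                     integration = cfg$integration, scenario = "factual"))
  hypothetical <- lapply(fits, function(f)
    predict_two_part(f$use, f$cost, cf_design, retransform = cfg$retransform,
                     integration = cfg$integration, scenario = "hypothetical"))
  strata_df <- if (length(cfg$strata))
    cov[, cfg$strata, drop = FALSE] else NULL
  saf <- compute_saf(factual, hypothetical, strata = strata_df)

  same <- NULL; cal <- NULL; svc_params <- NULL
  if (!is.null(cfg$national)) {
    np <- if (inherits(cfg$national, "national_params")) cfg$national
          else national_params(cfg$national)
    svc_params <- estimate_service_params(panel_a)
    for (f in names(svc_params))
      if (is.null(np[[f]])) np[[f]] <- svc_params[[f]]
    survey_est <- sum(national_the(np, factor = 1))
    cal <- calibration_factor(survey_est, np$official_the_all_ages,
                              np$share_45plus)
    same <- compute_same(saf, np, factor = cal, stratum = "all")
  }

  descriptives <- weighted_descriptives(panel)
  manifest <- list(
    package = "samecost",
    package_version = as.character(utils::packageVersion("samecost")),
    r_version = as.character(getRversion()),
    seed = if (!is.null(truth)) truth$seed else NA,
    config = serialize_config(cfg),
    drop_log = drop_log,
    n_obs = nrow(panel_a),
    n_individuals = length(unique(panel_a$person_id)),
    n_users = lapply(fits, `[[`, "n_users"),
    n_missing_outcomes = lapply(fits, `[[`, "n_missing"),
    converged = lapply(fits, function(f)
      list(use = f$use$converged, cost = f$cost$converged)),
    calibration_factor = cal)

  res <- list(panel = panel, truth = truth, fits = fits, saf = saf,
              same = same, descriptives = descriptives,
              service_params = svc_params, calibration_factor = cal,
              manifest = manifest)
  if (!is.null(cfg$out_dir)) write_run_artifacts(res, design, cfg$out_dir)
  invisible(res)
}

serialize_config <- function(cfg) {
  out <- cfg
  if (inherits(out$input, "sim_config")) out$input <- unclass(out$input)
  if (inherits(out$national, "national_params"))
    out$national <- unclass(out$national)
  out$out_dir <- NULL
  out
}

write_run_artifacts <- function(res, design, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$panel, file.path(out_dir, "panel.csv"),
                   row.names = FALSE)
  utils::write.csv(design, file.path(out_dir, "design.csv"),
                   row.names = FALSE)
  for (s in names(res$fits)) {
    jsonlite::write_json(
      list(use = refit_to_list(res$fits[[s]]$use),
           cost = refit_to_list(res$fits[[s]]$cost)),
      file.path(out_dir, paste0("fit_", s, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(res$saf, file.path(out_dir, "saf.csv"), row.names = FALSE)
  if (!is.null(res$same))
    utils::write.csv(res$same, file.path(out_dir, "same.csv"),
                     row.names = FALSE)
  utils::write.csv(res$descriptives, file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
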