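#' Service types and their recall windows
#'
#' The three health-care service categories and the recall window (months)
#' over which use and spending are reported: outpatient visits (1 month),
#' inpatient hospitalizations (12 months), self-medication (1 month).
#'
#' @return Named numeric vector of recall windows in months.
#' @export
service_recall_months <- function() {
  c(outpatient = 1, inpatient = 12, selfmed = 1)
}

# Factor converting a recall-window total to an annual total.
service_annualization <- function() 12 / service_recall_months()

service_columns <- function(service) {
  switch(service,
    outpatient = list(use = "used_outpatient_1m", exp = "outpatient_exp_1m"),
    inpatient = list(use = "used_inpatient_12m", exp = "inpatient_exp_12m"),
    selfmed = list(use = "used_selfmed_1m", exp = "selfmed_exp_1m"),
    stop("unknown service: ", service, call. = FALSE))
}

#' Default covariate prevalences for the synthetic panel
#'
#' Baseline-wave marginal distributions of the generator, chosen to mirror a
#' weighted national panel of adults aged 45+: majority female, rural,
#' low-education, partnered, insured; roughly 28% current smokers and 7%
#' former smokers at baseline.
#'
#' @return Named list of category probabilities.
#' @export
default_prevalences <- function() {
  list(
    male = 0.4456, rural = 0.5752, edu_middle_plus = 0.3488,
    partnered = 0.8930, poverty = 0.2235, insured = 0.9420,
    region = c(west = 0.2955, middle = 0.2786, east = 0.4259),
    bmi = c(normal = 0.4940, underweight = 0.0611, overweight = 0.4449),
    drinker = 0.2434,
    age_group = c(a45_54 = 0.3934, a55_64 = 0.3750, a65_plus = 0.2315),
    smoking = c(never = 0.6440, current_light = 0.0410,
                current_heavy = 0.2437, former_quit_lt5 = 0.0294,
                former_quit_ge5 = 0.0390)
  )
}

#' Default generating parameters of the two-part model
#'
#' Per-service coefficient vectors for the use (logit, `gamma`) and log-cost
#' (`beta`) equations, on the canonical design layout of
#' [design_columns()] with an `(Intercept)` entry first. The logit
#' coefficients are logs of adjusted odds ratios of realistic magnitude
#' (e.g. aOR 1.421 for recent quitters on outpatient use, and 0.886 on log
#' outpatient cost). Variance components: SD of the use-equation random
#' intercept (`sigma_alpha_logit`), SD of the cost-equation random
#' intercept (`sigma_alpha_cost`), and residual SD of log cost
#' (`sigma_u_cost`).
#'
#' @return Named list with one element per service.
#' @export
default_true_params <- function() {
  nm <- c("(Intercept)", design_columns())
  mk <- function(v) stats::setNames(v, nm)
  aor <- function(const, v) mk(log(c(const, v)))
  params <- list(
    outpatient = list(
      gamma = aor(0.433, c(0.907, 0.740, 1.421, 1.574, 0.742, 0.998, 1.106,
                           1.015, 0.883, 0.984, 1.035, 1.322, 0.672, 0.480,
                           1.125, 0.979, 0.876,
                           1.053, 1.024, 1.200, 1.206, 1.043, 0.83, 0.798,
                           1.093)),
      beta = mk(c(5.072, -0.0298, 0.103, 0.886, 0.137, -0.0903, 0.159, 0.352,
                  0.148, 0.222, 0.154, -0.0394, -0.0147, -0.118, 0.0495,
                  0.172, 0.122, -0.305,
                  0.335, -0.0807, -0.173, -0.148, -0.190, -0.405, 0.217,
                  0.190))),
    inpatient = list(
      gamma = aor(0.0738, c(1.082, 0.875, 1.728, 1.138, 0.975, 1.395, 1.940,
                            1.122, 0.963, 0.883, 1.000, 1.595, 0.712, 0.530,
                            1.217, 1.202, 0.649,
                            1.194, 0.991, 0.898, 1.019, 1.348, 1.381, 1.452,
                            1.728)),
      beta = mk(c(7.887, -0.0593, 0.0579, 0.445, 0.518, 0.157, 0.0952, 0.0862,
                  0.283, 0.146, 0.143, -0.127, 0.0573, 0.0241, 0.360, 0.0970,
                  0.133, -0.156,
                  0.0171, -0.126, -0.178, -0.0289, 0.0139, 0.0948, -0.543,
                  -0.223))),
    selfmed = list(
      gamma = aor(0.624, c(1.028, 1.097, 1.287, 1.582, 0.801, 1.255, 1.238,
                           1.160, 1.099, 1.075, 1.140, 1.408, 0.598, 0.595,
                           0.903, 1.305, 0.953,
                           1.058, 1.055, 0.973, 1.105, 0.989, 0.835, 0.945,
                           1.039)),
      beta = mk(c(4.057, -0.0250, -0.181, 0.206, 0.0456, -0.0818, 0.156,
                  0.270, 0.135, 0.125, 0.117, 0.0162, 0.0464, -0.225, -0.274,
                  0.0881, 0.0771, -0.243,
                  -0.0320, -0.130, 0.0992, 0.136, 0.102, 0.113, 0.162,
                  0.322))))
  for (s in names(params)) {
    params[[s]]$sigma_alpha_logit <- 1.0
    params[[s]]$sigma_alpha_cost <- 0.8
    params[[s]]$sigma_u_cost <- 1.3
  }
  params
}

#' Build a simulation configuration
#'
#' @param n_individuals Number of individuals in the balanced panel.
#' @param wave_years Calendar years of the waves.
#' @param prevalences Baseline covariate prevalences
#'   (see [default_prevalences()]).
#' @param true_params Generating two-part parameters per service
#'   (see [default_true_params()]).
#' @param quit_prob Per-wave probability that a current smoker quits.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @param emit_nominal If `TRUE`, expenditures are written in nominal
#'   wave-year prices (inflated with `cpi_medical`) so that deflation with
#'   [deflate_panel()] is required to recover 2015 dollars. Default
#'   `FALSE`: costs are generated directly in 2015 dollars.
#' @param cpi_medical Named year -> medical CPI map used when
#'   `emit_nominal = TRUE`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 2000,
                       wave_years = c(2011, 2013, 2015),
                       prevalences = default_prevalences(),
                       true_params = default_true_params(),
                       quit_prob = 0.06,
                       seed = 1L,
                       emit_nominal = FALSE,
                       cpi_medical = c("2011" = 0.90, "2013" = 0.95,
                                       "2015" = 1.00)) {
  stopifnot(n_individuals >= 1, length(wave_years) >= 1)
  probs <- unlist(prevalences[c("male", "rural", "edu_middle_plus",
                                "partnered", "poverty", "insured",
                                "drinker")])
  if (any(probs < 0 | probs > 1))
    stop("sim_config: prevalences must be probabilities in [0, 1]",
         call. = FALSE)
  for (blk in c("region", "bmi", "age_group", "smoking")) {
    p <- prevalences[[blk]]
    if (any(p < 0) || abs(sum(p) - 1) > 0.02)
      stop("sim_config: prevalence block '", blk, "' must sum to 1",
           call. = FALSE)
    prevalences[[blk]] <- p / sum(p)  # absorb printed-rounding slack
  }
  for (s in names(true_params)) {
    sd3 <- unlist(true_params[[s]][c("sigma_alpha_logit", "sigma_alpha_cost",
                                     "sigma_u_cost")])
    if (any(sd3 < 0))
      stop("sim_config: variance-component SDs must be >= 0", call. = FALSE)
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 wave_years = wave_years, prevalences = prevalences,
                 true_params = true_params, quit_prob = quit_prob,
                 seed = as.integer(seed), emit_nominal = emit_nominal,
                 cpi_medical = cpi_medical),
            class = "sim_config")
}

# Draw one categorical level per row from a named probability vector.
draw_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Simulate a balanced person-wave panel with known ground truth
#'
#' Generates a balanced multi-wave panel with the statistical structure the
#' analysis assumes: time-invariant sociodemographics, smoking status that
#' evolves across waves (current smokers may quit; quitters age into the
#' 5+-year class; light smokers whose cumulative index crosses 200 become
#' heavy), one normal random intercept per person per equation per service,
#' and two-part outcomes (Bernoulli use, conditional lognormal cost) for
#' the three services. Raw record fields (weight/height, deprivation
#' indicators, drinking frequency, smoking history) are emitted so the
#' measurement layer's coding can be exercised end to end.
#'
#' @param config A [sim_config()].
#' @return List with elements `panel` (raw person-wave `data.frame`) and
#'   `truth` (a `truth_bundle`: the config, realized random intercepts, the
#'   realized design rows, and the analytic true SAF per service).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  n <- config$n_individuals
  pv <- config$prevalences
  waves <- sort(config$wave_years)
  W <- length(waves)

  person_id <- sprintf("P%05d", seq_len(n))
  sex <- ifelse(stats::runif(n) < pv$male, "male", "female")
  residency <- ifelse(stats::runif(n) < pv$rural, "rural", "urban")
  education <- ifelse(stats::runif(n) < pv$edu_middle_plus,
                      "middle_or_above", "primary_or_below")
  marital <- ifelse(stats::runif(n) < pv$partnered, "partnered",
                    "unpartnered")
  insurance <- ifelse(stats::runif(n) < pv$insured, "yes", "no")
  region <- draw_cat(n, pv$region)
  bmi_class <- draw_cat(n, pv$bmi)
  drinker <- stats::runif(n) < pv$drinker
  poverty <- stats::runif(n) < pv$poverty
  age_grp <- draw_cat(n, pv$age_group)
  age0 <- stats::runif(n,
                       min = c(a45_54 = 45, a55_64 = 55, a65_plus = 65)[age_grp],
                       max = c(a45_54 = 55, a55_64 = 65, a65_plus = 80)[age_grp])

  # raw-field backfill consistent with the drawn classes
  height_m <- round(stats::rnorm(n, 1.60, 0.06), 2)
  bmi_val <- ifelse(bmi_class == "normal", stats::runif(n, 18.6, 23.8),
             ifelse(bmi_class == "underweight", stats::runif(n, 15.0, 18.2),
                    stats::runif(n, 24.2, 32.0)))
  weight_kg <- round(bmi_val * height_m^2, 1)
  drink_freq <- ifelse(drinker, stats::runif(n, 2, 30),
                       sample(c(0, 1), n, replace = TRUE))
  fuel <- toilet <- water <- rep(FALSE, n)
  asset_count <- integer(n)
  pov_t <- which(poverty)
  fuel[pov_t] <- TRUE
  toilet[pov_t] <- TRUE
  water[pov_t] <- stats::runif(length(pov_t)) < 0.4
  asset_count[pov_t] <- sample(0:6, length(pov_t), replace = TRUE)
  pov_f <- which(!poverty)
  kind <- sample(c("none", "one", "asset"), length(pov_f), replace = TRUE,
                 prob = c(0.6, 0.25, 0.15))
  asset_count[pov_f] <- sample(2:8, length(pov_f), replace = TRUE)
  one_sel <- pov_f[kind == "one"]
  pick <- sample(1:3, length(one_sel), replace = TRUE)
  fuel[one_sel[pick == 1]] <- TRUE
  toilet[one_sel[pick == 2]] <- TRUE
  water[one_sel[pick == 3]] <- TRUE
  asset_count[pov_f[kind == "asset"]] <- sample(0:1,
                                                sum(kind == "asset"),
                                                replace = TRUE)

  # baseline smoking state
  status <- draw_cat(n, pv$smoking)
  cigs <- years <- quit_yrs <- numeric(n)
  li <- status == "current_light"
  cigs[li] <- stats::runif(sum(li), 1, 10)
  years[li] <- stats::runif(sum(li), 20, 199) / cigs[li]
  he <- status == "current_heavy"
  cigs[he] <- stats::runif(sum(he), 10, 40)
  years[he] <- stats::runif(sum(he), 200, 900) / cigs[he]
  fo <- status %in% c("former_quit_lt5", "former_quit_ge5")
  cigs[fo] <- stats::runif(sum(fo), 5, 30)
  years[fo] <- stats::runif(sum(fo), 5, 35)
  quit_yrs[status == "former_quit_lt5"] <-
    stats::runif(sum(status == "former_quit_lt5"), 0, 5)
  quit_yrs[status == "former_quit_ge5"] <-
    stats::runif(sum(status == "former_quit_ge5"), 5, 25)

  sampling_weight <- stats::rlnorm(n, 0, 0.3)

  # one random intercept per person per equation per service
  services <- names(config$true_params)
  alpha <- data.frame(person_id = person_id)
  for (s in services) {
    tp <- config$true_params[[s]]
    alpha[[paste0("alpha_use_", s)]] <-
      stats::rnorm(n, 0, tp$sigma_alpha_logit)
    alpha[[paste0("alpha_cost_", s)]] <-
      stats::rnorm(n, 0, tp$sigma_alpha_cost)
  }

  rows <- vector("list", W)
  step <- if (W > 1) diff(waves)[1] else 2
  for (w in seq_len(W)) {
    if (w > 1) {
      cur <- status %in% c("current_light", "current_heavy")
      quits <- cur & stats::runif(n) < config$quit_prob
      years[cur & !quits] <- years[cur & !quits] + step
      quit_yrs[quits] <- stats::runif(sum(quits), 0, step)
      status[quits] <- "former_quit_lt5"
      former <- status %in% c("former_quit_lt5", "former_quit_ge5")
      quit_yrs[former & !quits] <- quit_yrs[former & !quits] + step
      idx <- cigs * years
      status[status == "current_light" & idx >= 200] <- "current_heavy"
      status[former] <- ifelse(quit_yrs[former] < 5, "former_quit_lt5",
                               "former_quit_ge5")
      age0 <- age0 + step
    }
    rows[[w]] <- data.frame(
      person_id = person_id, wave_year = waves[w], sex = sex, age = age0,
      residency = residency, education = education, marital = marital,
      insurance = insurance, region = region,
      cooking_fuel_traditional = fuel, toilet_not_flushable = toilet,
      no_running_water = water, asset_count = asset_count,
      weight_kg = weight_kg, height_m = height_m,
      drink_freq_per_month = drink_freq,
      ever_smoked_100 = status != "never",
      currently_smokes = status %in% c("current_light", "current_heavy"),
      cigs_per_day = cigs, years_smoked = years,
      years_since_quit = quit_yrs,
      sampling_weight = sampling_weight,
      stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, rows)

  cov <- data.frame(
    person_id = panel$person_id, wave_year = panel$wave_year,
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
    poverty = poverty, insurance = factor(panel$insurance,
                                          levels = c("no", "yes")),
    region = factor(panel$region, levels = c("west", "middle", "east")),
    bmi_class = factor(bmi_class,
                       levels = c("normal", "underweight", "overweight")),
    drinker = drinker, stringsAsFactors = FALSE)
  design <- build_design(cov)
  X <- design_matrix(design)
  ord <- match(panel$person_id, alpha$person_id)

  for (s in services) {
    tp <- config$true_params[[s]]
    sc <- service_columns(s)
    eta_u <- drop(X %*% tp$gamma) + alpha[[paste0("alpha_use_", s)]][ord]
    use <- stats::runif(nrow(panel)) < stats::plogis(eta_u)
    eta_c <- drop(X %*% tp$beta) + alpha[[paste0("alpha_cost_", s)]][ord]
    cost <- ifelse(use,
                   exp(eta_c + stats::rnorm(nrow(panel), 0, tp$sigma_u_cost)),
                   0)
    panel[[sc$use]] <- use
    panel[[sc$exp]] <- cost
  }

  if (isTRUE(config$emit_nominal)) {
    cpi <- config$cpi_medical
    for (s in services) {
      sc <- service_columns(s)
      infl <- unname(cpi[as.character(panel$wave_year)] / cpi[["2015"]])
      panel[[sc$exp]] <- panel[[sc$exp]] * infl
    }
  }

  panel <- panel[, panel_columns()]
  truth <- structure(list(config = config, intercepts = alpha,
                          design = design, seed = config$seed),
                     class = "truth_bundle")
  truth$true_saf <- true_saf(truth)
  list(panel = panel, truth = truth)
}

# Gauss-Hermite rule rescaled for expectations over N(0, 1).
gh_normal <- function(nodes) {
  gh <- pracma::gaussHermite(nodes)
  list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

# E[plogis(eta + sigma * Z)], Z ~ N(0,1), per element of eta.
gh_mean_plogis <- function(eta, sigma, nodes = 40) {
  if (sigma == 0) return(stats::plogis(eta))
  gh <- gh_normal(nodes)
  p <- numeric(length(eta))
  for (j in seq_along(gh$z))
    p <- p + gh$w[j] * stats::plogis(eta + sigma * gh$z[j])
  p
}

# Population expected cost per row for one service under given parameters.
analytic_expected_cost <- function(X, tp, nodes = 40) {
  p <- gh_mean_plogis(drop(X %*% tp$gamma), tp$sigma_alpha_logit, nodes)
  m <- exp(drop(X %*% tp$beta) +
             (tp$sigma_alpha_cost^2 + tp$sigma_u_cost^2) / 2)
  p * m
}

#' True smoking-attributable fraction of a simulated population
#'
#' Analytic replay of the generating model: for every realized person-wave
#' design row, the expected cost (use probability integrated over the
#' random-intercept distribution, times the lognormal conditional mean) is
#' computed under the factual design and under the never-smoker
#' counterfactual (all smoking and smoking-by-age columns zeroed); the SAF
#' is one minus the ratio of counterfactual to factual totals. The
#' `overall` entry pools the three services after annualizing each
#' service's recall window.
#'
#' @param truth A `truth_bundle` from [simulate_panel()].
#' @param nodes Gauss-Hermite nodes for the use-probability integral.
#' @return Named numeric vector of SAFs (per service plus `overall`).
#' @export
true_saf <- function(truth, nodes = 60) {
  stopifnot(inherits(truth, "truth_bundle"))
  X <- design_matrix(truth$design)
  Xh <- X
  Xh[, smoking_design_columns()] <- 0
  ann <- service_annualization()
  services <- names(truth$config$true_params)
  fact_tot <- hyp_tot <- stats::setNames(numeric(length(services)), services)
  for (s in services) {
    tp <- truth$config$true_params[[s]]
    fact_tot[s] <- sum(analytic_expected_cost(X, tp, nodes))
    hyp_tot[s] <- sum(analytic_expected_cost(Xh, tp, nodes))
  }
  saf <- 1 - hyp_tot / fact_tot
  overall <- 1 - sum(ann[services] * hyp_tot) / sum(ann[services] * fact_tot)
  c(saf, overall = unname(overall))
}
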