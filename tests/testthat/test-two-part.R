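null_fits <- function() {
  nm <- c("(Intercept)", design_columns())
  co <- stats::setNames(rep(0, length(nm)), nm)
  list(use = manual_refit("re_logit", co, sigma_alpha = 0),
       cost = manual_refit("re_gls", co, sigma_alpha = 0, sigma_u = 0,
                           residuals = rep(0, 5)))
}

test_that("null model predicts p = 0.5 and unit conditional cost", {
  f <- null_fits()
  d <- rbind(one_row_design(), one_row_design("smk_current_heavy"))
  pred <- predict_two_part(f$use, f$cost, d)
  expect_equal(pred$p_use, c(0.5, 0.5))
  expect_equal(pred$cond_cost, c(1, 1))
  expect_equal(pred$expected_cost, c(0.5, 0.5))
  expect_equal(pred$expected_cost, pred$p_use * pred$cond_cost)
})

test_that("zero-intercept normal-theory prediction has a closed form", {
  nm <- c("(Intercept)", design_columns())
  g <- stats::setNames(rep(0, length(nm)), nm)
  g[c("(Intercept)", "smk_former_lt5")] <- c(-1.2, log(1.421))
  b <- stats::setNames(rep(0, length(nm)), nm)
  b[c("(Intercept)", "smk_former_lt5")] <- c(4.0, 0.886)
  use <- manual_refit("re_logit", g, sigma_alpha = 0.9)
  cost <- manual_refit("re_gls", b, sigma_alpha = 0.5, sigma_u = 1.1)
  d <- one_row_design("smk_former_lt5")
  pred <- predict_two_part(use, cost, d, retransform = "normal_theory",
                           integration = "zero_intercept")
  expect_equal(pred$p_use, plogis(-1.2 + log(1.421)))
  expect_equal(pred$cond_cost,
               exp(4.0 + 0.886) * exp((0.5^2 + 1.1^2) / 2))
})

test_that("population-average probability lies inside the node envelope", {
  sim <- simulate_panel(sim_config(n_individuals = 80, seed = 19))
  d <- build_design(derive_covariates(sim$panel))
  nm <- c("(Intercept)", design_columns())
  g <- stats::setNames(runif(length(nm), -0.5, 0.5), nm)
  use <- manual_refit("re_logit", g, sigma_alpha = 1.3)
  cost <- manual_refit("re_gls", g, sigma_alpha = 0.2, sigma_u = 0.4)
  pred <- predict_two_part(use, cost, d, retransform = "normal_theory")
  X <- samecost:::design_matrix(d)
  eta <- drop(X %*% g)
  gh <- samecost:::gh_normal(40)
  lo <- plogis(eta + 1.3 * min(gh$z))
  hi <- plogis(eta + 1.3 * max(gh$z))
  expect_true(all(pred$p_use >= lo & pred$p_use <= hi))
  # averaging a concave-convex mix still differs from the naive plug-in
  expect_false(isTRUE(all.equal(pred$p_use, plogis(eta))))
})

test_that("design mismatch between fit and rows is refused", {
  f <- null_fits()
  d <- one_row_design()
  d$smk_current_light <- NULL
  expect_error(predict_two_part(f$use, f$cost, d), "match|missing")
})

test_that("SAF arithmetic and alignment checks", {
  mk <- function(costs, scenario)
    data.frame(person_id = paste0("P", seq_along(costs)), wave_year = 2015,
               p_use = 1, cond_cost = costs, expected_cost = costs,
               scenario = scenario, service = "outpatient")
  f <- mk(c(60, 40), "factual")
  h <- mk(c(55, 35), "hypothetical")
  saf <- compute_saf(f, h)
  row <- saf[saf$service == "outpatient" & saf$stratum == "all", ]
  expect_equal(row$saf, (100 - 90) / 100)
  expect_equal(compute_saf(f, f)$saf, c(0, 0))
  h_bad <- h[2:1, ]
  expect_error(compute_saf(f, h_bad), "row-aligned")
})

test_that("SAF is invariant to the retransformation factor", {
  sim <- simulate_panel(sim_config(n_individuals = 200, seed = 77))
  panel <- sim$panel
  d <- build_design(derive_covariates(panel))
  fit <- fit_two_part(panel, d, "selfmed", quadrature_nodes = 3)
  cf <- make_counterfactual(d)
  saf_for <- function(rt) {
    f <- predict_two_part(fit$use, fit$cost, d, retransform = rt)
    h <- predict_two_part(fit$use, fit$cost, cf, retransform = rt)
    f$service <- h$service <- "selfmed"
    compute_saf(f, h)$saf
  }
  expect_equal(saf_for("smearing"), saf_for("normal_theory"),
               tolerance = 1e-12)
})

test_that("SAF is exactly zero when fits carry no smoking effects", {
  sim <- simulate_panel(sim_config(n_individuals = 150, seed = 13))
  d <- build_design(derive_covariates(sim$panel))
  nm <- c("(Intercept)", design_columns())
  g <- stats::setNames(runif(length(nm), -0.3, 0.3), nm)
  b <- stats::setNames(runif(length(nm), -0.3, 0.3), nm)
  zero <- samecost:::smoking_design_columns()
  g[zero] <- 0; b[zero] <- 0
  use <- manual_refit("re_logit", g, sigma_alpha = 0.7)
  cost <- manual_refit("re_gls", b, sigma_alpha = 0.4, sigma_u = 1.0)
  f <- predict_two_part(use, cost, d, retransform = "normal_theory")
  h <- predict_two_part(use, cost, make_counterfactual(d),
                        retransform = "normal_theory")
  f$service <- h$service <- "outpatient"
  expect_equal(compute_saf(f, h)$saf, c(0, 0))
})

test_that("raising a smoking cost coefficient cannot lower that SAF", {
  sim <- simulate_panel(sim_config(n_individuals = 150, seed = 34))
  d <- build_design(derive_covariates(sim$panel))
  nm <- c("(Intercept)", design_columns())
  g <- stats::setNames(rep(0.1, length(nm)), nm)
  use <- manual_refit("re_logit", g, sigma_alpha = 0.5)
  saf_at <- function(bheavy) {
    b <- stats::setNames(rep(0.05, length(nm)), nm)
    b["smk_current_heavy"] <- bheavy
    cost <- manual_refit("re_gls", b, sigma_alpha = 0.3, sigma_u = 0.8)
    f <- predict_two_part(use, cost, d, retransform = "normal_theory")
    h <- predict_two_part(use, cost, make_counterfactual(d),
                          retransform = "normal_theory")
    f$service <- h$service <- "inpatient"
    compute_saf(f, h)$saf[1]
  }
  vals <- vapply(c(-0.2, 0, 0.2, 0.5, 1), saf_at, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("pooled overall SAF lies between the service extremes", {
  sim <- simulate_panel(sim_config(n_individuals = 200, seed = 55))
  tr <- sim$truth$true_saf
  expect_gte(tr[["overall"]], min(tr[c("outpatient", "inpatient", "selfmed")]))
  expect_lte(tr[["overall"]], max(tr[c("outpatient", "inpatient", "selfmed")]))
})

test_that("per-stratum SAF rows cover every level plus the pooled sample", {
  mk <- function(costs)
    data.frame(person_id = paste0("P", seq_along(costs)), wave_year = 2015,
               p_use = 1, cond_cost = costs, expected_cost = costs,
               scenario = "factual", service = "inpatient")
  f <- mk(c(10, 20, 30, 40))
  h <- mk(c(9, 18, 30, 40))
  strata <- data.frame(sex = c("male", "male", "female", "female"))
  saf <- compute_saf(f, h, strata = strata)
  m <- saf[saf$stratum == "sex=male" & saf$service == "inpatient", ]
  expect_equal(m$saf, (30 - 27) / 30)
  fm <- saf[saf$stratum == "sex=female" & saf$service == "inpatient", ]
  expect_equal(fm$saf, 0)
  expect_setequal(unique(saf$stratum), c("all", "sex=male", "sex=female"))
})
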