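test_that("simulation is reproducible bit-for-bit from (config, seed)", {
  cfg <- sim_config(n_individuals = 120, seed = 99)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth$intercepts, b$truth$intercepts)
  expect_identical(a$truth$true_saf, b$truth$true_saf)
})

test_that("panel outcomes have strict two-part structure", {
  sim <- simulate_panel(sim_config(n_individuals = 250, seed = 2))
  p <- sim$panel
  expect_true(all((p$outpatient_exp_1m > 0) == p$used_outpatient_1m))
  expect_true(all((p$inpatient_exp_12m > 0) == p$used_inpatient_12m))
  expect_true(all((p$selfmed_exp_1m > 0) == p$used_selfmed_1m))
  # balanced panel: every person appears in every wave
  expect_true(all(table(p$person_id) == 3))
})

test_that("baseline covariate frequencies match configured prevalences", {
  cfg <- sim_config(n_individuals = 4000, seed = 31)
  sim <- simulate_panel(cfg)
  w1 <- sim$panel[sim$panel$wave_year == 2011, ]
  n <- nrow(w1)
  mc3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  pv <- cfg$prevalences
  expect_lt(abs(mean(w1$sex == "male") - pv$male), mc3(pv$male))
  expect_lt(abs(mean(w1$residency == "rural") - pv$rural), mc3(pv$rural))
  st <- classify_smoking_status(w1$ever_smoked_100, w1$currently_smokes,
                                w1$cigs_per_day, w1$years_smoked,
                                w1$years_since_quit)
  p_never <- unname(pv$smoking["never"])
  expect_lt(abs(mean(st == "never") - p_never), mc3(p_never))
  pov <- classify_poverty(w1$cooking_fuel_traditional,
                          w1$toilet_not_flushable, w1$no_running_water,
                          w1$asset_count)
  expect_lt(abs(mean(pov) - pv$poverty), mc3(pv$poverty))
})

test_that("a degenerate generator reduces to a single Bernoulli rate", {
  tp <- default_true_params()
  for (s in names(tp)) {
    tp[[s]]$gamma[-1] <- 0
    tp[[s]]$sigma_alpha_logit <- 0
  }
  cfg <- sim_config(n_individuals = 5000, seed = 17, true_params = tp)
  sim <- simulate_panel(cfg)
  for (s in names(tp)) {
    p0 <- plogis(tp[[s]]$gamma[["(Intercept)"]])
    use <- sim$panel[[samecost:::service_columns(s)$use]]
    expect_lt(abs(mean(use) - p0), 3 * sqrt(p0 * (1 - p0) / nrow(sim$panel)))
  }
})

test_that("true SAF is zero without smoking effects, positive with them", {
  tp <- default_true_params()
  for (s in names(tp)) {
    zero <- samecost:::smoking_design_columns()
    tp[[s]]$gamma[zero] <- 0
    tp[[s]]$beta[zero] <- 0
  }
  sim <- simulate_panel(sim_config(n_individuals = 150, seed = 4,
                                   true_params = tp))
  expect_equal(unname(sim$truth$true_saf), rep(0, 4))

  # all-positive smoking effects give strictly positive SAF
  tp2 <- default_true_params()
  for (s in names(tp2)) {
    zero <- samecost:::smoking_design_columns()
    tp2[[s]]$gamma[zero] <- abs(tp2[[s]]$gamma[zero])
    tp2[[s]]$beta[zero] <- abs(tp2[[s]]$beta[zero])
  }
  sim2 <- simulate_panel(sim_config(n_individuals = 150, seed = 4,
                                    true_params = tp2))
  expect_true(all(sim2$truth$true_saf > 0))
})

test_that("single-row true SAF matches direct numerical integration", {
  tp <- default_true_params()["outpatient"]
  g <- tp$outpatient$gamma
  b <- tp$outpatient$beta
  truth <- structure(
    list(config = list(true_params = tp),
         design = one_row_design(c("smk_current_heavy", "age_65_plus",
                                   "it4"))),
    class = "truth_bundle")
  got <- true_saf(truth)

  # independent oracle: adaptive quadrature over the intercept distribution
  pbar <- function(eta, sig) stats::integrate(function(a)
    plogis(eta + a) * dnorm(a, 0, sig), -Inf, Inf, rel.tol = 1e-10)$value
  sa <- tp$outpatient$sigma_alpha_logit
  lognorm <- exp((tp$outpatient$sigma_alpha_cost^2 +
                    tp$outpatient$sigma_u_cost^2) / 2)
  eta_f <- g[["(Intercept)"]] + g[["smk_current_heavy"]] +
    g[["age_65_plus"]] + g[["it4"]]
  eta_h <- g[["(Intercept)"]] + g[["age_65_plus"]]
  mu_f <- b[["(Intercept)"]] + b[["smk_current_heavy"]] +
    b[["age_65_plus"]] + b[["it4"]]
  mu_h <- b[["(Intercept)"]] + b[["age_65_plus"]]
  fact <- pbar(eta_f, sa) * exp(mu_f) * lognorm
  hyp <- pbar(eta_h, sa) * exp(mu_h) * lognorm
  expect_equal(unname(got["outpatient"]), (fact - hyp) / fact,
               tolerance = 1e-8)
})

test_that("analytic true SAF agrees with counterfactual replay simulation", {
  cfg <- sim_config(n_individuals = 1500, seed = 23)
  sim <- simulate_panel(cfg)
  X <- samecost:::design_matrix(sim$truth$design)
  Xh <- X; Xh[, samecost:::smoking_design_columns()] <- 0
  n_id <- cfg$n_individuals
  ord <- match(sim$truth$design$person_id,
               sim$truth$intercepts$person_id)
  set.seed(555)
  replay_saf <- function(s) {
    tp <- cfg$true_params[[s]]
    draw_total <- function(M) {
      au <- rnorm(n_id, 0, tp$sigma_alpha_logit)[ord]
      ac <- rnorm(n_id, 0, tp$sigma_alpha_cost)[ord]
      use <- runif(nrow(M)) < plogis(drop(M %*% tp$gamma) + au)
      sum(exp(drop(M %*% tp$beta) + ac +
                rnorm(nrow(M), 0, tp$sigma_u_cost))[use])
    }
    1 - draw_total(Xh) / draw_total(X)
  }
  K <- 12
  for (s in c("outpatient", "inpatient")) {
    reps <- replicate(K, replay_saf(s))
    mc_se <- sd(reps) / sqrt(K)
    expect_lt(abs(mean(reps) - sim$truth$true_saf[[s]]), 3 * mc_se)
  }
})

test_that("nominal-price emission is undone by deflation", {
  cfg_n <- sim_config(n_individuals = 100, seed = 12, emit_nominal = TRUE)
  cfg_r <- sim_config(n_individuals = 100, seed = 12, emit_nominal = FALSE)
  nom <- simulate_panel(cfg_n)$panel
  real <- simulate_panel(cfg_r)$panel
  defl <- deflate_panel(nom, list(cpi_medical = cfg_n$cpi_medical,
                                  fx_rate = 1))
  expect_equal(defl$outpatient_exp_1m, real$outpatient_exp_1m,
               tolerance = 1e-12)
  expect_equal(defl$inpatient_exp_12m, real$inpatient_exp_12m,
               tolerance = 1e-12)
})
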