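# Independent oracles and tiny fixture builders used across test files.

# Dense trapezoid integration of the RE-logit marginal log-likelihood over
# the random intercept: the brute-force counterpart of the quadrature fit.
dense_marginal_loglik <- function(X, y, gi, beta, sigma,
                                  grid_n = 4001, width = 8) {
  eta <- drop(X %*% beta)
  if (sigma <= 0) {
    return(sum(stats::dbinom(y, 1, stats::plogis(eta), log = TRUE)))
  }
  a <- seq(-width * sigma, width * sigma, length.out = grid_n)
  da <- a[2] - a[1]
  ll <- 0
  for (i in unique(gi)) {
    sel <- gi == i
    lp <- colSums(stats::dbinom(matrix(y[sel], sum(sel), length(a)), 1,
                                stats::plogis(outer(eta[sel], a, "+")),
                                log = TRUE))
    ll <- ll + log(sum(exp(lp) * stats::dnorm(a, 0, sigma)) * da)
  }
  ll
}

# Explicit GLS solve with the block covariance Sigma_i = s2a J + s2u I,
# the brute-force counterpart of the quasi-demeaning transform.
block_gls_beta <- function(X, y, gi, s2a, s2u) {
  n <- length(y)
  V <- diag(s2u, n)
  for (i in unique(gi)) {
    sel <- which(gi == i)
    V[sel, sel] <- V[sel, sel] + s2a
  }
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
}

# Small panel with one covariate and a known random-intercept SD, for
# focused logit tests that do not need the full covariate battery.
tiny_logit_panel <- function(n_id = 20, waves = 3, sigma = 1,
                             beta = c(-0.3, 0.8), seed = 3) {
  set.seed(seed)
  pid <- rep(sprintf("I%03d", seq_len(n_id)), each = waves)
  x1 <- stats::rnorm(n_id * waves)
  a_i <- rep(stats::rnorm(n_id, 0, sigma), each = waves)
  y <- as.numeric(stats::runif(n_id * waves) <
                    stats::plogis(beta[1] + beta[2] * x1 + a_i))
  list(design = data.frame(person_id = pid,
                           wave_year = rep(seq_len(waves) + 2010, n_id),
                           x1 = x1),
       y = y, gi = match(pid, unique(pid)))
}

# A refit object with chosen coefficients, for prediction-layer tests that
# need exact parameter control.
manual_refit <- function(model, coefficients, sigma_alpha = 0,
                         sigma_u = NA_real_, residuals = NULL) {
  samecost:::new_refit(
    model = model, coefficients = coefficients,
    std_errors = coefficients * 0, sigma_alpha = sigma_alpha,
    sigma_u = sigma_u, n_obs = 1L, n_individuals = 1L,
    converged = TRUE, iterations = 1L, residuals = residuals)
}

# One-row design on the canonical layout.
one_row_design <- function(set = character()) {
  d <- as.data.frame(as.list(stats::setNames(rep(0, length(design_columns())),
                                             design_columns())))
  d <- cbind(data.frame(person_id = "P1", wave_year = 2015), d)
  for (col in set) d[[col]] <- 1
  d
}
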