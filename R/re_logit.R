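#' Random-effects logit for any service use
#'
#' Fits the use equation of the two-part model: a panel logit with a
#' time-invariant individual random intercept `alpha_i ~ N(0, sigma_alpha^2)`
#' integrated out of the likelihood by adaptive Gauss-Hermite quadrature
#' (the marginal maximum-likelihood estimator). Standard errors come from
#' the observed information at the optimum.
#'
#' @param design Design `data.frame` from [build_design()] (person_id,
#'   wave_year, and the canonical predictor columns).
#' @param outcome Logical/0-1 vector, one per design row: any use of the
#'   service in its recall window.
#' @param quadrature_nodes Number of adaptive quadrature points (default 15).
#' @param max_iterations Optimizer evaluation budget.
#' @param columns Predictor columns to use, in order
#'   (default [design_columns()]).
#' @return A `refit` with coefficients (intercept first, then `columns`),
#'   standard errors, `sigma_alpha`, marginal log-likelihood, and
#'   convergence metadata.
#' @export
fit_re_logit <- function(design, outcome, quadrature_nodes = 15,
                         max_iterations = 10000,
                         columns = design_columns()) {
  y <- as.numeric(outcome)
  if (length(y) != nrow(design))
    stop("fit_re_logit: outcome length must match design rows",
         call. = FALSE)
  if (length(unique(y[!is.na(y)])) < 2)
    stop("fit_re_logit: outcome is constant (degenerate)", call. = FALSE)
  X <- design_matrix(design, columns)
  df <- as.data.frame(X[, -1, drop = FALSE])
  df$.y <- y
  df$.pid <- design$person_id
  fml <- stats::as.formula(paste(".y ~", paste(columns, collapse = " + "),
                                 "+ (1 | .pid)"))
  fit <- suppressWarnings(suppressMessages(lme4::glmer(
    fml, data = df, family = stats::binomial(),
    nAGQ = quadrature_nodes,
    control = lme4::glmerControl(
      optimizer = "nloptwrap", optCtrl = list(maxeval = max_iterations),
      calc.derivs = TRUE, check.conv.singular = "ignore"))))
  # the optimizer status is authoritative; lme4's post-hoc gradient checks
  # are kept as notes
  conv <- fit@optinfo$conv$opt == 0
  check_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  co <- lme4::fixef(fit)
  se <- suppressWarnings(sqrt(diag(as.matrix(stats::vcov(fit)))))
  names(se) <- names(co)
  sigma_alpha <- sqrt(unname(lme4::VarCorr(fit)$.pid[1, 1]))
  # columns dropped by the fitter for rank deficiency are reported as zero
  full <- c("(Intercept)", columns)
  co_full <- stats::setNames(rep(0, length(full)), full)
  se_full <- stats::setNames(rep(NA_real_, length(full)), full)
  co_full[names(co)] <- co
  se_full[names(se)] <- se
  notes <- as.character(check_msgs)
  if (length(setdiff(full, names(co))))
    notes <- c(notes, paste("aliased columns set to zero:",
                            paste(setdiff(full, names(co)), collapse = ", ")))
  new_refit(model = "re_logit",
            coefficients = co_full,
            std_errors = se_full,
            sigma_alpha = sigma_alpha,
            log_likelihood = as.numeric(stats::logLik(fit)),
            n_obs = nrow(df),
            n_individuals = length(unique(df$.pid)),
            converged = conv,
            iterations = as.integer(fit@optinfo$feval %||% NA_integer_),
            notes = notes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
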