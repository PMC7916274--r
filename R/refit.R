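new_refit <- function(model, coefficients, std_errors, sigma_alpha,
                      sigma_u = NA_real_, log_likelihood = NA_real_,
                      n_obs, n_individuals, converged, iterations,
                      residuals = NULL, notes = character()) {
  structure(list(model = model, coefficients = coefficients,
                 std_errors = std_errors, sigma_alpha = sigma_alpha,
                 sigma_u = sigma_u, log_likelihood = log_likelihood,
                 n_obs = n_obs, n_individuals = n_individuals,
                 converged = converged, iterations = iterations,
                 residuals = residuals, notes = notes),
            class = "refit")
}

#' @export
print.refit <- function(x, ...) {
  cat(sprintf("Random-effects %s fit: %d obs, %d individuals%s\n",
              if (x$model == "re_logit") "logit" else "GLS",
              x$n_obs, x$n_individuals,
              if (x$converged) "" else " (NOT CONVERGED)"))
  tab <- data.frame(estimate = x$coefficients, std_error = x$std_errors)
  print(round(tab, 4))
  cat(sprintf("sigma_alpha = %.4f", x$sigma_alpha))
  if (!is.na(x$sigma_u)) cat(sprintf(", sigma_u = %.4f", x$sigma_u))
  if (!is.na(x$log_likelihood))
    cat(sprintf(", logLik = %.3f", x$log_likelihood))
  cat("\n")
  for (nt in x$notes) cat("note:", nt, "\n")
  invisible(x)
}

#' Adjusted odds ratios from a random-effects logit fit
#'
#' Exponentiates every coefficient except the intercept, giving the
#' association of each covariate with service use conditional on the
#' others and on the individual random intercept.
#'
#' @param fit A converged `refit` from [fit_re_logit()].
#' @return Named numeric vector of adjusted odds ratios.
#' @export
adjusted_odds_ratios <- function(fit) {
  stopifnot(inherits(fit, "refit"))
  if (fit$model != "re_logit")
    stop("adjusted_odds_ratios: fit must come from fit_re_logit",
         call. = FALSE)
  if (!isTRUE(fit$converged))
    stop("adjusted_odds_ratios: fit did not converge", call. = FALSE)
  co <- fit$coefficients
  exp(co[setdiff(names(co), "(Intercept)")])
}

# Serialize a refit to a JSON-ready list (used by the CLI and pipeline).
refit_to_list <- function(fit) {
  fit[c("model", "coefficients", "std_errors", "sigma_alpha", "sigma_u",
        "log_likelihood", "n_obs", "n_individuals", "converged",
        "iterations", "notes")]
}
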