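#' Random-effects GLS regression on log expenditure
#'
#' Fits the cost equation of the two-part model among service users:
#' `log(Exp_it) = x_it' beta + alpha_i + u_it` by feasible GLS. Variance
#' components are estimated by the Swamy-Arora method (idiosyncratic
#' variance from the within regression, between variance from the
#' group-means regression; a negative between estimate is clamped to zero
#' with a note), followed by the quasi-demeaning GLS transform and OLS.
#' Standard errors are cluster-robust by individual.
#'
#' @param design Design `data.frame` from [build_design()].
#' @param expenditure Strictly positive expenditures, one per design row;
#'   the log is taken inside.
#' @param columns Predictor columns (default [design_columns()]).
#' @return A `refit` with coefficients, cluster-robust standard errors,
#'   `sigma_alpha`, `sigma_u`, and the composite residuals
#'   `log(exp) - x'beta` used for smearing retransformation.
#' @export
fit_re_gls <- function(design, expenditure, columns = design_columns()) {
  if (length(expenditure) != nrow(design))
    stop("fit_re_gls: expenditure length must match design rows",
         call. = FALSE)
  if (any(expenditure <= 0))
    stop("fit_re_gls: expenditures must be strictly positive", call. = FALSE)
  y <- log(expenditure)
  X <- design_matrix(design, columns)
  g <- as.character(design$person_id)
  N <- nrow(X); p <- ncol(X)
  if (N <= p)
    stop("fit_re_gls: fewer observations than parameters (rank deficiency)",
         call. = FALSE)
  groups <- unique(g)
  n <- length(groups)
  Ti <- as.vector(table(g)[groups])
  gi <- match(g, groups)

  group_mean <- function(v) tapply(v, gi, mean)[gi]
  ybar <- group_mean(y)
  Xbar <- apply(X, 2, group_mean)

  # within (fixed-effects) regression for the idiosyncratic variance
  yw <- y - ybar
  Xw <- X - Xbar
  keep_w <- colSums(Xw^2) > 1e-10
  qw <- qr(Xw[, keep_w, drop = FALSE])
  k_w <- qw$rank
  ew <- stats::residuals(stats::lm.fit(Xw[, keep_w, drop = FALSE], yw))
  df_w <- N - n - k_w
  if (df_w <= 0)
    stop("fit_re_gls: not enough within-group degrees of freedom",
         call. = FALSE)
  sigma2_u <- sum(ew^2) / df_w

  # between regression for the individual-level variance
  Xb <- apply(X, 2, function(v) tapply(v, gi, mean))
  yb <- tapply(y, gi, mean)
  qb <- qr(Xb)
  k_b <- qb$rank
  eb <- stats::residuals(stats::lm.fit(Xb, yb))
  df_b <- n - k_b
  if (df_b <= 0)
    stop("fit_re_gls: not enough between-group degrees of freedom",
         call. = FALSE)
  sigma2_1 <- sum(eb^2) / df_b
  sigma2_alpha <- sigma2_1 - sigma2_u * mean(1 / Ti)
  notes <- character()
  if (sigma2_alpha < 0) {
    sigma2_alpha <- 0
    notes <- "between-individual variance estimate was negative; clamped to 0"
  }

  # GLS via quasi-demeaning; aliased (collinear or empty) columns are
  # dropped from estimation and reported as zero with NA standard errors
  theta_i <- 1 - sqrt(sigma2_u / (sigma2_u + Ti * sigma2_alpha))
  th <- theta_i[gi]
  ys <- as.vector(y - th * ybar)
  Xs <- X - th * Xbar
  qs <- qr(Xs)
  keep <- sort(qs$pivot[seq_len(qs$rank)])
  if (qs$rank < p)
    notes <- c(notes, paste("aliased columns set to zero:",
                            paste(colnames(X)[-keep], collapse = ", ")))
  Xk <- Xs[, keep, drop = FALSE]
  XtX <- crossprod(Xk)
  beta <- stats::setNames(rep(0, p), colnames(X))
  beta[keep] <- drop(solve(XtX, crossprod(Xk, ys)))

  # cluster-robust (by individual) covariance
  es <- as.vector(ys - Xs %*% beta)
  bread <- solve(XtX)
  scores <- rowsum(Xk * es, gi)
  meat <- crossprod(as.matrix(scores))
  adj <- (n / (n - 1)) * ((N - 1) / (N - length(keep)))
  V <- adj * bread %*% meat %*% bread
  se <- stats::setNames(rep(NA_real_, p), colnames(X))
  se[keep] <- sqrt(diag(V))

  new_refit(model = "re_gls", coefficients = beta, std_errors = se,
            sigma_alpha = sqrt(sigma2_alpha), sigma_u = sqrt(sigma2_u),
            n_obs = N, n_individuals = n, converged = TRUE,
            iterations = 1L,
            residuals = y - drop(X %*% beta), notes = notes)
}
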