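# OLS with explicit model-matrix algebra: the coefficient vector, (X'X)^-1 and
# the residual standard error are retained so that confidence intervals for
# differences between predictions can be formed directly from t critical
# values, as in compositional reallocation and isotemporal substitution
# estimands.

#' Fit ordinary least squares with explicit normal-equation components
#'
#' Solves `beta = (X'X)^-1 X'y` (via a QR decomposition for numerical
#' stability) and retains `(X'X)^-1`, the residual standard error
#' `s = sqrt(RSS / (n - p))` and the residual degrees of freedom, which
#' together determine prediction-difference confidence intervals.
#'
#' @param X Design matrix (include an intercept column if wanted), full
#'   column rank, n > p.
#' @param y Numeric outcome vector of length n.
#' @return An object of class `ols_fit` with elements `coefficients`,
#'   `xtx_inv`, `sigma` (residual SE), `df` (n - p), `n`, `columns`,
#'   `residuals`, `fitted`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y have incompatible dimensions")
  if (anyNA(X) || anyNA(y)) stop("fit_ols() does not accept missing values")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than columns (n > p)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fitted <- as.numeric(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  df <- n - p
  xtx_inv <- chol2inv(chol(crossprod(X)))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  structure(
    list(coefficients = beta, xtx_inv = xtx_inv,
         sigma = sqrt(rss / df), df = df, n = n,
         columns = colnames(X), residuals = res, fitted = fitted),
    class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, p = %d, residual SE = %.4g on %d df\n",
              x$n, length(x$coefficients), x$sigma, x$df))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Confidence interval for a difference between two mean predictions
#'
#' For design rows `x1` and `x0`, the estimated difference is
#' `d' beta` with `d = x1 - x0`, and the interval is
#' `d' beta +/- t_{df, (1+level)/2} * s * sqrt(d' (X'X)^-1 d)`.
#' Covariate columns identical in the two rows cancel exactly, so the
#' interval only reflects the columns being contrasted.
#'
#' @param fit An [fit_ols()] object.
#' @param x1,x0 Numeric design rows conforming to `fit$columns`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A one-row data.frame with `estimate`, `lower`, `upper`, `level`.
#' @export
predict_difference_ci <- function(fit, x1, x0, level = 0.95) {
  stopifnot(inherits(fit, "ols_fit"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1")
  }
  x1 <- as.numeric(x1); x0 <- as.numeric(x0)
  p <- length(fit$coefficients)
  if (length(x1) != p || length(x0) != p) {
    stop("design rows must have one entry per fitted coefficient")
  }
  d <- x1 - x0
  est <- sum(d * fit$coefficients)
  half <- stats::qt((1 + level) / 2, df = fit$df) * fit$sigma *
    sqrt(as.numeric(t(d) %*% fit$xtx_inv %*% d))
  data.frame(estimate = est, lower = est - half, upper = est + half,
             level = level)
}

#' Regression diagnostic battery
#'
#' Runs the standard checks on a fitted model: Ramsey RESET (powers 2-3 of the
#' fitted values) for functional form, variance inflation factors for
#' collinearity, the Durbin-Watson statistic for residual autocorrelation,
#' Breusch-Pagan for heteroscedasticity, and Shapiro-Wilk for residual
#' normality. Tests that cannot be run at the given sample size are reported
#' as `NA` rather than raising.
#'
#' @param fit An [fit_ols()] object produced from `(X, y)`.
#' @param X,y The design matrix and outcome used for the fit.
#' @return A list with `reset_p`, `vif` (named, non-intercept columns),
#'   `durbin_watson`, `breusch_pagan_p`, `shapiro_w`, `shapiro_p`.
#' @export
ols_diagnostics <- function(fit, X, y) {
  stopifnot(inherits(fit, "ols_fit"))
  X <- as.matrix(X); y <- as.numeric(y)
  e <- fit$residuals
  dw <- sum(diff(e)^2) / sum(e^2)

  # VIF_j = 1 / (1 - R^2_j) from regressing column j on the other columns
  # (intercept-like constant columns excluded from the report).
  is_const <- apply(X, 2, function(v) stats::var(v) == 0)
  vif <- rep(NA_real_, ncol(X))
  names(vif) <- colnames(X)
  idx <- which(!is_const)
  for (j in idx) {
    others <- X[, setdiff(seq_len(ncol(X)), j), drop = FALSE]
    r2 <- tryCatch({
      f <- stats::lm.fit(others, X[, j])
      1 - sum(f$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    }, error = function(e) NA_real_)
    vif[j] <- if (is.na(r2) || r2 >= 1) Inf else 1 / (1 - r2)
  }
  vif <- vif[idx]

  lmfit <- tryCatch(stats::lm(y ~ X0, data = list(y = y, X0 = X[, !is_const, drop = FALSE])),
                    error = function(e) NULL)
  reset_p <- tryCatch(lmtest::resettest(lmfit, power = 2:3, type = "fitted")$p.value,
                      error = function(e) NA_real_)
  bp_p <- tryCatch(lmtest::bptest(lmfit)$p.value, error = function(e) NA_real_)
  # shapiro.test caps at n = 5000; take a deterministic evenly-spaced subset
  e_sw <- if (length(e) > 5000) e[round(seq(1, length(e), length.out = 5000))] else e
  sw <- tryCatch(stats::shapiro.test(e_sw), error = function(e) NULL)

  list(reset_p = as.numeric(reset_p),
       vif = vif,
       durbin_watson = dw,
       breusch_pagan_p = as.numeric(bp_p),
       shapiro_w = if (is.null(sw)) NA_real_ else as.numeric(sw$statistic),
       shapiro_p = if (is.null(sw)) NA_real_ else sw$p.value)
}
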