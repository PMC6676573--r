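#' Specify the treatment-marker interaction analysis model
#'
#' The analysis model is `Y = alpha(X) + theta(X) * T` with both parts linear
#' or both quadratic in the marker:
#' \describe{
#'   \item{linear}{columns 1, x, t, t:x — `theta(x) = b0 + b1 x`}
#'   \item{quadratic}{columns 1, x, x^2, t, t:x, t:x^2 —
#'     `theta(x) = b0 + b1 x + b2 x^2`}
#' }
#'
#' @param degree `"linear"`/`1` or `"quadratic"`/`2`.
#' @return An object of class `tx_model_spec`.
#' @export
model_spec <- function(degree = c("linear", "quadratic")) {
  if (is.numeric(degree)) degree <- c("linear", "quadratic")[degree]
  degree <- match.arg(degree)
  structure(list(degree = if (degree == "linear") 1L else 2L,
                 label = degree),
            class = "tx_model_spec")
}

design_matrix <- function(marker, arm, degree) {
  if (degree == 1L) {
    X <- cbind(1, marker, arm, arm * marker)
    colnames(X) <- c("(Intercept)", "x", "t", "t:x")
  } else {
    X <- cbind(1, marker, marker^2, arm, arm * marker, arm * marker^2)
    colnames(X) <- c("(Intercept)", "x", "x2", "t", "t:x", "t:x2")
  }
  X
}

#' Fit the interaction model by ordinary least squares
#'
#' Plain OLS with the usual unbiased error-variance estimate; the coefficient
#' covariance is `sigma2 * (X'X)^{-1}`. The treatment block (coefficients of
#' `t`, `t:x` and, for the quadratic model, `t:x2`) parameterizes the estimated
#' treatment-effect function `theta_hat(x)`.
#'
#' @param data A `tx_trial` or any data.frame with numeric columns `marker`,
#'   `arm` (0/1) and `outcome`.
#' @param spec A [model_spec()].
#' @return An object of class `tx_fit` with elements `coefficients`,
#'   `covariance`, `residual_df`, `treatment_block` (column indices), `sigma2`,
#'   `degree`, `n`.
#' @export
fit_interaction_model <- function(data, spec = model_spec("linear")) {
  stopifnot(inherits(spec, "tx_model_spec"))
  if (!all(c("marker", "arm", "outcome") %in% names(data)))
    stop("'data' needs columns marker, arm, outcome")
  if (!all(data$arm %in% c(0, 1))) stop("'arm' must be coded 0/1")
  X <- design_matrix(data$marker, data$arm, spec$degree)
  y <- data$outcome
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than design columns")
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R) || min(abs(diag(R))) < 1e-10 * max(abs(diag(R))))
    stop("singular design: interaction model cannot be fitted")
  coef <- drop(backsolve(R, forwardsolve(t(R), crossprod(X, y))))
  res <- y - drop(X %*% coef)
  df <- n - p
  sigma2 <- sum(res^2) / df
  cov <- sigma2 * chol2inv(R)
  dimnames(cov) <- list(colnames(X), colnames(X))
  names(coef) <- colnames(X)
  tb <- if (spec$degree == 1L) 3:4 else 4:6
  structure(list(coefficients = coef, covariance = cov, residual_df = df,
                 treatment_block = tb, sigma2 = sigma2,
                 degree = spec$degree, n = n),
            class = "tx_fit")
}

# treatment-block coefficient vector and covariance submatrix
effect_block <- function(fit) {
  stopifnot(inherits(fit, "tx_fit"))
  list(g = unname(fit$coefficients[fit$treatment_block]),
       Sigma = unname(fit$covariance[fit$treatment_block, fit$treatment_block]))
}

# basis a(x) = (1, x[, x^2]) as a matrix with one row per x
effect_basis <- function(x, degree) {
  if (degree == 1L) cbind(1, x) else cbind(1, x, x^2)
}

#' Estimated treatment effect and its standard error at marker values
#'
#' `theta_hat(x) = a(x)' g` with `a(x) = (1, x)` or `(1, x, x^2)` and `g` the
#' treatment-block coefficients; the standard error is
#' `sqrt(a(x)' Sigma a(x))` with `Sigma` the treatment-block covariance.
#'
#' @param fit A [fit_interaction_model()] result.
#' @param x Marker values in \[0, 1\] (vectorized).
#' @return A list with numeric vectors `estimate` and `stderr`.
#' @export
estimate_effect <- function(fit, x) {
  x <- check_domain(x)
  eb <- effect_block(fit)
  A <- effect_basis(x, fit$degree)
  est <- drop(A %*% eb$g)
  se <- sqrt(rowSums((A %*% eb$Sigma) * A))
  list(estimate = est, stderr = se)
}

#' Interaction pretest
#'
#' F-test that the treatment-marker interaction coefficients (`t:x`, and
#' `t:x2` for the quadratic model) are jointly zero, with the fit's residual
#' degrees of freedom in the denominator. For the linear model this equals the
#' squared t-test of the single interaction coefficient. Selection rules are
#' only constructed when this pretest is significant; otherwise every candidate
#' set is empty.
#'
#' @param fit A [fit_interaction_model()] result.
#' @param level Test level in (0, 1); default 0.05.
#' @return A list with `statistic`, `df1`, `df2`, `p_value`, `significant`
#'   (`p_value < level`).
#' @export
interaction_pretest <- function(fit, level = 0.05) {
  stopifnot(inherits(fit, "tx_fit"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must be in (0, 1)")
  # interaction coefficients = treatment block without the main t term
  idx <- fit$treatment_block[-1]
  g <- fit$coefficients[idx]
  V <- fit$covariance[idx, idx, drop = FALSE]
  q <- length(g)
  stat <- drop(crossprod(g, solve(V, g))) / q
  p <- stats::pf(stat, q, fit$residual_df, lower.tail = FALSE)
  list(statistic = stat, df1 = q, df2 = fit$residual_df,
       p_value = p, significant = p < level)
}

#' @export
print.tx_fit <- function(x, ...) {
  cat(sprintf("<tx_fit: %s interaction model, n = %d, residual df = %d>\n",
              if (x$degree == 1L) "linear" else "quadratic", x$n, x$residual_df))
  print(round(x$coefficients, 4))
  invisible(x)
}
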