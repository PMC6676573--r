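#' Confidence bands for the treatment-effect function
#'
#' `pointwise_band()` builds the classical t-based band
#' `theta_hat(x) -/+ t_{df, 1-gamma/2} * se(x)` which controls coverage at each
#' marker value separately. `simultaneous_band()` replaces the t quantile by a
#' critical value controlling coverage of the whole function over the marker
#' domain at once, so its lower bound never lies above the pointwise one at the
#' same level.
#'
#' @param fit A [fit_interaction_model()] result.
#' @param level Confidence level `1 - gamma` in (0, 1).
#' @param method,draws,grid_size,domain Passed to
#'   [simultaneous_critical_value()].
#' @return An object of class `tx_band` with fields `kind`, `level`,
#'   `critical_value` and vectorized functions `estimate(x)`, `lower(x)`,
#'   `upper(x)`.
#' @examples
#' set.seed(1)
#' tr <- sample_trial(scenario("linear", 0.8), 500)
#' f <- fit_interaction_model(tr, model_spec("linear"))
#' b <- pointwise_band(f, 0.95)
#' b$lower(c(0.25, 0.75))
#' @export
pointwise_band <- function(fit, level = 0.95) {
  check_level(level)
  crit <- stats::qt(1 - (1 - level) / 2, fit$residual_df)
  new_band(fit, level, crit, "pointwise")
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must be a number in (0, 1)")
  invisible(level)
}

new_band <- function(fit, level, crit, kind) {
  eb <- effect_block(fit)
  degree <- fit$degree
  est_fun <- function(x) drop(effect_basis(check_domain(x), degree) %*% eb$g)
  se_fun <- function(x) {
    A <- effect_basis(check_domain(x), degree)
    sqrt(rowSums((A %*% eb$Sigma) * A))
  }
  structure(list(kind = kind, level = level, critical_value = crit,
                 g = eb$g, Sigma = eb$Sigma, degree = degree,
                 residual_df = fit$residual_df,
                 estimate = est_fun,
                 lower = function(x) est_fun(x) - crit * se_fun(x),
                 upper = function(x) est_fun(x) + crit * se_fun(x)),
            class = "tx_band")
}

# rows of A %*% t(chol(Sigma)) normalized to unit length: the path u(x) of the
# standardized band-deviation process on the sphere.
band_unit_path <- function(Sigma, degree, domain, grid_size) {
  x <- seq(domain[1], domain[2], length.out = grid_size)
  A <- effect_basis(x, degree)
  U <- chol(Sigma)
  M <- A %*% t(U)
  M / sqrt(rowSums(M^2))
}

# draws of sup_x |a(x)' Z| / se(x) with Z ~ N(0, Sigma); consumes the current
# RNG stream. Returns the vector of sups so quantiles at several levels can be
# taken from one set of draws.
supt_sup_draws <- function(Sigma, degree, domain = c(0, 1),
                           draws = 1e5, grid_size = 201L, chunk = 20000L) {
  Mu <- band_unit_path(Sigma, degree, domain, grid_size)
  d <- ncol(Mu)
  sups <- numeric(draws)
  done <- 0L
  while (done < draws) {
    m <- min(chunk, draws - done)
    P <- abs(matrix(stats::rnorm(m * d), m, d) %*% t(Mu))
    idx <- max.col(P, ties.method = "first")
    sups[done + seq_len(m)] <- P[cbind(seq_len(m), idx)]
    done <- done + m
  }
  sups
}

# tube-formula (Kac-Rice type) tail approximation for the sup of the absolute
# standardized process along a curve of length kappa on the sphere:
#   P(sup |t| > c) ~ (kappa / pi) exp(-c^2 / 2) + 2 (1 - Phi(c))
tube_critical_value <- function(Sigma, degree, level, domain = c(0, 1),
                                grid_size = 201L) {
  Mu <- band_unit_path(Sigma, degree, domain, grid_size)
  dots <- rowSums(Mu[-1, , drop = FALSE] * Mu[-nrow(Mu), , drop = FALSE])
  kappa <- sum(acos(pmin(1, pmax(-1, dots))))
  gamma <- 1 - level
  f <- function(c) kappa / pi * exp(-c^2 / 2) + 2 * stats::pnorm(c, lower.tail = FALSE) - gamma
  lo <- stats::qnorm(1 - gamma / 2)
  hi <- lo + 10
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simultaneous critical value for a band over a bounded marker interval
#'
#' Constant `c` with
#' `P(sup_x |theta_hat(x) - theta(x)| / se(x) <= c) ~ level` over the domain,
#' for the fitted design's treatment-block covariance. The reference method is
#' sup-t Monte Carlo: draw zero-mean normal vectors with the plug-in
#' covariance, evaluate the sup of the absolute standardized process on a grid,
#' and take the level quantile. A fast analytic tube-formula backend
#' (`method = "tube"`) is also provided; both agree closely at the usual
#' levels. The returned value is floored at the pointwise t quantile, so the
#' simultaneous band always contains the pointwise band, and it never exceeds
#' the Scheffé bound `sqrt(d * qf(level, d, df))`.
#'
#' @param fit A [fit_interaction_model()] result.
#' @param level Confidence level in (0, 1).
#' @param domain Marker subinterval of \[0, 1\].
#' @param method `"supt"` (Monte Carlo reference) or `"tube"` (analytic).
#' @param draws Monte Carlo draws for `"supt"`.
#' @param grid_size Grid resolution for the sup.
#' @return The critical value (a positive scalar).
#' @export
simultaneous_critical_value <- function(fit, level = 0.95, domain = c(0, 1),
                                        method = c("supt", "tube"),
                                        draws = 1e5, grid_size = 201L) {
  check_level(level)
  method <- match.arg(method)
  if (domain[1] < 0 || domain[2] > 1 || domain[1] > domain[2])
    stop("'domain' must be a subinterval of [0, 1]")
  eb <- effect_block(fit)
  if (domain[2] - domain[1] < 1e-12) {
    return(stats::qt(1 - (1 - level) / 2, fit$residual_df))
  }
  crit <- if (method == "supt") {
    sups <- supt_sup_draws(eb$Sigma, fit$degree, domain, draws, grid_size)
    stats::quantile(sups, level, names = FALSE)
  } else {
    tube_critical_value(eb$Sigma, fit$degree, level, domain, grid_size)
  }
  max(crit, stats::qt(1 - (1 - level) / 2, fit$residual_df))
}

#' @rdname pointwise_band
#' @export
simultaneous_band <- function(fit, level = 0.95, method = c("supt", "tube"),
                              draws = 1e5, grid_size = 201L, domain = c(0, 1)) {
  crit <- simultaneous_critical_value(fit, level, domain, method, draws, grid_size)
  new_band(fit, level, crit, "simultaneous")
}

#' Horizontal inversion of a confidence band
#'
#' A pointwise `1 - gamma` band for `theta(.)` read horizontally: the set of
#' marker values `x` for which `(threshold, x)` lies inside the band, i.e.
#' `lower(x) <= threshold <= upper(x)`. This set is a `1 - gamma` confidence
#' set for `theta^{-1}(threshold)`, which ties the pointwise-band rule to the
#' root-interval rule. Boundaries solve the polynomial equation
#' `(theta_hat(x) - threshold)^2 = c^2 * se(x)^2`.
#'
#' @param band A `tx_band` (pointwise by construction; any band is accepted).
#' @param threshold Effect threshold (the rules in this package use 0).
#' @param domain Marker subinterval.
#' @return A [selection_set()] of marker values compatible with
#'   `theta(x) = threshold`.
#' @export
invert_band_horizontally <- function(band, threshold = 0, domain = c(0, 1)) {
  stopifnot(inherits(band, "tx_band"))
  q1 <- numeric(band$degree + 1L)
  q1[seq_along(band$g)] <- band$g
  q1[1] <- q1[1] - threshold
  q2 <- quadform_coefs(band$Sigma)
  # inside the band <=> c^2 se^2 - (theta_hat - thr)^2 >= 0
  h <- polyadd(band$critical_value^2 * q2, -polymul(q1, q1))
  s <- selection_set(NULL, domain)
  s$intervals <- poly_sign_set(h, domain)
  s
}

# ascending coefficients of the polynomial a(x)' Sigma a(x)
quadform_coefs <- function(Sigma) {
  d <- nrow(Sigma)
  out <- numeric(2L * d - 1L)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    k <- i + j - 1L
    out[k] <- out[k] + Sigma[i, j]
  }
  out
}

#' @export
print.tx_band <- function(x, ...) {
  cat(sprintf("<tx_band: %s, level %.3g, critical value %.4f>\n",
              x$kind, x$level, x$critical_value))
  invisible(x)
}
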