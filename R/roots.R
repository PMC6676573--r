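#' Delta-method confidence intervals for the roots of the estimated effect
#'
#' The estimated treatment-effect polynomial `theta_hat(x) = a(x)' g` has at
#' most `degree` real roots. For each root inside the domain a symmetric
#' normal-quantile interval `root +- z_{1-gamma/2} * SE` is returned, with the
#' standard error from first-order (delta-method) propagation of the
#' treatment-block covariance: the gradient of the root with respect to the
#' coefficient `g_k` is `-r^k / theta_hat'(r)`.
#'
#' If the derivative of the effect polynomial vanishes at a root (a double
#' root, or a constant linear effect), the root location is not first-order
#' identified and the result is flagged `degenerate`; the CIR rule then treats
#' the exclusion as the whole domain (maximally conservative, i.e. an empty
#' selection).
#'
#' @param fit A [fit_interaction_model()] result.
#' @param level Confidence level in (0, 1).
#' @param domain Marker subinterval; roots outside it are dropped, intervals
#'   are clipped to it.
#' @return A list with `roots`: a list of entries `root`, `se`, `lower`,
#'   `upper`; and `degenerate`: logical.
#' @examples
#' # a linear effect block with a root at 0.5
#' f <- structure(list(coefficients = c(0, 0, -0.4, 0.8),
#'                     covariance = diag(c(1, 1, 0.01, 0.04)),
#'                     residual_df = 100L, treatment_block = 3:4,
#'                     sigma2 = 1, degree = 1L, n = 104L), class = "tx_fit")
#' root_cis_delta(f, 0.95)$roots[[1]]
#' @export
root_cis_delta <- function(fit, level = 0.95, domain = c(0, 1)) {
  check_level(level)
  eb <- effect_block(fit)
  g <- eb$g
  dcoef <- poly_deriv(g)
  rts <- effect_poly_roots(g)
  rts <- rts[rts >= domain[1] - 1e-12 & rts <= domain[2] + 1e-12]
  rts <- pmin(pmax(rts, domain[1]), domain[2])
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- list()
  degenerate <- FALSE
  for (r in rts) {
    slope <- polyval(dcoef, r)
    if (abs(slope) < 1e-12 * max(abs(g), 1)) {
      degenerate <- TRUE
      next
    }
    grad <- -r^(seq_along(g) - 1L) / slope
    se <- sqrt(drop(crossprod(grad, eb$Sigma %*% grad)))
    out[[length(out) + 1L]] <- list(
      root = r, se = se,
      lower = max(domain[1], r - z * se),
      upper = min(domain[2], r + z * se))
  }
  # linear model with zero slope: root of a constant, nowhere identified
  if (length(g) == 2L && abs(g[2]) < 1e-12 * max(abs(g), 1) && abs(g[1]) < 1e-12)
    degenerate <- TRUE
  list(roots = out, degenerate = degenerate)
}

poly_deriv <- function(coefs) {
  if (length(coefs) <= 1L) return(0)
  coefs[-1] * seq_len(length(coefs) - 1L)
}

# real roots of the (degree <= 2) effect polynomial, closed form
effect_poly_roots <- function(g) {
  g <- as.numeric(g)
  if (length(g) == 2L) {
    if (g[2] == 0) return(numeric(0))
    return(-g[1] / g[2])
  }
  if (g[3] == 0) {
    if (g[2] == 0) return(numeric(0))
    return(-g[1] / g[2])
  }
  disc <- g[2]^2 - 4 * g[3] * g[1]
  if (disc < 0) return(numeric(0))
  if (disc == 0) return(-g[2] / (2 * g[3]))
  sq <- sqrt(disc)
  sort(c((-g[2] - sq) / (2 * g[3]), (-g[2] + sq) / (2 * g[3])))
}
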