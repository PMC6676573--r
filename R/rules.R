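#' The four treatment selection rules
#'
#' Given a fitted interaction model and its uncertainty objects, four
#' construction principles turn the estimated treatment-effect function into a
#' selection set on the marker domain (closed `>=` convention throughout):
#' \describe{
#'   \item{EST}{`{x : theta_hat(x) >= 0}` — positivity of the estimate
#'     ([rule_est()]).}
#'   \item{POI}{`{x : l_p(x) >= 0}` — positivity of the pointwise band's lower
#'     bound ([rule_band()] on a pointwise band).}
#'   \item{SIM}{`{x : l_s(x) >= 0}` — positivity of the simultaneous band's
#'     lower bound ([rule_band()] on a simultaneous band).}
#'   \item{CIR}{the EST set minus the union of delta-method confidence
#'     intervals around the roots of `theta_hat` ([rule_cir()]).}
#' }
#' All are gated by the interaction pretest via [gate_by_pretest()]: without a
#' significant interaction every candidate set is empty.
#'
#' @param fit A [fit_interaction_model()] result.
#' @param domain Marker subinterval of \[0, 1\].
#' @return A [selection_set()].
#' @examples
#' set.seed(7)
#' tr <- sample_trial(scenario("linear", 0.8), 1500)
#' f <- fit_interaction_model(tr, model_spec("linear"))
#' rule_est(f)
#' rule_band(simultaneous_band(f, 0.95, draws = 2e4))
#' @export
rule_est <- function(fit, domain = c(0, 1)) {
  eb <- effect_block(fit)
  s <- selection_set(NULL, domain)
  s$intervals <- poly_sign_set(eb$g, domain)
  s
}

#' @rdname rule_est
#' @param band A `tx_band` from [pointwise_band()] or [simultaneous_band()].
#' @details Band-rule boundaries solve `(a(x)' g)^2 = c^2 a(x)' Sigma a(x)`
#'   with `a(x)' g >= 0` — a polynomial equation of degree at most 4, solved by
#'   companion-matrix root finding with bisection refinement, then
#'   sign-classified on midpoints of the induced partition.
#' @export
rule_band <- function(band, domain = c(0, 1)) {
  stopifnot(inherits(band, "tx_band"))
  band_lower_set(band$g, band$Sigma, band$critical_value, domain)
}

band_lower_set <- function(g, Sigma, crit, domain = c(0, 1)) {
  q1 <- as.numeric(g)
  q2 <- quadform_coefs(Sigma)
  h <- polyadd(polymul(q1, q1), -crit^2 * q2)
  cand <- sort(unique(c(domain,
                        poly_real_roots(h, domain),
                        poly_real_roots(q1, domain))))
  cand <- cand[c(TRUE, diff(cand) > 1e-12)]
  lower <- function(x) polyval(q1, x) - crit * sqrt(pmax(polyval(q2, x), 0))
  pieces <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(length(cand) - 1L)) {
    mid <- (cand[i] + cand[i + 1L]) / 2
    if (lower(mid) >= 0) pieces <- rbind(pieces, c(cand[i], cand[i + 1L]))
  }
  s <- selection_set(NULL, domain)
  s$intervals <- ss_normalize(pieces)
  s
}

#' @rdname rule_est
#' @param root_cis A [root_cis_delta()] result at the same level configuration.
#' @export
rule_cir <- function(fit, root_cis = NULL, level = 0.95, domain = c(0, 1)) {
  if (is.null(root_cis)) root_cis <- root_cis_delta(fit, level, domain)
  est <- rule_est(fit, domain)
  if (isTRUE(root_cis$degenerate)) {
    # root location not identified: exclude the whole domain
    return(selection_set(NULL, domain))
  }
  if (length(root_cis$roots) == 0L) return(est)
  excl <- do.call(rbind, lapply(root_cis$roots, function(r) c(r$lower, r$upper)))
  ss_difference(est, selection_set(excl, domain))
}

#' @rdname rule_est
#' @param set A [selection_set()].
#' @param significant Logical, the interaction pretest decision.
#' @param level Confidence level for the root CIs when `root_cis` is `NULL`.
#' @export
gate_by_pretest <- function(set, significant) {
  set <- as_ss(set)
  if (isTRUE(significant)) set else selection_set(NULL, set$domain)
}
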