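#' Performance of a selection set against the true scenario
#'
#' Quality measures of a single selection set `C`, computed exactly against the
#' known scenario (no resampling of future patients), with the future-patient
#' marker `X*` following the scenario's marker distribution:
#' \describe{
#'   \item{sensitivity}{`P(X* in C | theta(X*) >= 0)` — ability to select
#'     patients who can expect to benefit.}
#'   \item{specificity}{`P(X* not in C | theta(X*) < 0)` — ability to avoid
#'     recommending the new treatment to patients who cannot benefit.}
#'   \item{overall gain}{`E(theta(X*) 1[X* in C])` — change in the population
#'     mean outcome when applying the rule, weighting each selected patient by
#'     their individual (possibly negative) benefit.}
#' }
#' Conditional masses come from the exact marker CDF; the gain integral is
#' evaluated per interval by adaptive quadrature (absolute tolerance 1e-9),
#' which for these polynomial-times-piecewise-linear integrands agrees with
#' the closed form to near machine precision.
#'
#' @param set A [selection_set()] (or interval matrix).
#' @param sc A [scenario()].
#' @return A probability ([sensitivity()], [specificity()]), an expected-gain
#'   value ([overall_gain()], [max_gain()]), or a one-row data.frame
#'   ([performance_summary()]).
#' @examples
#' sc <- scenario("linear", 0.8)
#' sensitivity(selection_set(c(0.75, 1)), sc)
#' overall_gain(selection_set(c(0.5, 1)), sc)
#' max_gain(sc)
#' @export
sensitivity <- function(set, sc) {
  stopifnot(inherits(sc, "tx_scenario"))
  pos <- positive_effect_region(sc)
  den <- marker_mass(sc, pos)
  if (den <= 0) stop("sensitivity undefined: no positive-effect mass")
  marker_mass(sc, ss_intersect(as_ss(set), pos)) / den
}

#' @rdname sensitivity
#' @details With `beta = 0` the true effect is identically zero, there are no
#'   negative-effect patients, and specificity is defined as 1.
#' @export
specificity <- function(set, sc) {
  stopifnot(inherits(sc, "tx_scenario"))
  neg <- ss_complement(positive_effect_region(sc))
  den <- marker_mass(sc, neg)
  if (den <= 1e-12) return(1)
  1 - marker_mass(sc, ss_intersect(as_ss(set), neg)) / den
}

#' @rdname sensitivity
#' @export
overall_gain <- function(set, sc) {
  stopifnot(inherits(sc, "tx_scenario"))
  m <- as_ss(set)$intervals
  if (nrow(m) == 0L) return(0)
  integrand <- function(x) true_effect(sc, x) * marker_density(sc, x)
  total <- 0
  for (i in seq_len(nrow(m))) {
    lo <- m[i, 1]; hi <- m[i, 2]
    if (hi - lo < 1e-14) next
    # split at the triangular density knot so each piece is smooth
    brks <- c(lo, if (sc$marker_dist == "triangular" && lo < 1 / 3 && hi > 1 / 3) 1 / 3, hi)
    for (j in seq_len(length(brks) - 1L)) {
      total <- total + stats::integrate(integrand, brks[j], brks[j + 1L],
                                        abs.tol = 1e-9, rel.tol = 1e-9)$value
    }
  }
  total
}

#' @rdname sensitivity
#' @description `max_gain()` is the benchmark: the overall gain of the oracle
#'   set `{x : theta(x) >= 0}`, the maximal gain any rule can attain.
#' @export
max_gain <- function(sc) {
  overall_gain(positive_effect_region(sc), sc)
}

#' @rdname sensitivity
#' @export
performance_summary <- function(set, sc) {
  set <- as_ss(set)
  data.frame(sensitivity = sensitivity(set, sc),
             specificity = specificity(set, sc),
             overall_gain = overall_gain(set, sc),
             nonempty = !ss_is_empty(set))
}
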