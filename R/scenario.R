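#' Define a true-world scenario for the simulation study
#'
#' A scenario fixes the data-generating process of one simulated randomized
#' trial: the shape of the true treatment-effect function theta(x) on the
#' marker domain \[0, 1\], its steepness `beta`, the marker distribution, and
#' (optionally) a prognostic component alpha(x). The outcome model is
#' `Y = alpha(X) + theta(X) * T + eps` with `eps ~ N(0, 1)`, so `beta` is on an
#' effect-size scale.
#'
#' The three shapes are
#' \describe{
#'   \item{linear}{`theta(x) = beta * (x - 0.5)`}
#'   \item{concave}{`theta(x) = beta * (0.3 - 0.9 * (x - 1)^2)`}
#'   \item{convex}{`theta(x) = beta * (-0.3 + 0.9 * x^2)`}
#' }
#' and the marker is either uniform on \[0, 1\] or triangular on (0, 1) with
#' mode 1/3.
#'
#' @param shape One of `"linear"`, `"concave"`, `"convex"`.
#' @param beta Non-negative steepness of the effect function (effect-size scale
#'   since the error SD is 1).
#' @param marker_dist One of `"uniform"`, `"triangular"`.
#' @param alpha Optional prognostic function `x -> alpha(x)`; `NULL` means
#'   identically zero. Correctly specified analysis models are invariant to it.
#' @return An object of class `tx_scenario`.
#' @examples
#' sc <- scenario("linear", beta = 0.8)
#' true_effect(sc, c(0, 0.5, 1))
#' positive_effect_region(sc)
#' @export
scenario <- function(shape = c("linear", "concave", "convex"), beta = 1,
                     marker_dist = c("uniform", "triangular"), alpha = NULL) {
  shape <- match.arg(shape)
  marker_dist <- match.arg(marker_dist)
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0)
    stop("'beta' must be a single non-negative number")
  if (!is.null(alpha) && !is.function(alpha))
    stop("'alpha' must be NULL or a function of x")
  structure(list(shape = shape, beta = as.numeric(beta),
                 marker_dist = marker_dist, alpha = alpha),
            class = "tx_scenario")
}

#' @rdname scenario
#' @description `scenario_from_id()` maps the four canonical study scenarios to
#'   ids 1 (linear/uniform), 2 (linear/triangular), 3 (concave/uniform),
#'   4 (convex/uniform).
#' @param id Integer 1--4.
#' @export
scenario_from_id <- function(id, beta = 1) {
  id <- as.integer(id)
  if (is.na(id) || id < 1L || id > 4L) stop("scenario 'id' must be 1, 2, 3 or 4")
  switch(id,
         scenario("linear",  beta, "uniform"),
         scenario("linear",  beta, "triangular"),
         scenario("concave", beta, "uniform"),
         scenario("convex",  beta, "uniform"))
}

#' @rdname scenario
#' @description `scenario_from_config()` reads a scenario from a plain-text
#'   config: JSON, YAML (if the yaml package is installed), or simple
#'   `key: value` / `key = value` lines with keys `id` or `shape`,
#'   `beta`, `marker_dist`.
#' @param path Path to a config file.
#' @export
scenario_from_config <- function(path) {
  cfg <- read_kv_config(path)
  beta <- if (!is.null(cfg$beta)) as.numeric(cfg$beta) else 1
  if (!is.null(cfg$id)) return(scenario_from_id(cfg$id, beta))
  if (is.null(cfg$shape)) stop("config must provide 'id' or 'shape'")
  dist <- if (!is.null(cfg$marker_dist)) as.character(cfg$marker_dist) else "uniform"
  dist <- match.arg(dist, c("uniform", "triangular"))
  scenario(as.character(cfg$shape), beta, dist)
}

read_kv_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") return(jsonlite::read_json(path, simplifyVector = TRUE))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    return(yaml::read_yaml(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[:=]", fixed = FALSE)[[1]]
    if (length(kv) < 2L) stop("cannot parse config line: ", ln)
    val <- trimws(paste(kv[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    out[[trimws(kv[1])]] <- if (!is.na(num)) num else val
  }
  out
}

# ascending polynomial coefficients of theta(x) for a scenario
effect_coefs <- function(sc) {
  switch(sc$shape,
         linear  = sc$beta * c(-0.5, 1),
         concave = sc$beta * c(-0.6, 1.8, -0.9),
         convex  = sc$beta * c(-0.3, 0, 0.9))
}

check_domain <- function(x) {
  if (any(is.na(x)) || any(x < -1e-12) || any(x > 1 + 1e-12))
    stop("marker values must lie in [0, 1]")
  pmin(pmax(x, 0), 1)
}

#' True treatment-effect function theta(x)
#'
#' @param sc A [scenario()].
#' @param x Marker values in \[0, 1\] (vectorized).
#' @return `theta(x)` under the scenario's shape and steepness.
#' @export
true_effect <- function(sc, x) {
  stopifnot(inherits(sc, "tx_scenario"))
  x <- check_domain(x)
  polyval(effect_coefs(sc), x)
}

#' Marker distribution: density, CDF and quantile function
#'
#' Uniform on \[0, 1\], or triangular on (0, 1) with mode 1/3 (density `6x` on
#' \[0, 1/3\] and `3(1-x)` on \[1/3, 1\]). `marker_quantile()` is the inverse
#' CDF used for deterministic inverse-transform sampling.
#'
#' @param sc A [scenario()].
#' @param x Marker values in \[0, 1\].
#' @param p Probabilities in \[0, 1\].
#' @return Density, CDF or quantile values (vectorized).
#' @export
marker_density <- function(sc, x) {
  stopifnot(inherits(sc, "tx_scenario"))
  x <- check_domain(x)
  if (sc$marker_dist == "uniform") return(rep(1, length(x)))
  ifelse(x <= 1 / 3, 6 * x, 3 * (1 - x))
}

#' @rdname marker_density
#' @export
marker_cdf <- function(sc, x) {
  stopifnot(inherits(sc, "tx_scenario"))
  x <- check_domain(x)
  if (sc$marker_dist == "uniform") return(x)
  ifelse(x <= 1 / 3, 3 * x^2, 1 - 1.5 * (1 - x)^2)
}

#' @rdname marker_density
#' @export
marker_quantile <- function(sc, p) {
  stopifnot(inherits(sc, "tx_scenario"))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("'p' must lie in [0, 1]")
  if (sc$marker_dist == "uniform") return(p)
  ifelse(p <= 1 / 3, sqrt(p / 3), 1 - sqrt(2 * (1 - p) / 3))
}

#' Simulate one randomized trial from a scenario
#'
#' Markers are drawn i.i.d. by inverse-transform sampling from the scenario's
#' marker distribution, treatment arms i.i.d. Bernoulli(0.5), and outcomes as
#' `alpha(x) + theta(x) * t + noise_sd * N(0, 1)`. Deterministic given the RNG
#' state (`set.seed()` before calling).
#'
#' @param sc A [scenario()].
#' @param n Number of patients (>= 1).
#' @param noise_sd Error standard deviation. The study design fixes 1; other
#'   values (in particular 0) are a hook for exact-recovery tests.
#' @return A `data.frame` of class `tx_trial` with columns `marker`, `arm`,
#'   `outcome`.
#' @export
sample_trial <- function(sc, n, noise_sd = 1) {
  stopifnot(inherits(sc, "tx_scenario"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  marker <- marker_quantile(sc, stats::runif(n))
  arm <- stats::rbinom(n, 1L, 0.5)
  mu <- true_effect(sc, marker) * arm
  if (!is.null(sc$alpha)) mu <- mu + sc$alpha(marker)
  outcome <- mu + noise_sd * stats::rnorm(n)
  structure(data.frame(marker = marker, arm = arm, outcome = outcome),
            class = c("tx_trial", "data.frame"))
}

#' Region of non-negative true treatment effect
#'
#' The oracle selection set `{x in [0, 1] : theta(x) >= 0}` (closed
#' inequality). For `beta = 0` the effect is identically zero and the whole
#' domain is returned.
#'
#' @param sc A [scenario()].
#' @return A [selection_set()].
#' @export
positive_effect_region <- function(sc) {
  stopifnot(inherits(sc, "tx_scenario"))
  s <- selection_set(NULL)
  s$intervals <- poly_sign_set(effect_coefs(sc))
  s
}

#' Probability that the true effect exceeds a threshold
#'
#' `P(theta(X) >= threshold)` under the scenario's marker distribution,
#' computed exactly from the polynomial sign set and the marker CDF. Useful to
#' judge the clinical relevance of a chosen `beta` (e.g. the fraction of
#' patients with an effect above 0.2).
#'
#' @param sc A [scenario()].
#' @param threshold Effect threshold.
#' @return A probability.
#' @export
effect_exceedance_prob <- function(sc, threshold = 0) {
  stopifnot(inherits(sc, "tx_scenario"))
  coefs <- effect_coefs(sc)
  coefs[1] <- coefs[1] - threshold
  s <- selection_set(NULL)
  s$intervals <- poly_sign_set(coefs)
  marker_mass(sc, s)
}

# probability mass of a selection set under the scenario's marker distribution
marker_mass <- function(sc, set) {
  m <- as_ss(set)$intervals
  if (nrow(m) == 0L) return(0)
  sum(marker_cdf(sc, m[, 2]) - marker_cdf(sc, m[, 1]))
}

#' @export
print.tx_scenario <- function(x, ...) {
  cat(sprintf("<tx_scenario: %s theta(x), beta = %g, %s marker%s>\n",
              x$shape, x$beta, x$marker_dist,
              if (is.null(x$alpha)) "" else ", custom alpha(x)"))
  invisible(x)
}
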