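#' Configure a simulation study
#'
#' Bundles everything one full study needs: the scenario, the steepness grid,
#' the per-trial sample size, the number of replicates, confidence level(s),
#' the analysis model, the pretest level and the master seed. Defaults mirror
#' the study design this package implements: `n = 1500` (chosen so the most
#' conservative rule keeps at least 90 percent power in the linear/uniform
#' scenario at `beta = 0.8`), 2500 replicates (standard error 0.6 percent for a
#' power of 90 percent), `beta` grid `{0.4, 0.6, 0.8, 1, 1.2}`, level 0.95 and
#' a 5 percent interaction pretest.
#'
#' @param scenario_id Integer 1--4 (see [scenario_from_id()]), or a
#'   [scenario()] object used as a template whose `beta` is replaced by each
#'   grid value.
#' @param beta_grid Numeric vector of steepness values.
#' @param n Patients per trial.
#' @param replicates Replicated trials per cell.
#' @param level Confidence level for bands and root CIs.
#' @param level_grid Optional vector of levels for the `1 - gamma` sweep
#'   ([run_level_sweep()]).
#' @param analysis `"auto"` (linear truth -> linear model, curved truth ->
#'   quadratic model), `"linear"` or `"quadratic"`; misspecified pairings are
#'   allowed.
#' @param pretest_level Level of the interaction pretest.
#' @param seed Master seed; every replicate gets its own derived substream, so
#'   results are reproducible and extensible in the replicate count.
#' @param band_draws Monte Carlo draws per replicate for the sup-t critical
#'   value (20000 keeps its Monte Carlo error below ~0.02, negligible against
#'   the band width).
#' @param band_grid Grid resolution for the sup.
#' @param crit_method `"supt"` or `"tube"` backend for the simultaneous
#'   critical value.
#' @param keep_sets Keep every replicate's selection sets (needed e.g. for
#'   marker-specific inclusion frequencies).
#' @param verbose Log per-cell progress to standard error.
#' @return An object of class `tx_study_config`.
#' @export
study_config <- function(scenario_id = 1, beta_grid = c(0.4, 0.6, 0.8, 1, 1.2),
                         n = 1500, replicates = 2500, level = 0.95,
                         level_grid = NULL,
                         analysis = c("auto", "linear", "quadratic"),
                         pretest_level = 0.05, seed = 1,
                         band_draws = 20000, band_grid = 201L,
                         crit_method = c("supt", "tube"),
                         keep_sets = FALSE, verbose = FALSE) {
  analysis <- match.arg(analysis)
  crit_method <- match.arg(crit_method)
  stopifnot(replicates >= 1, n >= 1, length(beta_grid) >= 1)
  check_level(level)
  for (l in level_grid) check_level(l)
  check_level(pretest_level)
  structure(list(scenario_id = scenario_id, beta_grid = as.numeric(beta_grid),
                 n = as.integer(n), replicates = as.integer(replicates),
                 level = level, level_grid = level_grid, analysis = analysis,
                 pretest_level = pretest_level, seed = as.integer(seed),
                 band_draws = as.integer(band_draws),
                 band_grid = as.integer(band_grid),
                 crit_method = crit_method, keep_sets = isTRUE(keep_sets),
                 verbose = isTRUE(verbose)),
            class = "tx_study_config")
}

#' @rdname study_config
#' @description `study_config_from_file()` reads a config from JSON, YAML or
#'   `key: value` text; unspecified fields keep their defaults.
#' @param path Path to a config file.
#' @param ... Overrides applied on top of the file's values.
#' @export
study_config_from_file <- function(path, ...) {
  cfg <- read_kv_config(path)
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  keep <- intersect(names(cfg), names(formals(study_config)))
  do.call(study_config, cfg[keep])
}

scenario_for <- function(config, beta) {
  if (inherits(config$scenario_id, "tx_scenario")) {
    sc <- config$scenario_id
    scenario(sc$shape, beta, sc$marker_dist, sc$alpha)
  } else {
    scenario_from_id(config$scenario_id, beta)
  }
}

analysis_spec_for <- function(config, sc) {
  if (config$analysis != "auto") return(model_spec(config$analysis))
  model_spec(if (sc$shape == "linear") "linear" else "quadratic")
}

# deterministic per-replicate substream seed (< 2^31, exact in doubles)
rep_seed <- function(seed, rep_index, attempt = 0L) {
  ((seed %% 2147483647) * 1000003 + rep_index * 7919 + attempt * 104729) %% 2147483647
}

#' Run a single replicate of the study pipeline
#'
#' Samples one trial, fits the interaction model, applies the pretest, and —
#' if significant — constructs all four rules (EST, POI, SIM, CIR) at each
#' requested level, sharing the trial and the sup-t draws across levels
#' (common random numbers), then scores every set against the true scenario.
#' Deterministic given `(config$seed, rep_index)`; a singular fit (possible
#' only for pathological marker samples) is redrawn on a derived substream and
#' counted.
#'
#' @param sc The true [scenario()] (its `beta` is the cell's steepness).
#' @param config A [study_config()].
#' @param rep_index Replicate number (1-based).
#' @return A list: `metrics` (data.frame with one row per level x rule),
#'   `sets` (nested list level -> rule -> [selection_set()]), `pretest`,
#'   `degenerate_roots` (count), `redraws` (count).
#' @export
run_replicate <- function(sc, config, rep_index = 1L) {
  stopifnot(inherits(sc, "tx_scenario"), inherits(config, "tx_study_config"))
  spec <- analysis_spec_for(config, sc)
  levels <- if (is.null(config$level_grid)) config$level else config$level_grid
  fit <- NULL
  redraws <- 0L
  for (attempt in 0:9) {
    set.seed(rep_seed(config$seed, rep_index, attempt))
    trial <- sample_trial(sc, config$n)
    fit <- tryCatch(fit_interaction_model(trial, spec), error = function(e) NULL)
    if (!is.null(fit)) break
    redraws <- redraws + 1L
  }
  if (is.null(fit)) stop("singular fit in 10 consecutive redraws")
  pre <- interaction_pretest(fit, config$pretest_level)

  rules <- c("EST", "POI", "SIM", "CIR")
  sets <- list()
  degenerate <- 0L
  if (pre$significant) {
    est_set <- rule_est(fit)
    sups <- if (config$crit_method == "supt") {
      eb <- effect_block(fit)
      supt_sup_draws(eb$Sigma, fit$degree, c(0, 1),
                     config$band_draws, config$band_grid)
    }
    eb <- effect_block(fit)
    for (lv in levels) {
      c_poi <- stats::qt(1 - (1 - lv) / 2, fit$residual_df)
      c_sim <- if (config$crit_method == "supt") {
        max(stats::quantile(sups, lv, names = FALSE), c_poi)
      } else {
        max(tube_critical_value(eb$Sigma, fit$degree, lv,
                                grid_size = config$band_grid), c_poi)
      }
      rci <- root_cis_delta(fit, lv)
      if (rci$degenerate) degenerate <- degenerate + 1L
      sets[[as.character(lv)]] <- list(
        EST = est_set,
        POI = band_lower_set(eb$g, eb$Sigma, c_poi),
        SIM = band_lower_set(eb$g, eb$Sigma, c_sim),
        CIR = rule_cir(fit, rci))
    }
  } else {
    empty <- selection_set(NULL)
    for (lv in levels) {
      sets[[as.character(lv)]] <-
        stats::setNames(rep(list(empty), 4L), rules)
    }
  }

  rows <- vector("list", length(levels) * 4L)
  k <- 0L
  for (lv in levels) {
    for (rl in rules) {
      k <- k + 1L
      perf <- performance_summary(sets[[as.character(lv)]][[rl]], sc)
      rows[[k]] <- cbind(data.frame(level = lv, rule = rl), perf)
    }
  }
  list(metrics = do.call(rbind, rows), sets = sets, pretest = pre,
       degenerate_roots = degenerate, redraws = redraws)
}

#' Run a replicated simulation study
#'
#' Replicates the whole pipeline across the `beta` grid (and level grid, if
#' any), aggregating per-replicate sensitivity, specificity and overall gain
#' into expected values with Monte Carlo standard errors, and the fraction of
#' non-empty selection sets into the power of each construction. The maximal
#' possible gain per `(scenario, beta)` is attached as a benchmark. Fully
#' reproducible: each replicate has its own seed substream derived from the
#' master seed, shared across rules and levels (common random numbers).
#'
#' @param config A [study_config()].
#' @return An object of class `tx_study_result`: a list with `results` (tidy
#'   data.frame with columns scenario, beta, level, rule, metric, estimate,
#'   mc_se, replicates, seed), `benchmarks` (scenario, beta, max_gain),
#'   `counts` (redraws, degenerate root flags), `config`, and optionally
#'   `sets`.
#' @examples
#' cfg <- study_config(scenario_id = 1, beta_grid = 0.8, n = 300,
#'                     replicates = 20, band_draws = 2000, seed = 42)
#' res <- run_study(cfg)
#' subset(res$results, metric == "power")
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "tx_study_config"))
  levels <- if (is.null(config$level_grid)) config$level else config$level_grid
  rules <- c("EST", "POI", "SIM", "CIR")
  R <- config$replicates
  res_rows <- list()
  bench_rows <- list()
  counts <- list(redraws = 0L, degenerate_roots = 0L)
  all_sets <- if (config$keep_sets) list()
  for (beta in config$beta_grid) {
    sc <- scenario_for(config, beta)
    dims <- c(R, length(levels), length(rules))
    sens <- array(NA_real_, dims); spec <- array(NA_real_, dims)
    gain <- array(NA_real_, dims); nonz <- array(NA_real_, dims)
    beta_sets <- if (config$keep_sets) vector("list", R)
    for (r in seq_len(R)) {
      rep <- run_replicate(sc, config, r)
      counts$redraws <- counts$redraws + rep$redraws
      counts$degenerate_roots <- counts$degenerate_roots + rep$degenerate_roots
      m <- rep$metrics
      for (li in seq_along(levels)) for (ri in seq_along(rules)) {
        row <- m[m$level == levels[li] & m$rule == rules[ri], ]
        sens[r, li, ri] <- row$sensitivity
        spec[r, li, ri] <- row$specificity
        gain[r, li, ri] <- row$overall_gain
        nonz[r, li, ri] <- as.numeric(row$nonempty)
      }
      if (config$keep_sets) beta_sets[[r]] <- rep$sets
    }
    if (config$keep_sets) all_sets[[as.character(beta)]] <- beta_sets
    label <- scenario_label(config)
    bench_rows[[length(bench_rows) + 1L]] <-
      data.frame(scenario = label, beta = beta, max_gain = max_gain(sc))
    for (li in seq_along(levels)) for (ri in seq_along(rules)) {
      vals <- list(sensitivity = sens[, li, ri], specificity = spec[, li, ri],
                   overall_gain = gain[, li, ri], power = nonz[, li, ri])
      for (metric in names(vals)) {
        v <- vals[[metric]]
        est <- mean(v)
        se <- if (metric == "power") power_se(est, R) else stats::sd(v) / sqrt(R)
        res_rows[[length(res_rows) + 1L]] <- data.frame(
          scenario = label, beta = beta, level = levels[li],
          rule = rules[ri], metric = metric, estimate = est, mc_se = se,
          replicates = R, seed = config$seed)
      }
    }
    if (config$verbose)
      message(sprintf("cell %s beta=%g done (%d replicates, redraws=%d, degenerate_roots=%d)",
                      label, beta, R, counts$redraws, counts$degenerate_roots))
  }
  out <- list(results = do.call(rbind, res_rows),
              benchmarks = do.call(rbind, bench_rows),
              counts = counts, config = config)
  if (config$keep_sets) out$sets <- all_sets
  structure(out, class = "tx_study_result")
}

scenario_label <- function(config) {
  if (inherits(config$scenario_id, "tx_scenario")) {
    sc <- config$scenario_id
    paste0(sc$shape, "/", sc$marker_dist)
  } else {
    as.character(config$scenario_id)
  }
}

#' Sweep the confidence level of the band/CI-based rules
#'
#' Runs the study across `config$level_grid`, sharing each replicate's trial
#' data and sup draws across levels, so the EST rule (which ignores the level)
#' is exactly constant across levels and the comparison between levels is
#' paired.
#'
#' @param config A [study_config()] with a non-empty `level_grid`.
#' @return A `tx_study_result` with one block of rows per level.
#' @export
run_level_sweep <- function(config) {
  if (is.null(config$level_grid) || length(config$level_grid) == 0L)
    stop("'config$level_grid' must be a non-empty vector of levels")
  run_study(config)
}

#' Monte Carlo standard error of a power (proportion) estimate
#'
#' `sqrt(p * (1 - p) / replicates)`; e.g. a power of 0.9 estimated from 2500
#' replicates has standard error 0.006.
#'
#' @param p Estimated proportion.
#' @param replicates Number of replicates.
#' @return The binomial standard error.
#' @export
power_se <- function(p, replicates) sqrt(p * (1 - p) / replicates)

#' Write a study result as a tidy CSV plus a JSON run manifest
#'
#' @param result A `tx_study_result`.
#' @param csv Path for the tidy results CSV.
#' @param manifest Optional path for a JSON manifest recording the full
#'   configuration and package version.
#' @return `result`, invisibly.
#' @export
write_study_result <- function(result, csv, manifest = NULL) {
  stopifnot(inherits(result, "tx_study_result"))
  utils::write.csv(result$results, csv, row.names = FALSE)
  if (!is.null(manifest)) {
    cfg <- unclass(result$config)
    cfg$scenario_id <- if (inherits(cfg$scenario_id, "tx_scenario"))
      unclass(cfg$scenario_id)[c("shape", "beta", "marker_dist")] else cfg$scenario_id
    jsonlite::write_json(
      list(config = cfg,
           package = "trtselect",
           version = as.character(utils::packageVersion("trtselect")),
           counts = result$counts),
      manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(result)
}

#' @export
print.tx_study_result <- function(x, ...) {
  cat(sprintf("<tx_study_result: scenario %s, %d beta value(s), %d level(s), %d replicates>\n",
              x$results$scenario[1], length(unique(x$results$beta)),
              length(unique(x$results$level)), x$results$replicates[1]))
  wide <- x$results[x$results$metric %in% c("power", "overall_gain"), ]
  print(utils::head(wide[order(wide$beta, wide$level, wide$metric, wide$rule), ], 16),
        row.names = FALSE)
  invisible(x)
}

#' @export
print.tx_study_config <- function(x, ...) {
  cat(sprintf("<tx_study_config: scenario %s, beta {%s}, n=%d, %d replicates, level(s) %s, %s analysis, seed %d>\n",
              scenario_label(x), paste(x$beta_grid, collapse = ", "), x$n,
              x$replicates,
              paste(if (is.null(x$level_grid)) x$level else x$level_grid, collapse = ", "),
              x$analysis, x$seed))
  invisible(x)
}
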