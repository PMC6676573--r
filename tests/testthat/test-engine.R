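small_cfg <- function(...) {
  study_config(scenario_id = 1, beta_grid = 0.8, n = 300, replicates = 12,
               band_draws = 3000, seed = 99, ...)
}

test_that("replicates and whole studies are deterministic under a fixed seed", {
  cfg <- small_cfg()
  sc <- scenario_from_id(1, 0.8)
  r1 <- run_replicate(sc, cfg, 3)
  r2 <- run_replicate(sc, cfg, 3)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(ss_mat(r1$sets[["0.95"]]$SIM), ss_mat(r2$sets[["0.95"]]$SIM))
  s1 <- run_study(cfg)
  s2 <- run_study(cfg)
  expect_identical(s1$results, s2$results)
  # different replicate indices give different trials
  r3 <- run_replicate(sc, cfg, 4)
  expect_false(identical(r1$metrics, r3$metrics))
})

test_that("a non-significant pretest empties all four candidate sets", {
  cfg <- study_config(scenario_id = 1, beta_grid = 0, n = 120, replicates = 1,
                      seed = 7)
  sc <- scenario_from_id(1, 0)
  found <- FALSE
  for (i in 1:30) {
    r <- run_replicate(sc, cfg, i)
    if (!r$pretest$significant) {
      found <- TRUE
      expect_true(all(!r$metrics$nonempty))
      expect_true(all(r$metrics$specificity == 1))
      expect_true(all(r$metrics$overall_gain == 0))
      break
    }
  }
  expect_true(found)
})

test_that("per-replicate rule nesting holds inside the engine", {
  cfg <- small_cfg(keep_sets = TRUE)
  sc <- scenario_from_id(1, 0.8)
  for (i in 1:6) {
    s <- run_replicate(sc, cfg, i)$sets[["0.95"]]
    expect_lt(ss_measure(ss_difference(s$SIM, s$POI)), 1e-9)
    expect_lt(ss_measure(ss_difference(s$POI, s$EST)), 1e-9)
    expect_lt(ss_measure(ss_difference(s$CIR, s$EST)), 1e-9)
  }
})

test_that("aggregates are means of replicate values with binomial power SE", {
  res <- run_study(small_cfg())
  d <- res$results
  expect_setequal(unique(d$metric),
                  c("sensitivity", "specificity", "overall_gain", "power"))
  expect_true(all(d$estimate[d$metric %in% c("sensitivity", "specificity", "power")] >= 0))
  expect_true(all(d$estimate[d$metric %in% c("sensitivity", "specificity", "power")] <= 1))
  pw <- d[d$metric == "power", ]
  expect_equal(pw$mc_se, power_se(pw$estimate, pw$replicates))
  expect_equal(res$benchmarks$max_gain, max_gain(scenario_from_id(1, 0.8)),
               tolerance = 1e-9)
  gains <- d[d$metric == "overall_gain", ]
  expect_true(all(gains$estimate <= res$benchmarks$max_gain + 1e-9))
  expect_equal(power_se(0.9, 2500), 0.006)
})

test_that("the level sweep shares trials so EST is exactly constant across levels", {
  cfg <- study_config(scenario_id = 1, beta_grid = 0.8, n = 300,
                      replicates = 10, level_grid = c(0.8, 0.95),
                      band_draws = 3000, seed = 17)
  res <- run_level_sweep(cfg)
  d <- res$results
  for (m in unique(d$metric)) {
    est <- d[d$rule == "EST" & d$metric == m, ]
    expect_equal(est$estimate[est$level == 0.8], est$estimate[est$level == 0.95])
  }
  # conservative rules can only gain power when the level drops
  for (rl in c("POI", "SIM", "CIR")) {
    g <- d[d$rule == rl & d$metric == "overall_gain", ]
    expect_gte(g$estimate[g$level == 0.8], g$estimate[g$level == 0.95] - 1e-12)
  }
  expect_error(run_level_sweep(small_cfg()), "level_grid")
})

test_that("null scenario power matches the pretest level", {
  cfg <- study_config(scenario_id = 1, beta_grid = 0, n = 120,
                      replicates = 400, band_draws = 2000, seed = 2718)
  res <- run_study(cfg)
  pw <- res_value(res, "EST", "power", beta_ = 0)
  expect_equal(pw, 0.05, tolerance = 3 * sqrt(0.05 * 0.95 / 400) / 0.05)
  # all rules share the gate, so their powers cannot exceed the EST power
  for (rl in c("POI", "SIM", "CIR"))
    expect_lte(res_value(res, rl, "power", beta_ = 0), pw)
})

test_that("results round-trip through the tidy CSV and JSON manifest", {
  res <- run_study(small_cfg())
  csv <- withr::local_tempfile(fileext = ".csv")
  man <- withr::local_tempfile(fileext = ".json")
  write_study_result(res, csv, man)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(res$results))
  expect_equal(back$estimate, res$results$estimate, tolerance = 1e-12)
  expect_named(back, c("scenario", "beta", "level", "rule", "metric",
                       "estimate", "mc_se", "replicates", "seed"))
  manifest <- jsonlite::read_json(man, simplifyVector = TRUE)
  expect_equal(manifest$config$seed, 99)
  expect_equal(manifest$package, "trtselect")
})

test_that("study configs load from files with flag-style overrides", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"scenario_id": 3, "beta_grid": [0.6, 0.8], "n": 500, "replicates": 5, "seed": 4}', f)
  cfg <- study_config_from_file(f, replicates = 9)
  expect_equal(cfg$scenario_id, 3)
  expect_equal(cfg$beta_grid, c(0.6, 0.8))
  expect_equal(cfg$replicates, 9L)
  expect_equal(cfg$analysis, "auto")
})

test_that("misspecified analysis models are allowed and run end to end", {
  cfg <- study_config(scenario_id = 4, beta_grid = 0.8, n = 300, replicates = 4,
                      analysis = "linear", band_draws = 2000, seed = 31)
  res <- run_study(cfg)
  expect_equal(nrow(res$results), 16)
  expect_true(all(is.finite(res$results$estimate)))
})
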