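make_fit2 <- function(g, Sigma, degree = length(g) - 1L, df = 400L) {
  p <- length(g) + degree + 1L
  coefs <- c(numeric(degree + 1L), g)
  cov <- diag(1e-6, p)
  tb <- (degree + 2L):p
  cov[tb, tb] <- Sigma
  structure(list(coefficients = coefs, covariance = cov, residual_df = df,
                 treatment_block = tb, sigma2 = 1, degree = degree,
                 n = df + p), class = "tx_fit")
}

band_of <- function(fit, crit) {
  structure(list(kind = "pointwise", level = NA, critical_value = crit,
                 g = fit$coefficients[fit$treatment_block],
                 Sigma = fit$covariance[fit$treatment_block, fit$treatment_block],
                 degree = fit$degree, residual_df = fit$residual_df),
            class = "tx_band")
}

test_that("EST rule is the sign set of the estimated effect polynomial", {
  expect_equal(ss_mat(rule_est(make_fit2(c(-0.5, 1), diag(1e-4, 2)))),
               matrix(c(0.5, 1), 1))
  expect_equal(ss_mat(rule_est(make_fit2(c(-0.3, 0, 0.9), diag(1e-4, 3)))),
               matrix(c(sqrt(1 / 3), 1), 1), tolerance = 1e-9)
  expect_true(ss_is_empty(rule_est(make_fit2(c(-0.2, 0, -0.1), diag(1e-4, 3)))))
})

test_that("band rule boundary solves the band-crossing polynomial (hand case + grid oracle)", {
  f <- make_fit2(c(-0.5, 1), diag(c(0.0025, 0.0025)))
  s <- rule_band(band_of(f, 2))
  # grid sign-scan oracle for {x : theta_hat - 2 * se >= 0}
  xs <- seq(0, 1, length.out = 1e5 + 1)
  lower <- (-0.5 + xs) - 2 * sqrt(0.0025 * (1 + xs^2))
  oracle_lo <- xs[min(which(lower >= 0))]
  expect_equal(nrow(ss_mat(s)), 1)
  expect_equal(ss_mat(s)[1, 1], oracle_lo, tolerance = 2e-5)
  expect_equal(ss_mat(s)[1, 1], (1 + sqrt(0.0496)) / 1.98, tolerance = 1e-9)
  expect_equal(ss_mat(s)[1, 2], 1)
})

test_that("band rule agrees with a dense grid sign scan on random fitted models", {
  set.seed(909)
  xs <- seq(0, 1, length.out = 1e5 + 1)
  for (i in 1:10) {
    sc <- scenario(sample(c("linear", "convex", "concave"), 1), runif(1, 0.3, 1.2))
    spec <- model_spec(if (sc$shape == "linear") "linear" else "quadratic")
    f <- fit_interaction_model(sample_trial(sc, 250), spec)
    b <- pointwise_band(f, 0.9)
    s <- rule_band(b)
    member_grid <- b$lower(xs) >= 0
    inset <- rep(FALSE, length(xs))
    m <- ss_mat(s)
    for (j in seq_len(nrow(m))) inset <- inset | (xs >= m[j, 1] & xs <= m[j, 2])
    # disagreement only possible within grid resolution of each boundary
    expect_lte(sum(member_grid != inset), 2 * (nrow(m) + 1))
  }
})

test_that("zero-width bands reproduce the EST rule", {
  f <- make_fit2(c(-0.5, 1), diag(1e-18, 2))
  s <- rule_band(band_of(f, 2))
  expect_equal(ss_mat(s), matrix(c(0.5, 1), 1), tolerance = 1e-8)
})

test_that("rules nest on every replicate: SIM within POI within EST, CIR within EST", {
  set.seed(321)
  for (i in 1:15) {
    sc <- scenario(sample(c("linear", "convex", "concave"), 1),
                   runif(1, 0.4, 1.2),
                   sample(c("uniform", "triangular"), 1))
    spec <- model_spec(if (sc$shape == "linear") "linear" else "quadratic")
    f <- fit_interaction_model(sample_trial(sc, 400), spec)
    est <- rule_est(f)
    poi <- rule_band(pointwise_band(f, 0.95))
    sim <- rule_band(simultaneous_band(f, 0.95, draws = 3000))
    cir <- rule_cir(f, level = 0.95)
    expect_lt(ss_measure(ss_difference(sim, poi)), 1e-9)
    expect_lt(ss_measure(ss_difference(poi, est)), 1e-9)
    expect_lt(ss_measure(ss_difference(cir, est)), 1e-9)
    for (s in list(est, poi, sim, cir)) {
      m <- ss_mat(s)
      if (nrow(m) > 1) expect_true(all(m[-1, 1] > m[-nrow(m), 2]))
      if (nrow(m) > 0) {
        expect_true(all(m[, 1] <= m[, 2]))
        expect_true(all(m >= 0 & m <= 1))
      }
    }
  }
})

test_that("CIR excises root intervals from the EST set", {
  f <- make_fit2(c(-0.5, 1), diag(c(0.01, 0.04)))
  rci <- list(roots = list(list(root = 0.5, se = NA, lower = 0.4, upper = 0.6)),
              degenerate = FALSE)
  expect_equal(ss_mat(rule_cir(f, rci)), matrix(c(0.6, 1), 1))
  # no real roots, positive everywhere -> full domain kept
  fpos <- make_fit2(c(0.5, 0, 0.9), diag(1e-4, 3))
  expect_equal(ss_mat(rule_cir(fpos, level = 0.95)), matrix(c(0, 1), 1))
  # no real roots, negative everywhere -> empty
  fneg <- make_fit2(c(-0.5, 0, -0.9), diag(1e-4, 3))
  expect_true(ss_is_empty(rule_cir(fneg, level = 0.95)))
  # degenerate root signal -> empty set (maximally conservative)
  fdeg <- make_fit2(c(0.25, -1, 1), diag(1e-4, 3))
  expect_true(ss_is_empty(rule_cir(fdeg, level = 0.95)))
  # quadratic with two interior roots: both neighborhoods removed
  f2 <- make_fit2(c(-0.08, 0.6, -0.6), diag(1e-5, 3))  # roots ~0.155, ~0.845
  cir2 <- rule_cir(f2, level = 0.95)
  est2 <- rule_est(f2)
  xs <- seq(0, 1, length.out = 2001)
  rts <- sort(Re(polyroot(c(-0.08, 0.6, -0.6))))
  for (x in xs) {
    if (ss_contains(cir2, x, tol = 0))
      expect_true(ss_contains(est2, x) && all(abs(x - rts) > 1e-4))
  }
})

test_that("pretest gating empties every candidate set when non-significant", {
  s <- selection_set(c(0.3, 0.9))
  expect_true(ss_is_empty(gate_by_pretest(s, FALSE)))
  expect_equal(ss_mat(gate_by_pretest(s, TRUE)), ss_mat(s))
  expect_true(ss_is_empty(gate_by_pretest(selection_set(NULL), TRUE)))
})

test_that("horizontal band inversion identity links POI to root exclusion", {
  set.seed(654)
  for (i in 1:8) {
    sc <- scenario(sample(c("linear", "convex"), 1), runif(1, 0.4, 1))
    spec <- model_spec(if (sc$shape == "linear") "linear" else "quadratic")
    f <- fit_interaction_model(sample_trial(sc, 300), spec)
    b <- pointwise_band(f, 0.95)
    poi <- rule_band(b)
    est <- rule_est(f)
    inv <- invert_band_horizontally(b, 0)
    identity_set <- ss_difference(est, ss_intersect(inv, est))
    expect_lt(ss_measure(ss_difference(identity_set, poi)) +
                ss_measure(ss_difference(poi, identity_set)), 1e-8)
  }
})
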