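# Independent oracles, deliberately not sharing code with the package.

# polynomial helpers on ascending coefficients
o_polyval <- function(coefs, x) {
  sapply(x, function(xi) sum(coefs * xi^(seq_along(coefs) - 1)))
}

o_polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) for (j in seq_along(b))
    out[i + j - 1] <- out[i + j - 1] + a[i] * b[j]
  out
}

# definite integral of a polynomial
o_polyint <- function(coefs, lo, hi) {
  anti <- coefs / seq_along(coefs)
  sum(anti * hi^seq_along(coefs)) - sum(anti * lo^seq_along(coefs))
}

o_effect_coefs <- function(shape, beta) {
  switch(shape,
         linear  = beta * c(-0.5, 1),
         concave = beta * c(-0.6, 1.8, -0.9),  # beta*(0.3 - 0.9*(x-1)^2) expanded
         convex  = beta * c(-0.3, 0, 0.9))
}

# closed-form E[theta(X) 1(X in set)] for uniform / triangular(0,1,1/3) markers
o_gain <- function(shape, beta, dist, intervals) {
  th <- o_effect_coefs(shape, beta)
  total <- 0
  for (i in seq_len(nrow(intervals))) {
    lo <- intervals[i, 1]; hi <- intervals[i, 2]
    if (dist == "uniform") {
      total <- total + o_polyint(th, lo, hi)
    } else {
      l1 <- min(hi, max(lo, 1 / 3))
      if (lo < 1 / 3) total <- total + o_polyint(o_polymul(th, c(0, 6)), lo, l1)
      if (hi > 1 / 3) total <- total + o_polyint(o_polymul(th, c(3, -3)), max(lo, 1 / 3), hi)
    }
  }
  total
}

# central finite-difference gradient
o_fd_grad <- function(f, x, h = 1e-6) {
  sapply(seq_along(x), function(k) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  })
}

# pull one aggregated estimate out of a tx_study_result
res_value <- function(res, rule_, metric_, beta_ = NULL, level_ = NULL) {
  d <- res$results
  keep <- d$rule == rule_ & d$metric == metric_
  if (!is.null(beta_)) keep <- keep & abs(d$beta - beta_) < 1e-9
  if (!is.null(level_)) keep <- keep & abs(d$level - level_) < 1e-9
  stopifnot(sum(keep) == 1L)
  d$estimate[keep]
}

# intervals matrix of a selection set (for matrix-level comparisons)
ss_mat <- function(s) s$intervals
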