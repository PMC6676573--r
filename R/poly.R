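# Internal polynomial helpers. Coefficients are ascending: c0 + c1*x + c2*x^2 + ...

polyval <- function(coefs, x) {
  out <- rep(0, length(x))
  for (k in rev(seq_along(coefs))) out <- out * x + coefs[k]
  out
}

polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# pad/truncate to common length and add
polyadd <- function(a, b) {
  n <- max(length(a), length(b))
  out <- numeric(n)
  out[seq_along(a)] <- a
  out[seq_along(b)] <- out[seq_along(b)] + b
  out
}

poly_trim <- function(coefs, tol = 1e-12) {
  scale <- max(abs(coefs), 1e-300)
  keep <- which(abs(coefs) > tol * scale)
  if (length(keep) == 0L) return(numeric(0))
  coefs[seq_len(max(keep))]
}

# Real roots of a polynomial inside [domain], companion-matrix solve (polyroot)
# followed by bisection refinement where the polynomial changes sign.
poly_real_roots <- function(coefs, domain = c(0, 1), tol = 1e-10) {
  coefs <- poly_trim(coefs)
  if (length(coefs) <= 1L) return(numeric(0))
  rts <- polyroot(coefs)
  re <- Re(rts)[abs(Im(rts)) < 1e-7 * (1 + Mod(rts))]
  if (length(re) == 0L) return(numeric(0))
  re <- re[re >= domain[1] - 1e-9 & re <= domain[2] + 1e-9]
  re <- pmin(pmax(re, domain[1]), domain[2])
  f <- function(x) polyval(coefs, x)
  vapply(re, function(r) {
    h <- 1e-6
    lo <- max(domain[1], r - h)
    hi <- min(domain[2], r + h)
    if (lo < hi && sign(f(lo)) != sign(f(hi)) && f(lo) != 0) {
      stats::uniroot(f, c(lo, hi), tol = tol)$root
    } else r
  }, numeric(1))
}

# {x in domain : p(x) >= 0} as an interval matrix (closed-set convention;
# isolated touch points of a non-negative-at-root polynomial are kept).
poly_sign_set <- function(coefs, domain = c(0, 1)) {
  coefs <- poly_trim(coefs)
  if (length(coefs) == 0L) return(matrix(domain, ncol = 2))      # p identically 0
  if (length(coefs) == 1L) {
    if (coefs >= 0) return(matrix(domain, ncol = 2))
    return(matrix(numeric(0), ncol = 2))
  }
  rts <- poly_real_roots(coefs, domain)
  brk <- sort(unique(c(domain, rts)))
  brk <- brk[c(TRUE, diff(brk) > 1e-12)]
  pieces <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(length(brk) - 1L)) {
    mid <- (brk[i] + brk[i + 1L]) / 2
    if (polyval(coefs, mid) >= 0) pieces <- rbind(pieces, c(brk[i], brk[i + 1L]))
  }
  # isolated roots (double roots of a locally negative polynomial) stay in the set
  for (r in rts) {
    inside <- nrow(pieces) > 0 &&
      any(r >= pieces[, 1] - 1e-12 & r <= pieces[, 2] + 1e-12)
    if (!inside) pieces <- rbind(pieces, c(r, r))
  }
  pieces
}
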