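#' Selection sets: finite unions of closed marker intervals
#'
#' A treatment selection rule recommends the new treatment on a subset C of the
#' marker domain \[0, 1\]. All rules in this package produce finite unions of
#' disjoint closed intervals, represented by a `selection_set` object: a matrix
#' of `[lo, hi]` rows, ordered and non-overlapping. Degenerate single-point
#' intervals (`lo == hi`) are allowed; they carry no probability mass but are
#' kept so that closed-set identities hold exactly.
#'
#' @param intervals A k x 2 numeric matrix (or a length-2 vector, or `NULL` for
#'   the empty set) of interval endpoints. Intervals are clipped to `domain`,
#'   sorted and merged.
#' @param domain Length-2 numeric, the marker domain (default `c(0, 1)`).
#' @return An object of class `selection_set`.
#' @examples
#' s <- selection_set(rbind(c(0.6, 1), c(0.2, 0.4)))
#' ss_measure(s)
#' ss_complement(s)
#' @export
selection_set <- function(intervals = NULL, domain = c(0, 1)) {
  if (is.null(intervals) || length(intervals) == 0L) {
    m <- matrix(numeric(0), ncol = 2)
  } else {
    if (is.numeric(intervals) && is.null(dim(intervals))) {
      if (length(intervals) != 2L) stop("'intervals' vector must have length 2")
      intervals <- matrix(intervals, ncol = 2)
    }
    m <- as.matrix(intervals)
    if (ncol(m) != 2L) stop("'intervals' must have two columns (lo, hi)")
    if (any(is.na(m))) stop("'intervals' must not contain NA")
    if (any(m[, 1] > m[, 2] + 1e-12)) stop("interval with lo > hi")
    m[, 1] <- pmax(pmin(m[, 1], m[, 2]), domain[1])
    m[, 2] <- pmin(pmax(m[, 2], m[, 1]), domain[2])
    # drop intervals entirely outside the domain
    m <- m[m[, 1] <= domain[2] & m[, 2] >= domain[1], , drop = FALSE]
    m <- ss_normalize(m)
  }
  structure(list(intervals = m, domain = as.numeric(domain)),
            class = "selection_set")
}

# merge sorted, touching or overlapping intervals
ss_normalize <- function(m, tol = 1e-12) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in 2:nrow(m)) {
    j <- nrow(out)
    if (m[i, 1] <= out[j, 2] + tol) {
      out[j, 2] <- max(out[j, 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

as_ss <- function(x, domain = c(0, 1)) {
  if (inherits(x, "selection_set")) x else selection_set(x, domain)
}

#' @rdname selection_set
#' @param x,a,b `selection_set` objects (or interval matrices).
#' @export
ss_is_empty <- function(x) nrow(as_ss(x)$intervals) == 0L

#' @rdname selection_set
#' @export
ss_measure <- function(x) {
  m <- as_ss(x)$intervals
  if (nrow(m) == 0L) return(0)
  sum(m[, 2] - m[, 1])
}

#' @rdname selection_set
#' @export
ss_union <- function(a, b) {
  a <- as_ss(a); b <- as_ss(b)
  selection_set(rbind(a$intervals, b$intervals), a$domain)
}

#' @rdname selection_set
#' @export
ss_intersect <- function(a, b) {
  a <- as_ss(a); b <- as_ss(b)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(a$intervals))) {
    for (j in seq_len(nrow(b$intervals))) {
      lo <- max(a$intervals[i, 1], b$intervals[j, 1])
      hi <- min(a$intervals[i, 2], b$intervals[j, 2])
      if (lo <= hi) out <- rbind(out, c(lo, hi))
    }
  }
  s <- selection_set(NULL, a$domain)
  s$intervals <- ss_normalize(out)
  s
}

#' @rdname selection_set
#' @param domain Length-2 numeric domain for the complement.
#' @export
ss_complement <- function(x, domain = NULL) {
  x <- as_ss(x)
  if (is.null(domain)) domain <- x$domain
  m <- x$intervals
  if (nrow(m) == 0L) return(selection_set(domain, domain))
  edges <- c(domain[1], as.vector(t(m)), domain[2])
  out <- matrix(edges, ncol = 2, byrow = TRUE)
  out <- out[out[, 2] - out[, 1] > 1e-12, , drop = FALSE]  # complement drops touch points
  s <- selection_set(NULL, domain)
  s$intervals <- out
  s
}

#' @rdname selection_set
#' @export
ss_difference <- function(a, b) {
  a <- as_ss(a)
  ss_intersect(a, ss_complement(b, a$domain))
}

#' @rdname selection_set
#' @param point Numeric scalar to test for membership.
#' @param tol Membership tolerance.
#' @export
ss_contains <- function(x, point, tol = 1e-9) {
  m <- as_ss(x)$intervals
  if (nrow(m) == 0L) return(FALSE)
  any(point >= m[, 1] - tol & point <= m[, 2] + tol)
}

#' @export
print.selection_set <- function(x, ...) {
  m <- x$intervals
  if (nrow(m) == 0L) {
    cat("<selection_set: empty>\n")
  } else {
    cat(sprintf("<selection_set: %d interval(s), measure %.4f>\n",
                nrow(m), ss_measure(x)))
    for (i in seq_len(nrow(m)))
      cat(sprintf("  [%.6g, %.6g]\n", m[i, 1], m[i, 2]))
  }
  invisible(x)
}

#' @rdname selection_set
#' @description `ss_to_json()` serializes a selection set to a JSON list of
#'   `[lo, hi]` pairs, the on-disk form used in result files.
#' @export
ss_to_json <- function(x) {
  m <- as_ss(x)$intervals
  jsonlite::toJSON(unname(lapply(seq_len(nrow(m)), function(i) m[i, ])),
                   digits = NA)
}
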