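# Exact rational arithmetic kernel.
#
# Rationals are stored as pairs of integer-valued doubles (numerator,
# denominator) kept reduced at every step.  IEEE doubles represent integers
# exactly up to 2^53; every product and sum is guarded so that a computation
# whose intermediates would leave the exactly-representable range aborts
# instead of silently rounding.  All geometric decisions in this package
# (ranks, dimensions, supports, LP verdicts) go through this kernel: there are
# no epsilon comparisons anywhere.

.RQ_LIMIT <- 2^51

.rq_check <- function(...) {
  for (x in list(...)) {
    if (any(abs(x) >= .RQ_LIMIT, na.rm = TRUE))
      stop("exact-arithmetic overflow: intermediate integer exceeded 2^51; ",
           "the instance is too large for the double-based rational kernel",
           call. = FALSE)
  }
  invisible(NULL)
}

# vectorized Euclid; gcd(a, 0) = |a|, gcd(0, 0) = 0
.gcdv <- function(a, b) {
  len <- max(length(a), length(b))
  a <- rep_len(abs(a), len)
  b <- rep_len(abs(b), len)
  while (any(b > 0)) {
    r <- ifelse(b > 0, a %% b, 0)
    a <- ifelse(b > 0, b, a)
    b <- r
  }
  a
}

.lcmv <- function(a, b) {
  g <- .gcdv(a, b)
  out <- ifelse(g > 0, (a / g) * b, 0)
  .rq_check(out)
  abs(out)
}

# normalize: denominator positive, fraction reduced, zero is 0/1
.rq_norm <- function(n, d) {
  if (any(d == 0)) stop("zero denominator in rational number", call. = FALSE)
  s <- ifelse(d < 0, -1, 1)
  n <- n * s
  d <- d * s
  g <- .gcdv(n, d)
  g[g == 0] <- 1
  n <- n / g
  d <- d / g
  d[n == 0] <- 1
  n[n == 0] <- 0 # clears -0
  list(n = n, d = d)
}

rq_add <- function(n1, d1, n2, d2) {
  g <- .gcdv(d1, d2)
  g[g == 0] <- 1
  m1 <- d2 / g
  m2 <- d1 / g
  p1 <- n1 * m1
  p2 <- n2 * m2
  d <- d1 * m1
  .rq_check(p1, p2, d)
  n <- p1 + p2
  .rq_check(n)
  .rq_norm(n, d)
}

rq_sub <- function(n1, d1, n2, d2) rq_add(n1, d1, -n2, d2)

rq_mul <- function(n1, d1, n2, d2) {
  g1 <- .gcdv(n1, d2); g1[g1 == 0] <- 1
  g2 <- .gcdv(n2, d1); g2[g2 == 0] <- 1
  n <- (n1 / g1) * (n2 / g2)
  d <- (d1 / g2) * (d2 / g1)
  .rq_check(n, d)
  .rq_norm(n, d)
}

rq_div <- function(n1, d1, n2, d2) {
  if (any(n2 == 0)) stop("division by zero rational", call. = FALSE)
  rq_mul(n1, d1, d2, n2)
}

# sign of n1/d1 - n2/d2 (denominators positive)
rq_cmp <- function(n1, d1, n2, d2) {
  p1 <- n1 * d2
  p2 <- n2 * d1
  .rq_check(p1, p2)
  sign(p1 - p2)
}

# ---- parsing and formatting ------------------------------------------------

# parse a single value (numeric or string) to an exact rational
.parse_rational_one <- function(x) {
  if (is.numeric(x)) {
    if (!is.finite(x) || x != round(x))
      stop("numeric entries must be integer-valued; encode non-integers as ",
           "\"p/q\" or decimal strings for exactness", call. = FALSE)
    .rq_check(x)
    return(c(x, 1))
  }
  s <- trimws(as.character(x))
  if (grepl("^[+-]?[0-9]+$", s)) {
    v <- as.numeric(s)
    .rq_check(v)
    return(c(v, 1))
  }
  if (grepl("^[+-]?[0-9]+/[0-9]+$", s)) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    n <- as.numeric(parts[1]); d <- as.numeric(parts[2])
    .rq_check(n, d)
    if (d == 0) stop("zero denominator in '", s, "'", call. = FALSE)
    r <- .rq_norm(n, d)
    return(c(r$n, r$d))
  }
  if (grepl("^[+-]?[0-9]*\\.[0-9]+$", s)) {
    sgn <- if (startsWith(s, "-")) -1 else 1
    s2 <- sub("^[+-]", "", s)
    parts <- strsplit(s2, ".", fixed = TRUE)[[1]]
    int <- if (nzchar(parts[1])) as.numeric(parts[1]) else 0
    frac <- parts[2]
    den <- 10^nchar(frac)
    num <- sgn * (int * den + as.numeric(frac))
    .rq_check(num, den)
    r <- .rq_norm(num, den)
    return(c(r$n, r$d))
  }
  stop("cannot parse '", s, "' as an exact rational (use integers, \"p/q\" ",
       "or plain decimal strings)", call. = FALSE)
}

# parse a vector of numbers/strings into an rq vector (list with $n, $d)
as_rq <- function(x) {
  if (is.list(x) && !is.null(x$n) && !is.null(x$d)) return(x)
  vals <- vapply(x, .parse_rational_one, numeric(2))
  list(n = unname(vals[1, ]), d = unname(vals[2, ]))
}

rq_format <- function(n, d) ifelse(d == 1, format(n, scientific = FALSE),
                                   paste0(n, "/", d))

# ---- rational matrices -----------------------------------------------------

# rq matrices are lists with $n, $d numeric matrices of equal dim
rq_mat <- function(n, d = NULL) {
  if (is.null(d)) d <- array(1, dim(n))
  r <- .rq_norm(as.numeric(n), as.numeric(d))
  list(n = array(r$n, dim(n)), d = array(r$d, dim(n)))
}

rq_mat_from_rows <- function(rows) {
  # rows: list of rq vectors of equal length
  n <- do.call(rbind, lapply(rows, `[[`, "n"))
  d <- do.call(rbind, lapply(rows, `[[`, "d"))
  list(n = n, d = d)
}

# clear denominators row-wise -> integer matrix (same rank / nullspace)
rq_mat_clear_denominators <- function(M) {
  n <- M$n; d <- M$d
  if (nrow(n) == 0) return(n)
  out <- matrix(0, nrow(n), ncol(n))
  for (i in seq_len(nrow(n))) {
    l <- Reduce(.lcmv, d[i, ], accumulate = FALSE)
    if (length(d[i, ]) == 0 || l == 0) l <- 1
    row <- n[i, ] * (l / d[i, ])
    .rq_check(row)
    out[i, ] <- row
  }
  out
}

# ---- integer rank via fraction-free (Bareiss) elimination ------------------

# rank of an integer matrix, exact; entries are guarded minors
int_rank <- function(M) {
  M <- as.matrix(M)
  if (any(M != round(M))) stop("int_rank requires an integer matrix")
  m <- nrow(M); k <- ncol(M)
  if (m == 0 || k == 0) return(0L)
  prev <- 1
  r <- 0L
  row <- 1L
  for (col in seq_len(k)) {
    piv <- which(M[row:m, col] != 0)
    if (length(piv) == 0) next
    p <- piv[1] + row - 1L
    if (p != row) M[c(row, p), ] <- M[c(p, row), ]
    if (row < m) {
      idx <- (row + 1L):m
      a <- M[row, col]
      prod1 <- M[idx, , drop = FALSE] * a
      prod2 <- outer(M[idx, col], M[row, ])
      .rq_check(prod1, prod2)
      newrows <- (prod1 - prod2) / prev
      if (any(newrows != round(newrows)))
        stop("internal error: non-exact Bareiss division")
      .rq_check(newrows)
      M[idx, ] <- newrows
    }
    prev <- M[row, col]
    r <- r + 1L
    row <- row + 1L
    if (row > m) break
  }
  r
}

# rank of an rq matrix
rq_rank <- function(M) {
  if (nrow(M$n) == 0 || ncol(M$n) == 0) return(0L)
  int_rank(rq_mat_clear_denominators(M))
}

# ---- rational RREF / nullspace / linear solve ------------------------------

# reduced row echelon form with exact rational arithmetic
rq_rref <- function(M) {
  n <- M$n; d <- M$d
  m <- nrow(n); k <- ncol(n)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(k)) {
    if (row > m) break
    cand <- which(n[row:m, col] != 0)
    if (length(cand) == 0) next
    p <- cand[1] + row - 1L
    if (p != row) {
      n[c(row, p), ] <- n[c(p, row), ]
      d[c(row, p), ] <- d[c(p, row), ]
    }
    # scale pivot row to leading 1
    sc <- rq_div(1, 1, n[row, col], d[row, col])
    r <- rq_mul(n[row, ], d[row, ], sc$n, sc$d)
    n[row, ] <- r$n; d[row, ] <- r$d
    # eliminate in all other rows
    for (i in seq_len(m)) {
      if (i == row || n[i, col] == 0) next
      f <- list(n = n[i, col], d = d[i, col])
      pr <- rq_mul(n[row, ], d[row, ], f$n, f$d)
      r <- rq_sub(n[i, ], d[i, ], pr$n, pr$d)
      n[i, ] <- r$n; d[i, ] <- r$d
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(n = n, d = d, pivots = pivots)
}

# scale a rational vector to primitive integer form: clear denominators,
# divide by gcd, sign so the first nonzero entry is positive
rq_primitive <- function(v) {
  n <- v$n; d <- v$d
  nz <- which(n != 0)
  if (length(nz) == 0) return(rep(0, length(n)))
  l <- Reduce(.lcmv, d[nz])
  x <- n * (l / d)
  .rq_check(x)
  g <- Reduce(.gcdv, abs(x[nz]))
  x <- x / g
  if (x[nz[1]] < 0) x <- -x
  x[x == 0] <- 0 # clear negative zeros introduced by the sign flip
  x
}

# basis of {x | Mx = 0} as a list of primitive integer vectors
rq_nullspace <- function(M) {
  k <- ncol(M$n)
  if (k == 0) return(list())
  R <- rq_rref(M)
  piv <- R$pivots
  free <- setdiff(seq_len(k), piv)
  lapply(free, function(j) {
    xn <- rep(0, k); xd <- rep(1, k)
    xn[j] <- 1
    if (length(piv) > 0) {
      r <- rq_sub(0, 1, R$n[seq_along(piv), j], R$d[seq_along(piv), j])
      xn[piv] <- r$n; xd[piv] <- r$d
    }
    rq_primitive(list(n = xn, d = xd))
  })
}

# solve Mx = b exactly; returns list(status = "unique"/"multiple"/
# "inconsistent", x = rq vector (a particular solution), free = free columns)
rq_solve <- function(M, bn, bd = rep(1, length(bn))) {
  k <- ncol(M$n)
  aug <- list(n = cbind(M$n, bn), d = cbind(M$d, bd))
  R <- rq_rref(aug)
  piv <- R$pivots
  if ((k + 1) %in% piv)
    return(list(status = "inconsistent", x = NULL, free = integer(0)))
  free <- setdiff(seq_len(k), piv)
  xn <- rep(0, k); xd <- rep(1, k)
  if (length(piv) > 0) {
    xn[piv] <- R$n[seq_along(piv), k + 1]
    xd[piv] <- R$d[seq_along(piv), k + 1]
  }
  list(status = if (length(free) == 0) "unique" else "multiple",
       x = list(n = xn, d = xd), free = free)
}

# numeric (double) view of an rq vector, for display only
rq_to_double <- function(v) v$n / v$d
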