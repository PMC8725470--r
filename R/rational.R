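# Exact rational linear algebra for integer matrices.
#
# Rank decisions drive the whole pipeline (lambda = N - s selects how many
# conservation laws exist), so rank, RREF, nullspaces and small determinants
# are computed over the rationals with numerator/denominator arithmetic,
# never with floating-point pivoting.  Entries of the inputs are small
# integers, so doubles hold the numerators/denominators exactly.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

gcd_vec <- function(v) Reduce(gcd2, abs(v[v != 0]), 0)

lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  abs(a / gcd2(a, b) * b)
}

rat_reduce <- function(num, den) {
  stopifnot(all(den != 0))
  g <- mapply(gcd2, num, den)
  g[g == 0] <- 1
  num <- num / g; den <- den / g
  sgn <- sign(den)
  list(num = num * sgn, den = den * sgn)
}

# Row-reduced echelon form of a matrix of integers (or rationals supplied as
# num/den), exact.  Returns list(num, den, pivots, rank).
rat_rref <- function(M, den = NULL) {
  num <- matrix(as.numeric(M), nrow(M), ncol(M))
  den <- if (is.null(den)) matrix(1, nrow(M), ncol(M)) else
    matrix(as.numeric(den), nrow(M), ncol(M))
  n <- nrow(num); m <- ncol(num)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(m)) {
    if (row > n) break
    pr <- which(num[row:n, col] != 0)
    if (length(pr) == 0L) next
    pr <- pr[1L] + row - 1L
    if (pr != row) {
      num[c(row, pr), ] <- num[c(pr, row), ]
      den[c(row, pr), ] <- den[c(pr, row), ]
    }
    # normalize pivot row to leading 1
    pn <- num[row, col]; pd <- den[row, col]
    r <- rat_reduce(num[row, ] * pd, den[row, ] * pn)
    num[row, ] <- r$num; den[row, ] <- r$den
    for (i in seq_len(n)) {
      if (i == row || num[i, col] == 0) next
      # row_i <- row_i - (num_i,col/den_i,col) * row_row
      fn <- num[i, col]; fd <- den[i, col]
      new_num <- num[i, ] * fd * den[row, ] - fn * den[i, ] * num[row, ]
      new_den <- den[i, ] * fd * den[row, ]
      r <- rat_reduce(new_num, new_den)
      num[i, ] <- r$num; den[i, ] <- r$den
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(num = num, den = den, pivots = pivots, rank = length(pivots))
}

rat_rank <- function(M) rat_rref(M)$rank

# Exact basis of the (right) nullspace of an integer matrix, columns scaled
# to integers with gcd 1.  Returns a matrix with ncol = dim of nullspace.
rat_nullspace_int <- function(M) {
  m <- ncol(M)
  rr <- rat_rref(M)
  free <- setdiff(seq_len(m), rr$pivots)
  basis <- matrix(0, m, length(free))
  for (jf in seq_along(free)) {
    col <- free[jf]
    v_num <- numeric(m); v_den <- rep(1, m)
    v_num[col] <- 1
    for (ip in seq_along(rr$pivots)) {
      v_num[rr$pivots[ip]] <- -rr$num[ip, col]
      v_den[rr$pivots[ip]] <- rr$den[ip, col]
    }
    L <- Reduce(lcm2, v_den, 1)
    v <- v_num * (L / v_den)
    g <- gcd_vec(v)
    if (g > 0) v <- v / g
    basis[, jf] <- v
  }
  basis
}

# Integer determinant by fraction-free (Bareiss) elimination; exact for
# integer input of moderate size.
int_det <- function(M) {
  n <- nrow(M)
  stopifnot(n == ncol(M))
  A <- matrix(as.numeric(M), n, n)
  sign <- 1
  prev <- 1
  for (k in seq_len(n - 1L)) {
    if (A[k, k] == 0) {
      swap <- which(A[(k + 1L):n, k] != 0)
      if (length(swap) == 0L) return(0)
      swap <- swap[1L] + k
      A[c(k, swap), ] <- A[c(swap, k), ]
      sign <- -sign
    }
    for (i in (k + 1L):n) {
      for (j in (k + 1L):n) {
        A[i, j] <- (A[i, j] * A[k, k] - A[i, k] * A[k, j]) / prev
      }
      A[i, k] <- 0
    }
    prev <- A[k, k]
  }
  sign * A[n, n]
}

# Adjugate of a small integer matrix via cofactor determinants (exact).
int_adjugate <- function(M) {
  n <- nrow(M)
  if (n == 1L) return(matrix(1, 1L, 1L))
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      minor <- M[-i, -j, drop = FALSE]
      adj[j, i] <- (-1) ^ (i + j) * int_det(minor)
    }
  }
  adj
}

# Scale a nonnegative rational vector to integers: divide by the smallest
# nonzero entry, clear residual denominators, reduce by the gcd.
#' Scale a nonnegative vector to a minimal integer vector
#'
#' Divides by the smallest nonzero entry, clears remaining denominators and
#' reduces by the greatest common divisor, so the result is the shortest
#' integer vector proportional to the input. Used to normalize
#' conservation-law basis vectors.
#'
#' @param v nonnegative numeric vector, not identically zero
#' @param max_den largest denominator tried when rationalizing entries
#' @return integer-valued numeric vector proportional to `v` with gcd 1
#' @export
integer_scale <- function(v, max_den = 10000L) {
  if (all(v == 0)) stop("cannot scale the zero vector")
  if (any(v < 0)) stop("integer_scale expects a nonnegative vector")
  v <- v / min(v[v > 0])
  # rationalize each entry with a bounded continued-fraction expansion
  fr <- lapply(v, rationalize, max_den = max_den)
  dens <- vapply(fr, `[[`, numeric(1), "den")
  L <- Reduce(lcm2, dens, 1)
  ints <- vapply(fr, `[[`, numeric(1), "num") * (L / dens)
  g <- gcd_vec(ints)
  if (g > 0) ints <- ints / g
  ints
}

# best rational approximation num/den with den <= max_den
rationalize <- function(x, max_den = 10000L, tol = 1e-9) {
  if (abs(x - round(x)) < tol) return(list(num = round(x), den = 1))
  # continued fraction
  a <- floor(x); frac <- x - a
  h1 <- 1; h0 <- a; k1 <- 0; k0 <- 1
  while (k0 <= max_den) {
    if (abs(h0 / k0 - x) < tol) break
    if (frac < 1e-15) break
    r <- 1 / frac
    a <- floor(r); frac <- r - a
    h <- a * h0 + h1; k <- a * k0 + k1
    h1 <- h0; h0 <- h; k1 <- k0; k0 <- k
  }
  if (abs(h0 / k0 - x) >= tol * max(1, abs(x)))
    stop("entry ", x, " is not close to a rational with denominator <= ",
         max_den)
  list(num = h0, den = k0)
}
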