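# Exact rational linear algebra on small integer matrices.
#
# All inputs in this package are stoichiometric-type matrices with entries in
# {-1, 0, 1} (occasionally small integers), and the quantities derived from
# them -- ranks, conservation-law bases, solutions of S^T b = w -- are exact
# integer/rational objects.  Floating-point elimination would force tolerance
# choices that the theory does not have, so ranks and solves are done over Q,
# with rationals held as reduced numerator/denominator pairs in doubles.
# Numerators never grow beyond a few hundred for the matrix sizes handled here
# (d <= ~15), far below 2^53, so double arithmetic is exact.

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

gcd_vec <- function(x) {
  g <- 0
  for (v in x) {
    g <- gcd_int(g, v)
    if (g == 1) break
  }
  g
}

# reduce num/den in place; den kept positive, zero stored as 0/1
rat_reduce <- function(num, den) {
  stopifnot(all(den != 0))
  s <- ifelse(den < 0, -1, 1)
  num <- num * s
  den <- den * s
  for (i in seq_along(num)) {
    if (num[i] == 0) {
      den[i] <- 1
    } else {
      g <- gcd_int(num[i], den[i])
      num[i] <- num[i] / g
      den[i] <- den[i] / g
    }
  }
  list(num = num, den = den)
}

# Reduced row echelon form over the rationals.
# A: integer matrix.  Returns list(num, den, pivots, rank).
rref_rational <- function(A) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  num <- matrix(as.numeric(A), m, n)
  den <- matrix(1, m, n)
  pivots <- integer(0)
  r <- 1L
  for (col in seq_len(n)) {
    if (r > m) break
    piv <- which(num[r:m, col] != 0)
    if (length(piv) == 0) next
    piv <- piv[1] + r - 1L
    if (piv != r) {
      tmp <- num[r, ]; num[r, ] <- num[piv, ]; num[piv, ] <- tmp
      tmp <- den[r, ]; den[r, ] <- den[piv, ]; den[piv, ] <- tmp
    }
    # scale pivot row to leading 1: multiply by den[r,col]/num[r,col]
    pn <- num[r, col]; pd <- den[r, col]
    rr <- rat_reduce(num[r, ] * pd, den[r, ] * pn)
    num[r, ] <- rr$num; den[r, ] <- rr$den
    # eliminate the pivot column from all other rows
    for (i in seq_len(m)) {
      if (i == r || num[i, col] == 0) next
      fn <- num[i, col]; fd <- den[i, col]
      # row_i <- row_i - (fn/fd) * row_r
      new_num <- num[i, ] * fd * den[r, ] - fn * num[r, ] * den[i, ]
      new_den <- den[i, ] * fd * den[r, ]
      rr <- rat_reduce(new_num, new_den)
      num[i, ] <- rr$num; den[i, ] <- rr$den
    }
    pivots <- c(pivots, col)
    r <- r + 1L
  }
  list(num = num, den = den, pivots = pivots, rank = length(pivots))
}

# exact rank of an integer matrix
rank_rational <- function(A) {
  if (length(A) == 0) return(0L)
  rref_rational(A)$rank
}

# Exact solve of the (generally overdetermined) system A x = b with integer
# A, b.  Returns the unique rational solution as a numeric vector when the
# system is consistent and A has full column rank; NULL when inconsistent.
# Stops if the solution is not unique.
solve_rational <- function(A, b) {
  A <- as.matrix(A)
  aug <- cbind(A, b)
  rr <- rref_rational(aug)
  n <- ncol(A)
  if ((n + 1L) %in% rr$pivots) return(NULL)        # inconsistent
  if (rr$rank < n) stop("system is underdetermined; solution not unique")
  x <- numeric(n)
  for (i in seq_len(rr$rank)) {
    col <- rr$pivots[i]
    x[col] <- rr$num[i, n + 1L] / rr$den[i, n + 1L]
  }
  x
}

# Integer basis of the null space {x : A x = 0} of an integer matrix, each
# basis vector scaled to integer entries with gcd 1 and positive leading
# (first nonzero) coefficient.  Basis vectors follow the free columns of the
# RREF in order, giving a reproducible canonical basis.
nullspace_rational <- function(A) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (nrow(A) == 0 || n == 0) {
    return(lapply(seq_len(n), function(j) { v <- numeric(n); v[j] <- 1; v }))
  }
  rr <- rref_rational(A)
  free <- setdiff(seq_len(n), rr$pivots)
  basis <- vector("list", length(free))
  for (idx in seq_along(free)) {
    j <- free[idx]
    # free variable j = 1, other free variables 0
    num <- numeric(n); den <- rep(1, n)
    num[j] <- 1
    for (i in seq_along(rr$pivots)) {
      col <- rr$pivots[i]
      num[col] <- -rr$num[i, j]
      den[col] <- rr$den[i, j]
    }
    scale <- 1
    for (d in unique(den)) scale <- scale * d / gcd_int(scale, d)
    v <- num * (scale / den)
    g <- gcd_vec(v)
    if (g > 0) v <- v / g
    lead <- v[which(v != 0)[1]]
    if (!is.na(lead) && lead < 0) v <- -v
    basis[[idx]] <- v
  }
  basis
}
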