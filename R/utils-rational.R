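# Exact rational linear algebra for small stoichiometric matrices.
#
# Stoichiometric coefficients are short decimals (1, 2, 0.6, 2.5, ...), so an
# exact rank and an exact integer basis of the left null space can be obtained
# by Gauss-Jordan elimination over the rationals.  Rationals are held as
# num/den pairs of doubles; all intermediate values stay far below 2^53 for
# matrices of this size, and every entry is gcd-reduced after each update.

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    t <- b
    b <- ifelse(b > 0, a %% b, 0)
    a <- ifelse(t > 0, t, a)
  }
  a
}

lcm_int <- function(a, b) {
  z <- a == 0 | b == 0
  out <- abs(a * b) / pmax(gcd_int(a, b), 1)
  out[z] <- 0
  out
}

# smallest-denominator rational representation of a numeric matrix
.rationalize <- function(x, max_den = 10000L, tol = 1e-9) {
  num <- x; den <- x; den[] <- 1
  todo <- which(x != round(x))
  for (i in todo) {
    d <- 2L
    while (d <= max_den && abs(x[i] * d - round(x[i] * d)) > tol * d) d <- d + 1L
    if (d > max_den)
      stop("cannot represent coefficient ", x[i], " as a small rational")
    num[i] <- round(x[i] * d); den[i] <- d
  }
  list(num = num, den = den)
}

.rat_reduce <- function(num, den) {
  g <- pmax(gcd_int(num, den), 1)
  num <- num / g; den <- den / g
  s <- den < 0
  num[s] <- -num[s]; den[s] <- -den[s]
  list(num = num, den = den)
}

# reduced row echelon form over the rationals; returns pivot columns and rank
.rat_rref <- function(num, den) {
  m <- nrow(num); n <- ncol(num)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    sel <- which(num[row:m, col] != 0)
    if (!length(sel)) next
    pr <- row + sel[1L] - 1L
    if (pr != row) {
      num[c(row, pr), ] <- num[c(pr, row), ]
      den[c(row, pr), ] <- den[c(pr, row), ]
    }
    # scale pivot row to 1
    pn <- num[row, col]; pd <- den[row, col]
    r <- .rat_reduce(num[row, ] * pd, den[row, ] * pn)
    num[row, ] <- r$num; den[row, ] <- r$den
    # eliminate other rows
    for (i in seq_len(m)) {
      if (i == row || num[i, col] == 0) next
      fn <- num[i, col]; fd <- den[i, col]
      nn <- num[i, ] * fd * den[row, ] - fn * num[row, ] * den[i, ]
      dd <- den[i, ] * fd * den[row, ]
      r <- .rat_reduce(nn, dd)
      num[i, ] <- r$num; den[i, ] <- r$den
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(num = num, den = den, pivots = pivots, rank = length(pivots))
}

# exact rank of a numeric matrix with small rational entries
rational_rank <- function(A) {
  r <- .rationalize(A)
  .rat_rref(r$num, r$den)$rank
}

# Integer basis of the left null space of A (vectors g with g %*% A = 0),
# one vector per column; entries scaled to the smallest integers with the
# first nonzero entry positive.
rational_left_null <- function(A) {
  At <- .rationalize(t(A))
  rr <- .rat_rref(At$num, At$den)
  n <- ncol(At$num)
  free <- setdiff(seq_len(n), rr$pivots)
  if (!length(free)) return(matrix(0, nrow(A), 0))
  G <- matrix(0, n, length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    gn <- numeric(n); gd <- rep(1, n)
    gn[f] <- 1
    for (i in seq_along(rr$pivots)) {
      gn[rr$pivots[i]] <- -rr$num[i, f]
      gd[rr$pivots[i]] <- rr$den[i, f]
    }
    l <- Reduce(lcm_int, gd[gn != 0], accumulate = FALSE)
    v <- gn * (l / gd)
    g <- Reduce(gcd_int, abs(v[v != 0]))
    v <- v / g
    if (v[which(v != 0)[1L]] < 0) v <- -v
    G[, k] <- v
  }
  G
}
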