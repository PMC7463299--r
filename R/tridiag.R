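# Internal tridiagonal linear algebra. The GMRF structure matrix Q is
# tridiagonal, so every precision matrix used by the samplers is
# tridiagonal too; Cholesky, solves and sampling are O(d).

# gamma' Q gamma = sum of squared first differences
qQuadform <- function(gamma) {
  d <- diff(gamma)
  sum(d * d)
}

# Q %*% gamma without forming Q
qProd <- function(gamma) {
  d <- length(gamma)
  if (d == 1L) return(0)
  out <- numeric(d)
  out[1] <- gamma[1] - gamma[2]
  out[d] <- gamma[d] - gamma[d - 1L]
  if (d > 2L) {
    i <- 2:(d - 1L)
    out[i] <- 2 * gamma[i] - gamma[i - 1L] - gamma[i + 1L]
  }
  out
}

# Cholesky P = L L' of a symmetric tridiagonal matrix with diagonal dg and
# sub/super-diagonal off. Returns lower-bidiagonal L as (diag l, sub m).
tridiagChol <- function(dg, off) {
  d <- length(dg)
  l <- numeric(d)
  m <- numeric(max(d - 1L, 0L))
  if (dg[1] <= 0) stop("precision matrix is not positive definite")
  l[1] <- sqrt(dg[1])
  if (d > 1L) for (i in seq_len(d - 1L)) {
    m[i] <- off[i] / l[i]
    pivot <- dg[i + 1L] - m[i]^2
    if (pivot <= 0) stop("precision matrix is not positive definite")
    l[i + 1L] <- sqrt(pivot)
  }
  list(l = l, m = m)
}

tridiagLogDet <- function(ch) 2 * sum(log(ch$l))

# Solve (L L') x = b
tridiagSolve <- function(ch, b) {
  l <- ch$l; m <- ch$m
  d <- length(l)
  y <- numeric(d)
  y[1] <- b[1] / l[1]
  if (d > 1L) for (i in 2:d) y[i] <- (b[i] - m[i - 1L] * y[i - 1L]) / l[i]
  x <- numeric(d)
  x[d] <- y[d] / l[d]
  if (d > 1L) for (i in (d - 1L):1L) x[i] <- (y[i] - m[i] * x[i + 1L]) / l[i]
  x
}

# Solve L' x = z (for sampling: x ~ N(0, P^{-1}) when z ~ N(0, I))
tridiagBacksolve <- function(ch, z) {
  l <- ch$l; m <- ch$m
  d <- length(l)
  x <- numeric(d)
  x[d] <- z[d] / l[d]
  if (d > 1L) for (i in (d - 1L):1L) x[i] <- (z[i] - m[i] * x[i + 1L]) / l[i]
  x
}

# x' P x for tridiagonal P given as (diag, off)
tridiagQuadform <- function(dg, off, x) {
  s <- sum(dg * x * x)
  if (length(x) > 1L)
    s <- s + 2 * sum(off * x[-length(x)] * x[-1L])
  s
}

# Dense reconstruction (tests / fallback agreement checks)
tridiagDense <- function(dg, off) {
  d <- length(dg)
  P <- diag(dg, d)
  if (d > 1L) {
    P[cbind(1:(d - 1L), 2:d)] <- off
    P[cbind(2:d, 1:(d - 1L))] <- off
  }
  P
}
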