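# Brute-force spatial-domain oracles, written independently of the FFT
# implementation: direct nested sums with cyclic index arithmetic and the
# zero-shift origin at the center pixel c0 = floor(dim/2) (0-based).

oracleConvolve <- function(f, g) {
  d <- dim(f); c0 <- d %/% 2L
  out <- matrix(0, d[1], d[2])
  for (x1 in 0:(d[1] - 1)) for (x2 in 0:(d[2] - 1)) {
    acc <- 0
    for (y1 in 0:(d[1] - 1)) for (y2 in 0:(d[2] - 1)) {
      z1 <- (x1 + c0[1] - y1) %% d[1]
      z2 <- (x2 + c0[2] - y2) %% d[2]
      acc <- acc + f[y1 + 1, y2 + 1] * g[z1 + 1, z2 + 1]
    }
    out[x1 + 1, x2 + 1] <- acc
  }
  out
}

oracleCorrelate <- function(f, g) {
  d <- dim(f); c0 <- d %/% 2L
  out <- matrix(0, d[1], d[2])
  for (x1 in 0:(d[1] - 1)) for (x2 in 0:(d[2] - 1)) {
    acc <- 0
    for (y1 in 0:(d[1] - 1)) for (y2 in 0:(d[2] - 1)) {
      z1 <- (y1 + x1 - c0[1]) %% d[1]
      z2 <- (y2 + x2 - c0[2]) %% d[2]
      acc <- acc + f[y1 + 1, y2 + 1] * g[z1 + 1, z2 + 1]
    }
    out[x1 + 1, x2 + 1] <- acc
  }
  out
}

# linear (non-cyclic) convolution: out-of-range kernel samples are zero
oracleLinearConvolve <- function(f, g) {
  d <- dim(f); c0 <- d %/% 2L
  out <- matrix(0, d[1], d[2])
  for (x1 in 0:(d[1] - 1)) for (x2 in 0:(d[2] - 1)) {
    acc <- 0
    for (y1 in 0:(d[1] - 1)) for (y2 in 0:(d[2] - 1)) {
      z1 <- x1 + c0[1] - y1
      z2 <- x2 + c0[2] - y2
      if (z1 >= 0 && z1 < d[1] && z2 >= 0 && z2 < d[2])
        acc <- acc + f[y1 + 1, y2 + 1] * g[z1 + 1, z2 + 1]
    }
    out[x1 + 1, x2 + 1] <- acc
  }
  out
}

oracleReverse <- function(f) {
  d <- dim(f); c0 <- d %/% 2L
  out <- matrix(0, d[1], d[2])
  for (x1 in 0:(d[1] - 1)) for (x2 in 0:(d[2] - 1)) {
    out[x1 + 1, x2 + 1] <-
      f[((2 * c0[1] - x1) %% d[1]) + 1, ((2 * c0[2] - x2) %% d[2]) + 1]
  }
  out
}

# one multiplicative Richardson-Lucy update via the direct-sum oracles
oracleRLStep <- function(o, f, h) {
  denom <- oracleConvolve(o, h)
  o * oracleConvolve(f / denom, oracleReverse(h))
}

# one anchor-update iteration with explicit kernel construction
oracleAUStep <- function(o, chi, H) {
  K <- oracleCorrelate(o, H)
  K <- K / sum(K)
  denom <- oracleConvolve(o, K)
  o * oracleConvolve(chi / denom, oracleReverse(K))
}

oracleRotate90 <- function(m) {
  # one counter-clockwise quarter turn by direct index mapping
  out <- matrix(0, ncol(m), nrow(m))
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out)))
    out[i, j] <- m[j, ncol(m) + 1 - i]
  out
}

centeredImpulse <- function(d) {
  x <- matrix(0, d[1], d[2])
  ctr <- centerIndex(d)
  x[ctr[1], ctr[2]] <- 1
  x
}

randRaster <- function(d, seed) {
  set.seed(seed)
  matrix(runif(prod(d)), d[1], d[2])
}
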