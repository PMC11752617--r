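# internal numeric helpers shared across the model code

elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}

# derivative of ELU evaluated at the pre-activation
eluGrad <- function(pre) {
  g <- matrix(1, nrow(pre), ncol(pre))
  neg <- pre < 0
  g[neg] <- exp(pre[neg])
  g
}

# numerically stable row-wise softmax; -Inf entries map to exact zeros
softmaxRows <- function(L) {
  mx <- apply(L, 1L, max)
  E <- exp(L - mx)
  E[L == -Inf] <- 0
  E / rowSums(E)
}

frobNorm <- function(x) sqrt(sum(x * x))

# Glorot-style normal initialisation from the current RNG stream
glorot <- function(nr, nc) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

# squared Euclidean distances between the COLUMNS of X and Y (p x n matrices)
colSqDist <- function(X, Y = X) {
  nx <- colSums(X * X)
  ny <- colSums(Y * Y)
  d <- outer(nx, ny, "+") - 2 * crossprod(X, Y)
  d[d < 0] <- 0
  d
}

stopIfNotFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

# standardize gene symbols: case folding + whitespace stripping only
standardizeIds <- function(ids) toupper(trimws(ids))
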