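#' Initialise the shared-weight variational autoencoder
#'
#' A two-layer encoder (genes -> `hidden` with ELU, then linear heads for
#' the latent mean and log-variance) and a mirrored two-layer decoder, so
#' the total depth is `L = 2 * l = 4` layer representations.  Weights are
#' shared between the original and augmented views by construction: both
#' views are pushed through the same parameter set.
#'
#' @param M number of genes.
#' @param hidden hidden width (default 128).
#' @param latent latent width (default 10).
#' @return parameter list.
#' @export
initVAEParams <- function(M, hidden = 128L, latent = 10L) {
  list(W1 = glorot(hidden, M), b1 = numeric(hidden),
       Wmu = glorot(latent, hidden), bmu = numeric(latent),
       Wlv = glorot(latent, hidden), blv = numeric(latent),
       W3 = glorot(hidden, latent), b3 = numeric(hidden),
       W4 = glorot(M, hidden), b4 = numeric(M),
       hidden = as.integer(hidden), latent = as.integer(latent))
}

#' Encode a view
#'
#' `H^(1) = ELU(W1 X + b1)`; the final encoder layer parameterises the
#' latent mean and log-variance (the mean is the layer-2 representation
#' used by the manifold and alignment losses).
#'
#' @param X M x N view matrix.
#' @param params from [initVAEParams()].
#' @return list with `H1` (hidden x N), `mu`, `logvar` (latent x N) and
#'   the pre-activation cache `pre1`.
#' @export
vaeEncode <- function(X, params) {
  stopIfNotFinite(X, "encoder input")
  if (nrow(X) != ncol(params$W1))
    stop("width mismatch: encoder expects ", ncol(params$W1), " genes, got ",
         nrow(X))
  pre1 <- params$W1 %*% X + params$b1
  H1 <- elu(pre1)
  mu <- params$Wmu %*% H1 + params$bmu
  logvar <- params$Wlv %*% H1 + params$blv
  list(H1 = H1, mu = mu, logvar = logvar, pre1 = pre1)
}

#' Decode a latent matrix
#'
#' `H^(3) = ELU(W3 z + b3)`, `H^(4) = W4 H^(3) + b4` (linear output head,
#' shaped M x N).
#'
#' @param z latent x N matrix (sampled during training, the mean at
#'   inference).
#' @param params from [initVAEParams()].
#' @return list with `H3` (hidden x N), `Xhat` (M x N) and cache `pre3`.
#' @export
vaeDecode <- function(z, params) {
  if (nrow(z) != ncol(params$W3))
    stop("width mismatch: decoder expects latent width ", ncol(params$W3))
  pre3 <- params$W3 %*% z + params$b3
  H3 <- elu(pre3)
  Xhat <- params$W4 %*% H3 + params$b4
  list(H3 = H3, Xhat = Xhat, pre3 = pre3)
}

#' Closed-form KL divergence to the standard normal
#'
#' Per latent unit, `KL(N(mu, sigma^2) || N(0, 1)) =
#' (mu^2 + sigma^2 - 1 - log sigma^2) / 2`.
#'
#' @param mu,logvar matrices (latent x N) or vectors.
#' @return array of the same shape with per-unit KL values.
#' @export
klDivergence <- function(mu, logvar) {
  0.5 * (mu^2 + exp(logvar) - 1 - logvar)
}

#' Gaussian ELBO loss for one view
#'
#' Squared-error reconstruction (Gaussian likelihood with unit variance)
#' plus the analytic KL to a standard-normal prior, both averaged per
#' spot: `recon = ||X - Xhat||_F^2 / N`, `kl = sum(KL) / N`.
#'
#' @param X view matrix (target).
#' @param Xhat reconstruction.
#' @param mu,logvar latent parameters.
#' @return list with `recon`, `kl` and their sum `elbo` (all >= 0).
#' @export
elboLoss <- function(X, Xhat, mu, logvar) {
  if (!identical(dim(X), dim(Xhat))) stop("shape mismatch in elboLoss")
  N <- ncol(X)
  recon <- sum((X - Xhat)^2) / N
  kl <- sum(klDivergence(mu, logvar)) / N
  if (!is.finite(recon) || !is.finite(kl))
    stop("non-finite ELBO component")
  list(recon = recon, kl = kl, elbo = recon + kl)
}

.asZ <- function(Z) if (is(Z, "ManifoldGraph")) Z@Z else as.matrix(Z)
.asB <- function(B) {
  if (is(B, "SpatialGraph")) as.matrix(B@B) else as.matrix(B)
}

#' Self-expressive manifold loss
#'
#' The view-unified manifold constraint over all layer representations:
#' `(1/L) * sum_i [ ||H1_i (I + alpha B) - H1_i Z||_F^2 / ||H1_i|| +
#' ||H2_i (I + alpha B) - H2_i Z||_F^2 / ||H2_i|| ]`, with `||.||` the
#' Frobenius norm.  A zero-norm layer is skipped with a warning.  The loss
#' vanishes exactly at `Z = I + alpha B`.
#'
#' @param H1,H2 lists of the L layer representations per view (each
#'   width x N).
#' @param Z N x N self-expressive matrix or a [ManifoldGraph-class].
#' @param B spatial graph weights (matrix or [SpatialGraph-class]).
#' @param alpha spatial-influence coefficient (ignored if `Z` is a
#'   `ManifoldGraph`, which carries its own).
#' @return non-negative scalar.
#' @export
manifoldLoss <- function(H1, H2, Z, B, alpha = 1) {
  if (is(Z, "ManifoldGraph")) alpha <- Z@alpha
  Zm <- .asZ(Z)
  Bm <- .asB(B)
  N <- nrow(Zm)
  Cmat <- diag(N) + alpha * Bm - Zm
  L <- length(H1)
  if (length(H2) != L) stop("views must expose the same number of layers")
  total <- 0
  for (i in seq_len(L)) {
    for (H in list(H1[[i]], H2[[i]])) {
      nrm <- frobNorm(H)
      if (nrm == 0) {
        warning("degenerate (all-zero) layer representation skipped")
        next
      }
      total <- total + sum((H %*% Cmat)^2) / nrm
    }
  }
  total / L
}
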