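#' Maximum mean discrepancy (Gaussian kernel, biased V-statistic)
#'
#' `MMD(X, Y) = mean K(x_i, x_j) - 2 mean K(x_i, y_j) + mean K(y_i, y_j)`
#' with the fixed-bandwidth Gaussian kernel
#' `K(x, y) = exp(-||x - y||^2 / 2)`.  Samples are the *columns* of the
#' input matrices (a bare vector is read as n one-dimensional samples).
#' Set sizes may differ (weights `1/n^2`, `1/m^2`, `2/nm`); both views
#' share the same spots in this package, so sizes are equal in practice.
#' The V-statistic is clamped at zero against roundoff.
#'
#' @param X,Y feature x samples matrices with equal feature dimension.
#' @return non-negative scalar.
#' @examples
#' mmd(0, 2)          # 2 - 2 * exp(-2)
#' mmd(cbind(0, 1), cbind(0, 1))   # 0
#' @export
mmd <- function(X, Y) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1L)
  if (nrow(X) != nrow(Y)) stop("sample sets must share the feature dimension")
  n <- ncol(X); m <- ncol(Y)
  if (n == 0L || m == 0L) stop("empty sample set")
  kxx <- exp(-colSqDist(X) / 2)
  kyy <- exp(-colSqDist(Y) / 2)
  kxy <- exp(-colSqDist(X, Y) / 2)
  v <- sum(kxx) / n^2 + sum(kyy) / m^2 - 2 * sum(kxy) / (n * m)
  max(v, 0)
}

.checkLayers <- function(H1, H2) {
  if (length(H1) != length(H2))
    stop("layer-count mismatch between the two views")
  if (!length(H1)) stop("need at least one layer")
}

#' Global distribution alignment
#'
#' Mean over layers of the MMD between the two views' spot distributions:
#' `(1/L) sum_i MMD(H2^(i), H1^(i))`, spots (columns) being the samples.
#'
#' @param H1,H2 lists of layer representations (width x N each).
#' @return non-negative scalar.
#' @export
alignGlobal <- function(H1, H2) {
  .checkLayers(H1, H2)
  mean(vapply(seq_along(H1), function(i) mmd(H2[[i]], H1[[i]]), numeric(1)))
}

#' Spatially local distribution alignment
#'
#' For every spot k, the MMD between the two views restricted to k's
#' spatial neighbourhood, averaged over layers and spots:
#' `(1/(L*N)) sum_i sum_k MMD(H2^(i)[, Nei(k)], H1^(i)[, Nei(k)])`.
#'
#' @param H1,H2 lists of layer representations.
#' @param neighbors neighbour sets covering all N spots (see
#'   [knnNeighbors()]).
#' @return non-negative scalar.
#' @export
alignLocal <- function(H1, H2, neighbors) {
  .checkLayers(H1, H2)
  if (any(lengths(neighbors) == 0L)) stop("empty neighbor set")
  N <- ncol(H1[[1L]])
  if (length(neighbors) != N)
    stop("neighbor sets must cover all ", N, " spots")
  total <- 0
  for (i in seq_along(H1)) {
    for (k in seq_len(N)) {
      idx <- neighbors[[k]]
      total <- total + mmd(H2[[i]][, idx, drop = FALSE],
                           H1[[i]][, idx, drop = FALSE])
    }
  }
  total / (length(H1) * N)
}

#' Contrastive view loss
#'
#' Keeps each spot's two view-specific representations close:
#' `(1/L) sum_i ||H1^(i) - H2^(i)||_F^2 / ||H1^(i) + H2^(i)||_F`.  A layer
#' with a zero denominator is skipped with a warning.
#'
#' @param H1,H2 lists of layer representations.
#' @return non-negative scalar.
#' @export
contrastiveLoss <- function(H1, H2) {
  .checkLayers(H1, H2)
  L <- length(H1)
  total <- 0
  for (i in seq_len(L)) {
    den <- frobNorm(H1[[i]] + H2[[i]])
    if (den == 0) {
      warning("zero denominator in contrastive loss at layer ", i,
              "; term skipped")
      next
    }
    total <- total + sum((H1[[i]] - H2[[i]])^2) / den
  }
  total / L
}

#' Overall training objective
#'
#' `total = (elbo1 + elbo2 + lambda1 * manifold) +
#'  lambda2 * (contrastive + align_GD + align_SLD)`.
#'
#' @param components named list or vector with `elbo1`, `elbo2`,
#'   `manifold`, `align_gd`, `align_sld`, `contrastive`.
#' @param lambda1 weight of the manifold constraint (default 1).
#' @param lambda2 weight of the cross-dimension block (default 0.1).
#' @return scalar total loss.
#' @export
totalLoss <- function(components, lambda1 = 1, lambda2 = 0.1) {
  cc <- as.list(components)
  need <- c("elbo1", "elbo2", "manifold", "align_gd", "align_sld",
            "contrastive")
  miss <- setdiff(need, names(cc))
  if (length(miss)) stop("missing components: ", paste(miss, collapse = ", "))
  (cc$elbo1 + cc$elbo2 + lambda1 * cc$manifold) +
    lambda2 * (cc$contrastive + cc$align_gd + cc$align_sld)
}
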