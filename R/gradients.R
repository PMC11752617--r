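# Full-model forward and analytic backward pass.
#
# The parameter tree mirrors the architecture:
#   params$Wpe           2r x N positional-encoding projection (or NULL)
#   params$tr$layers     transformer units (heads: Wq/Wk/Wv; Wo; FFN W1/b1/W2/b2)
#   params$vae           shared encoder/decoder weights
#   params$Z             N x N self-expressive spot graph
# `const` carries everything fixed during optimisation: X1, the prior A,
# the dense spatial graph B, IaB = I + alpha*B, the PE basis, and the
# neighbourhood pair-weight matrix used by the local alignment loss.

# pair-weight matrix for the local MMD: W = sum_k (1/|Nei(k)|^2) e e'
# so that <W, K> accumulates every neighbourhood's V-statistic in one
# Frobenius product with the full kernel matrix.
.neighborPairWeights <- function(neighbors, N) {
  Wp <- matrix(0, N, N)
  for (k in seq_len(N)) {
    idx <- neighbors[[k]]
    Wp[idx, idx] <- Wp[idx, idx] + 1 / length(idx)^2
  }
  Wp
}

# forward pass; eps = list(e1, e2) reparameterisation noise (latent x N).
# Sampling them outside the forward keeps finite-difference checks exact.
gtlForward <- function(params, const, cfg, eps) {
  X1 <- const$X1
  N <- ncol(X1)
  P <- if (!is.null(params$Wpe)) const$peBasis %*% params$Wpe else NULL
  tf <- transformerForward(X1, list(layers = params$tr$layers), P = P,
                           A = const$A, mode = cfg$mode, mu = cfg$mu,
                           maskDiag = cfg$maskDiag)
  X2 <- tf$X2
  vp <- params$vae
  enc1 <- vaeEncode(X1, vp)
  enc2 <- vaeEncode(X2, vp)
  z1 <- enc1$mu + eps$e1 * exp(0.5 * enc1$logvar)
  z2 <- enc2$mu + eps$e2 * exp(0.5 * enc2$logvar)
  dec1 <- vaeDecode(z1, vp)
  dec2 <- vaeDecode(z2, vp)
  # layer representations; element 1 is the input view itself (H^(0)),
  # which joins the contrastive/alignment sums when cfg$includeInput is
  # set, giving the augmented view a direct anchor to the original
  Hv1 <- list(X1, enc1$H1, enc1$mu, dec1$H3, dec1$Xhat)
  Hv2 <- list(X2, enc2$H1, enc2$mu, dec2$H3, dec2$Xhat)
  nAll <- length(Hv1)
  vaeIdx <- 2:nAll                       # the L encoder/decoder layers
  alnIdx <- if (isTRUE(cfg$includeInput)) seq_len(nAll) else vaeIdx
  L <- length(vaeIdx)
  La <- length(alnIdx)

  # both views reconstruct the ORIGINAL expression: the augmented view is
  # by construction a reconstruction of X1 from other genes' signals, so
  # its decoding is anchored to X1 as well
  el1 <- elboLoss(X1, dec1$Xhat, enc1$mu, enc1$logvar)
  el2 <- elboLoss(X1, dec2$Xhat, enc2$mu, enc2$logvar)

  # manifold residuals (encoder/decoder layers only, per the constraint's
  # definition over the autoencoder stack)
  Cmat <- const$IaB - params$Z
  diag(Cmat) <- diag(Cmat) + 1          # C = I + alpha*B - Z
  manifold <- 0
  R1 <- vector("list", nAll); R2 <- vector("list", nAll)
  n1 <- numeric(nAll); n2 <- numeric(nAll)
  for (i in seq_len(nAll)) {
    n1[i] <- frobNorm(Hv1[[i]]); n2[i] <- frobNorm(Hv2[[i]])
  }
  for (i in vaeIdx) {
    R1[[i]] <- Hv1[[i]] %*% Cmat
    R2[[i]] <- Hv2[[i]] %*% Cmat
    if (n1[i] > 0) manifold <- manifold + sum(R1[[i]]^2) / n1[i]
    if (n2[i] > 0) manifold <- manifold + sum(R2[[i]]^2) / n2[i]
  }
  manifold <- manifold / L

  # kernel matrices shared by the global and local alignment losses
  kern <- vector("list", nAll)
  gd <- 0; sld <- 0
  for (i in alnIdx) {
    K11 <- exp(-colSqDist(Hv1[[i]]) / 2)
    K22 <- exp(-colSqDist(Hv2[[i]]) / 2)
    K21 <- exp(-colSqDist(Hv2[[i]], Hv1[[i]]) / 2)
    kern[[i]] <- list(K11 = K11, K22 = K22, K21 = K21)
    gd <- gd + (sum(K22) + sum(K11) - 2 * sum(K21)) / N^2
    Wp <- const$pairW
    sld <- sld + (sum(Wp * K22) + sum(Wp * K11) - 2 * sum(Wp * K21)) / N
  }
  gd <- gd / La
  sld <- sld / La

  contrastive <- 0
  clDen <- numeric(nAll)
  for (i in alnIdx) {
    clDen[i] <- frobNorm(Hv1[[i]] + Hv2[[i]])
    if (clDen[i] > 0)
      contrastive <- contrastive + sum((Hv1[[i]] - Hv2[[i]])^2) / clDen[i]
  }
  contrastive <- contrastive / La

  comps <- list(elbo1 = el1$elbo, elbo2 = el2$elbo, manifold = manifold,
                align_gd = gd, align_sld = sld, contrastive = contrastive)
  total <- totalLoss(comps, cfg$lambda1, cfg$lambda2)

  list(losses = c(comps, list(total = total)),
       X2 = X2, S_heads = tf$S_heads,
       cache = list(tf = tf, enc1 = enc1, enc2 = enc2, dec1 = dec1,
                    dec2 = dec2, z1 = z1, z2 = z2, eps = eps,
                    Hv1 = Hv1, Hv2 = Hv2, R1 = R1, R2 = R2,
                    n1 = n1, n2 = n2, Cmat = Cmat, kern = kern,
                    clDen = clDen, vaeIdx = vaeIdx, alnIdx = alnIdx))
}

# direct loss gradients at every layer representation of both views,
# plus dZ.  Returns lists dH1/dH2 (length L) and dZ.
.layerLossGrads <- function(params, const, cfg, cache) {
  Hv1 <- cache$Hv1; Hv2 <- cache$Hv2
  nAll <- length(Hv1)
  vaeIdx <- cache$vaeIdx; alnIdx <- cache$alnIdx
  L <- length(vaeIdx); La <- length(alnIdx)
  N <- ncol(Hv1[[1L]])
  lam1 <- cfg$lambda1; lam2 <- cfg$lambda2
  dH1 <- vector("list", nAll); dH2 <- vector("list", nAll)
  for (i in seq_len(nAll)) {
    dH1[[i]] <- matrix(0, nrow(Hv1[[i]]), N)
    dH2[[i]] <- matrix(0, nrow(Hv2[[i]]), N)
  }
  dZ <- matrix(0, N, N)
  Ct <- t(cache$Cmat)

  for (i in vaeIdx) {
    # manifold: ||H C||_F^2 / ||H||_F, both quotient-rule terms
    for (v in 1:2) {
      H <- if (v == 1) Hv1[[i]] else Hv2[[i]]
      R <- if (v == 1) cache$R1[[i]] else cache$R2[[i]]
      nrm <- if (v == 1) cache$n1[i] else cache$n2[i]
      if (nrm > 0) {
        g <- (lam1 / L) * (2 * (R %*% Ct) / nrm - (sum(R^2) / nrm^3) * H)
        if (v == 1) dH1[[i]] <- dH1[[i]] + g else dH2[[i]] <- dH2[[i]] + g
        dZ <- dZ + (lam1 / L) * (-2) * crossprod(H, R) / nrm
      }
    }
  }

  for (i in alnIdx) {
    # alignment (global + local share the kernels; combine their weights)
    kk <- cache$kern[[i]]
    cgd <- lam2 / (La * N^2)
    csld <- lam2 / (La * N)
    G <- cgd + csld * const$pairW        # symmetric weight matrix
    E11 <- G * kk$K11
    E22 <- G * kk$K22
    E21 <- G * kk$K21
    H1 <- Hv1[[i]]; H2 <- Hv2[[i]]
    # self terms: d/dX sum G_ab K(x_a, x_b) = 2 (X E - X diag(rowSums E))
    rs11 <- rowSums(E11); rs22 <- rowSums(E22)
    g1 <- 2 * (H1 %*% E11 - H1 * rep(rs11, each = nrow(H1)))
    g2 <- 2 * (H2 %*% E22 - H2 * rep(rs22, each = nrow(H2)))
    # cross term -2 sum G_ab K(h2_a, h1_b)
    rs21 <- rowSums(E21); cs21 <- colSums(E21)
    g2 <- g2 - 2 * (H1 %*% t(E21) - H2 * rep(rs21, each = nrow(H2)))
    g1 <- g1 - 2 * (H2 %*% E21 - H1 * rep(cs21, each = nrow(H1)))
    dH1[[i]] <- dH1[[i]] + g1
    dH2[[i]] <- dH2[[i]] + g2

    # contrastive
    den <- cache$clDen[i]
    if (den > 0) {
      D <- H1 - H2
      Ssum <- H1 + H2
      sc <- sum(D^2) / den^3
      dH1[[i]] <- dH1[[i]] + (lam2 / La) * (2 * D / den - sc * Ssum)
      dH2[[i]] <- dH2[[i]] + (lam2 / La) * (-2 * D / den - sc * Ssum)
    }
  }
  list(dH1 = dH1, dH2 = dH2, dZ = dZ)
}

# backward through one view's VAE chain.  dHs = direct gradients at the
# four layer representations; Xtarget is the reconstruction target and
# Xin the encoder input.  Returns parameter gradients plus the gradient
# at the encoder input.
.vaeBackwardView <- function(Xin, Xtarget, vp, enc, dec, z, eps, dHs, N) {
  # layer 4 (linear output)
  G4 <- dHs[[4L]] + 2 * (dec$Xhat - Xtarget) / N
  dW4 <- tcrossprod(G4, dec$H3)
  db4 <- rowSums(G4)
  dH3 <- crossprod(vp$W4, G4) + dHs[[3L]]
  dpre3 <- dH3 * eluGrad(dec$pre3)
  dW3 <- tcrossprod(dpre3, z)
  db3 <- rowSums(dpre3)
  dz <- crossprod(vp$W3, dpre3)
  # reparameterisation + KL + direct layer-2 gradient (H^(2) = mu)
  dmu <- dz + dHs[[2L]] + enc$mu / N
  dlv <- dz * eps * 0.5 * exp(0.5 * enc$logvar) +
    0.5 * (exp(enc$logvar) - 1) / N
  dWmu <- tcrossprod(dmu, enc$H1)
  dbmu <- rowSums(dmu)
  dWlv <- tcrossprod(dlv, enc$H1)
  dblv <- rowSums(dlv)
  dH1 <- crossprod(vp$Wmu, dmu) + crossprod(vp$Wlv, dlv) + dHs[[1L]]
  dpre1 <- dH1 * eluGrad(enc$pre1)
  dW1 <- tcrossprod(dpre1, Xin)
  db1 <- rowSums(dpre1)
  dX <- crossprod(vp$W1, dpre1)
  list(grads = list(W1 = dW1, b1 = db1, Wmu = dWmu, bmu = dbmu,
                    Wlv = dWlv, blv = dblv, W3 = dW3, b3 = db3,
                    W4 = dW4, b4 = db4),
       dX = dX)
}

gtlBackward <- function(params, const, cfg, fw) {
  cache <- fw$cache
  X1 <- const$X1
  X2 <- fw$X2
  N <- ncol(X1)
  ll <- .layerLossGrads(params, const, cfg, cache)

  bv1 <- .vaeBackwardView(X1, X1, params$vae, cache$enc1, cache$dec1,
                          cache$z1, cache$eps$e1, ll$dH1[2:5], N)
  bv2 <- .vaeBackwardView(X2, X1, params$vae, cache$enc2, cache$dec2,
                          cache$z2, cache$eps$e2, ll$dH2[2:5], N)
  vaeGrads <- mapply(`+`, bv1$grads, bv2$grads, SIMPLIFY = FALSE)

  # X2 feeds the shared encoder, carries its own layer-0 loss gradient,
  # and its reconstruction target is X1 (constant)
  dX2 <- bv2$dX + ll$dH2[[1L]]

  trLayers <- params$tr$layers
  gLayers <- vector("list", length(trLayers))
  dX <- dX2
  for (l in rev(seq_along(trLayers))) {
    bk <- .attentionLayerBackward(dX, trLayers[[l]], cache$tf$caches[[l]])
    gLayers[[l]] <- bk$grads
    dX <- bk$dX
  }
  gWpe <- if (!is.null(params$Wpe)) crossprod(const$peBasis, dX) else NULL

  out <- list(tr = list(layers = gLayers), vae = vaeGrads, Z = ll$dZ)
  if (!is.null(gWpe)) out$Wpe <- gWpe
  out
}

## ---- parameter-tree utilities (Adam needs elementwise tree algebra) ----

treeMap <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- if (is.null(b)) lapply(a, function(x) treeMap(f, x))
      else mapply(function(x, y) treeMap(f, x, y), a, b, SIMPLIFY = FALSE)
    return(out)
  }
  if (is.null(b)) f(a) else f(a, b)
}

treeZero <- function(a) treeMap(function(x) x * 0, a)

# flatten all numeric leaves into one vector (used by checkpoints/tests)
treeFlatten <- function(a) {
  if (is.list(a)) return(unlist(lapply(a, treeFlatten), use.names = FALSE))
  as.numeric(a)
}
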