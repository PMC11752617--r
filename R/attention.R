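#' SVD positional encodings from a prior network
#'
#' Factorises the prior gene adjacency `A = U S V'` and keeps the top-r
#' factors `Utilde = U sqrt(S)`, `Vtilde = V sqrt(S)` (so that
#' `Utilde %*% t(Vtilde)` is the best rank-r Frobenius approximation of
#' `A`); the positional encoding is `P = [Utilde || Vtilde] %*% W`, with
#' `W` a learnable `2r x N` projection, randomly initialised from the
#' current RNG stream when not supplied.
#'
#' @param A M x M prior adjacency.
#' @param r truncation rank (`r <= M`).
#' @param N number of spots (width of `P`); required when `W` is `NULL`.
#' @param W optional `2r x N` projection matrix.
#' @return list with `P` (M x N), `Utilde`, `Vtilde` (M x r) and `W`.
#' @export
svdPositionalEncoding <- function(A, r, N = NULL, W = NULL) {
  M <- nrow(A)
  if (r > M) stop("r (", r, ") exceeds the matrix dimension (", M, ")")
  sv <- svd(A, nu = r, nv = r)
  sq <- sqrt(sv$d[seq_len(r)])
  Ut <- sv$u * rep(sq, each = M)
  Vt <- sv$v * rep(sq, each = M)
  if (is.null(W)) {
    if (is.null(N)) stop("supply N (or W) to build the projection")
    W <- glorot(2L * r, N)
  }
  list(P = cbind(Ut, Vt) %*% W, Utilde = Ut, Vtilde = Vt, W = W)
}

#' Initialise transformer parameters
#'
#' Glorot-normal weights drawn from the current RNG stream for a stack of
#' `nLayers` encoder units, each a multi-head self-attention sublayer
#' (per-head query/key/value projections of width `dHead`), a learned
#' output projection back to the spot dimension, and a position-wise
#' feed-forward sublayer with a residual connection.
#'
#' With `valueMode = "identity"` (the default) each head owns a
#' contiguous block of the spot columns and its value matrix is the
#' layer input restricted to that block, so the head output is literally
#' an attention-weighted mixture of the other genes' expression on those
#' spots and the concatenated head outputs reassemble an M x N matrix
#' with no output projection; only the query/key projections are
#' learned.  With `valueMode = "learned"` per-head value projections, an
#' output projection and a residual feed-forward sublayer are added.
#'
#' @param M,N genes and spots.
#' @param nLayers number of encoder units (default 3).
#' @param nHeads attention heads per unit (default 5).
#' @param dHead query/key width per head (default 8).
#' @param ffDim feed-forward hidden width (`"learned"` mode, default 32).
#' @param valueMode `"identity"` or `"learned"`.
#' @return nested parameter list (block bounds for identity mode are in
#'   `attr(, "blocks")`).
#' @export
initTransformerParams <- function(M, N, nLayers = 3L, nHeads = 5L,
                                  dHead = 8L, ffDim = 32L,
                                  valueMode = c("identity", "learned")) {
  valueMode <- match.arg(valueMode)
  if (nHeads < 1L || dHead < 1L) stop("need at least one head of width >= 1")
  layers <- lapply(seq_len(nLayers), function(l) {
    heads <- lapply(seq_len(nHeads), function(t) {
      h <- list(Wq = glorot(N, dHead), Wk = glorot(N, dHead))
      if (valueMode == "learned") h$Wv <- glorot(N, dHead)
      h
    })
    ly <- list(heads = heads)
    if (valueMode == "identity") {
      # per-gene gain/offset: amplitude freedom for the attention mixture
      # without any cross-gene or cross-spot mixing outside S
      ly$gamma <- rep(1, M)
      ly$beta <- numeric(M)
    }
    if (valueMode == "learned") {
      ly$Wo <- glorot(nHeads * dHead, N)
      ly$W1 <- glorot(N, ffDim); ly$b1 <- numeric(ffDim)
      ly$W2 <- glorot(ffDim, N); ly$b2 <- numeric(N)
    }
    ly
  })
  list(layers = layers, nHeads = as.integer(nHeads), dHead = as.integer(dHead))
}

# contiguous column blocks assigning each spot to exactly one head
.headBlocks <- function(N, nHeads) {
  sizes <- rep(N %/% nHeads, nHeads)
  extra <- N %% nHeads
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  mapply(function(a, b) seq.int(a, b), c(1L, head(ends, -1) + 1L), ends,
         SIMPLIFY = FALSE)
}

#' One multi-head self-attention encoder unit
#'
#' Per head t, the map is
#' `S_t = Normalize(softmax(Q_t K_t' / sqrt(d_t)) + mu * A)` where
#' `Normalize` renormalises every row to sum to one (so each row stays a
#' convex combination over genes) and the softmax diagonal is masked by
#' default so a gene is reconstructed from *other* genes.  Head outputs
#' `S_t V_t` are concatenated, projected back to the spot dimension, and
#' passed through a residual feed-forward sublayer.
#'
#' In `mode = "finetune"` the prior weight `mu` is forced to zero; in
#' `mode = "pretrain"` it defaults to 0.2 and `A` must be supplied when
#' `mu > 0`.
#'
#' @param X M x N layer input.
#' @param layer one element of `initTransformerParams(...)$layers`.
#' @param A optional M x M prior adjacency.
#' @param mode `"finetune"` or `"pretrain"`.
#' @param mu prior-constraint weight (pretrain only).
#' @param maskDiag logical, mask self-attention logits (default TRUE).
#' @return list with `X_out` (M x N), `S_heads` (list of M x M maps) and a
#'   `cache` of intermediates for the backward pass.
#' @export
attentionLayer <- function(X, layer, A = NULL,
                           mode = c("finetune", "pretrain"),
                           mu = 0.2, maskDiag = TRUE) {
  mode <- match.arg(mode)
  if (mode == "finetune") mu <- 0
  if (mu > 0 && is.null(A)) stop("pretrain mode with mu > 0 requires A")
  M <- nrow(X)
  identityV <- is.null(layer$heads[[1L]]$Wv)
  blocks <- if (identityV) .headBlocks(ncol(X), length(layer$heads))
  d <- ncol(layer$heads[[1L]]$Wq)
  heads <- vector("list", length(layer$heads))
  Cc <- vector("list", length(layer$heads))
  Smaps <- vector("list", length(layer$heads))
  for (t in seq_along(layer$heads)) {
    h <- layer$heads[[t]]
    Q <- X %*% h$Wq; K <- X %*% h$Wk
    V <- if (identityV) X[, blocks[[t]], drop = FALSE] else X %*% h$Wv
    logits <- tcrossprod(Q, K) / sqrt(d)
    if (!all(is.finite(logits)))
      stop("non-finite attention logits at head ", t)
    if (maskDiag) diag(logits) <- -Inf
    P <- softmaxRows(logits)
    R <- if (mu > 0) P + mu * A else P
    rs <- rowSums(R)
    S <- R / rs
    O <- S %*% V
    heads[[t]] <- list(Q = Q, K = K, V = V, P = P, S = S, rs = rs)
    Smaps[[t]] <- S
    Cc[[t]] <- O
  }
  C <- do.call(cbind, Cc)
  if (identityV) {
    Xout <- layer$gamma * C + layer$beta
    return(list(X_out = Xout, S_heads = Smaps,
                cache = list(X = X, heads = heads, C = C, blocks = blocks,
                             mu = mu, maskDiag = maskDiag, d = d,
                             identityV = TRUE)))
  }
  Xatt <- C %*% layer$Wo
  pre <- sweep(Xatt %*% layer$W1, 2L, layer$b1, "+")
  Hf <- elu(pre)
  Xout <- Xatt + sweep(Hf %*% layer$W2, 2L, layer$b2, "+")
  list(X_out = Xout, S_heads = Smaps,
       cache = list(X = X, heads = heads, C = C, Xatt = Xatt,
                    pre = pre, Hf = Hf, mu = mu, maskDiag = maskDiag,
                    d = d, identityV = FALSE))
}

# backward through one encoder unit.
# dXout: gradient at the unit output. Returns gradient at the unit input
# plus parameter gradients (same shapes as `layer`).
.attentionLayerBackward <- function(dXout, layer, cache) {
  identityV <- isTRUE(cache$identityV)
  if (identityV) {
    dgamma <- rowSums(dXout * cache$C)
    dbeta <- rowSums(dXout)
    dC <- dXout * layer$gamma
  } else {
    Hf <- cache$Hf
    dW2 <- crossprod(Hf, dXout)
    db2 <- colSums(dXout)
    dHf <- tcrossprod(dXout, layer$W2)
    dpre <- dHf * eluGrad(cache$pre)
    dW1 <- crossprod(cache$Xatt, dpre)
    db1 <- colSums(dpre)
    dXatt <- dXout + tcrossprod(dpre, layer$W1)   # residual + FFN path
    dWo <- crossprod(cache$C, dXatt)
    dC <- tcrossprod(dXatt, layer$Wo)
  }
  d <- cache$d
  nH <- length(cache$heads)
  dX <- matrix(0, nrow(cache$X), ncol(cache$X))
  gHeads <- vector("list", nH)
  colAt <- 0L
  for (t in seq_len(nH)) {
    hc <- cache$heads[[t]]
    h <- layer$heads[[t]]
    wV <- ncol(hc$V)
    cols <- (colAt + 1L):(colAt + wV)
    colAt <- colAt + wV
    dO <- dC[, cols, drop = FALSE]
    dS <- tcrossprod(dO, hc$V)
    dV <- crossprod(hc$S, dO)
    # row renormalisation backward: S = R / rowSums(R)
    dR <- (dS - rowSums(dS * hc$S)) / hc$rs
    # + mu*A is constant in R's gradient w.r.t. P
    dP <- dR
    # softmax backward (masked entries have P = 0 and drop out)
    dlog <- hc$P * (dP - rowSums(dP * hc$P))
    dQ <- dlog %*% hc$K / sqrt(d)
    dK <- crossprod(dlog, hc$Q) / sqrt(d)
    gHeads[[t]] <- list(Wq = crossprod(cache$X, dQ),
                        Wk = crossprod(cache$X, dK))
    dX <- dX + tcrossprod(dQ, h$Wq) + tcrossprod(dK, h$Wk)
    if (identityV) {
      dX[, cache$blocks[[t]]] <- dX[, cache$blocks[[t]]] + dV
    } else {
      gHeads[[t]]$Wv <- crossprod(cache$X, dV)
      dX <- dX + tcrossprod(dV, h$Wv)
    }
  }
  grads <- list(heads = gHeads)
  if (identityV) {
    grads$gamma <- dgamma; grads$beta <- dbeta
  } else {
    grads$Wo <- dWo; grads$W1 <- dW1; grads$b1 <- db1
    grads$W2 <- dW2; grads$b2 <- db2
  }
  list(dX = dX, grads = grads)
}

#' Transformer forward pass
#'
#' Adds the positional encoding to the input (injection at layer 0) and
#' applies the encoder units in sequence.
#'
#' @param X1 original M x N expression (log scale).
#' @param params from [initTransformerParams()].
#' @param P optional M x N positional encoding.
#' @param A,mode,mu,maskDiag see [attentionLayer()].
#' @return list with `X2` (augmented expression), `S_heads` (list of
#'   layers, each a list of per-head M x M maps) and per-layer caches.
#' @export
transformerForward <- function(X1, params, P = NULL, A = NULL,
                               mode = c("finetune", "pretrain"),
                               mu = 0.2, maskDiag = TRUE) {
  mode <- match.arg(mode)
  X <- if (is.null(P)) X1 else X1 + P
  Sh <- vector("list", length(params$layers))
  caches <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    out <- attentionLayer(X, params$layers[[l]], A = A, mode = mode,
                          mu = mu, maskDiag = maskDiag)
    X <- out$X_out
    Sh[[l]] <- out$S_heads
    caches[[l]] <- out$cache
  }
  list(X2 = X, S_heads = Sh, caches = caches)
}

#' Aggregate attention maps into the gene-gene network
#'
#' The aggregated network is the arithmetic mean of every per-layer,
#' per-head attention map; `denom = "printed"` instead divides their sum
#' by `nHeads + (nLayers - 1)`.  The two choices differ by a positive
#' global scale only, so every downstream edge ranking is identical.
#'
#' @param S_heads nested list as returned by [transformerForward()].
#' @param geneIds gene identifiers for the rows/columns.
#' @param denom `"mean"` (default) or `"printed"`.
#' @param zeroDiag zero the diagonal for downstream edge ranking
#'   (default TRUE).
#' @return an [AttentionNetwork-class].
#' @export
aggregateAttention <- function(S_heads, geneIds,
                               denom = c("mean", "printed"),
                               zeroDiag = TRUE) {
  denom <- match.arg(denom)
  if (!length(S_heads) || !length(S_heads[[1L]]))
    stop("need at least one computed attention layer")
  flat <- unlist(S_heads, recursive = FALSE)
  S <- Reduce(`+`, flat)
  nL <- length(S_heads)
  nH <- length(S_heads[[1L]])
  S <- switch(denom,
              mean = S / length(flat),
              printed = S / (nH + (nL - 1L)))
  if (zeroDiag) diag(S) <- 0
  new("AttentionNetwork", S = S, geneIds = as.character(geneIds),
      nLayers = as.integer(nL), nHeads = as.integer(nH))
}
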