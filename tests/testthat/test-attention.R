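test_that("SVD positional encodings reconstruct as the theory says", {
  # identity: exact reconstruction at full rank
  A <- diag(4)
  pe <- svdPositionalEncoding(A, 4, N = 6)
  expect_equal(pe$Utilde %*% t(pe$Vtilde), A, tolerance = 1e-12)
  expect_equal(dim(pe$P), c(4L, 6L))
  # rank-1 matrix at r = 1: zero reconstruction error
  u <- c(1, 2, 3); v <- c(2, 0, 1)
  A1 <- u %*% t(v)
  pe1 <- svdPositionalEncoding(A1, 1, N = 5)
  expect_equal(pe1$Utilde %*% t(pe1$Vtilde), A1, tolerance = 1e-10)
  # random symmetric 6x6 at r = 3: error = rms of discarded singular values
  set.seed(8)
  S6 <- matrix(rnorm(36), 6, 6); S6 <- S6 + t(S6)
  pe3 <- svdPositionalEncoding(S6, 3, N = 4)
  resid <- sqrt(sum((S6 - pe3$Utilde %*% t(pe3$Vtilde))^2))
  sv <- svd(S6)$d
  expect_equal(resid, sqrt(sum(sv[4:6]^2)), tolerance = 1e-10)
  expect_error(svdPositionalEncoding(S6, 7, N = 4), "exceeds")
})

test_that("attention rows are stochastic and reduce to uniform at zero weights", {
  set.seed(14)
  M <- 6; N <- 10
  X <- matrix(rnorm(M * N), M, N)
  pars <- initTransformerParams(M, N, nLayers = 1, nHeads = 2, dHead = 3,
                                valueMode = "learned")
  ly <- pars$layers[[1]]
  # zero W_Q/W_K, no masking: every row uniform 1/M
  ly0 <- ly
  for (t in seq_along(ly0$heads)) {
    ly0$heads[[t]]$Wq[] <- 0; ly0$heads[[t]]$Wk[] <- 0
  }
  out0 <- attentionLayer(X, ly0, mode = "finetune", maskDiag = FALSE)
  for (Sh in out0$S_heads)
    expect_equal(Sh, matrix(1 / M, M, M), tolerance = 1e-12)
  # arbitrary weights: rows sum to one
  out <- attentionLayer(X, ly, mode = "finetune", maskDiag = TRUE)
  for (Sh in out$S_heads) {
    expect_equal(rowSums(Sh), rep(1, M), tolerance = 1e-10)
    expect_equal(diag(Sh), rep(0, M))   # masked diagonal
  }
})

test_that("3-gene attention matches a hand-computed softmax table", {
  X <- matrix(c(1, 0, 0,
                0, 1, 0), 3, 2)   # M=3 genes, N=2 spots
  pars <- initTransformerParams(3, 2, nLayers = 1, nHeads = 1, dHead = 2,
                                valueMode = "learned")
  ly <- pars$layers[[1]]
  ly$heads[[1]]$Wq <- diag(2)
  ly$heads[[1]]$Wk <- diag(2)
  out <- attentionLayer(X, ly, mode = "finetune", maskDiag = FALSE)
  logits <- (X %*% diag(2)) %*% t(X %*% diag(2)) / sqrt(2)
  hand <- t(apply(logits, 1, function(r) exp(r) / sum(exp(r))))
  expect_equal(out$S_heads[[1]], hand, tolerance = 1e-12)
})

test_that("pretrain mode biases attention toward the prior", {
  set.seed(15)
  M <- 5; N <- 8
  X <- matrix(rnorm(M * N), M, N)
  A <- matrix(0, M, M); A[1, 2] <- A[2, 1] <- 1
  pars <- initTransformerParams(M, N, nLayers = 1, nHeads = 1, dHead = 2)
  ly <- pars$layers[[1]]
  # large mu: S ranking converges to A's ranking
  big <- attentionLayer(X, ly, A = A, mode = "pretrain", mu = 1e4)
  S <- big$S_heads[[1]]
  expect_equal(which.max(S[1, ]), 2L)
  expect_equal(which.max(S[2, ]), 1L)
  # finetune mode ignores mu entirely
  ft <- attentionLayer(X, ly, A = A, mode = "finetune", mu = 1e4)
  ft2 <- attentionLayer(X, ly, mode = "finetune")
  expect_equal(ft$S_heads, ft2$S_heads)
  expect_error(attentionLayer(X, ly, mode = "pretrain", mu = 0.2), "requires A")
})

test_that("identity-value mode concatenates blocks back to M x N", {
  set.seed(16)
  M <- 5; N <- 11
  X <- matrix(rnorm(M * N), M, N)
  pars <- initTransformerParams(M, N, nLayers = 2, nHeads = 3, dHead = 2,
                                valueMode = "identity")
  fw <- transformerForward(X, pars, mode = "finetune")
  expect_equal(dim(fw$X2), c(M, N))
  # with gamma=1, beta=0 at init the output is exactly the blockwise
  # attention mixture of the input
  ly <- pars$layers[[1]]
  out <- attentionLayer(X, ly, mode = "finetune")
  blocks <- regatta:::.headBlocks(N, 3)
  manual <- do.call(cbind, lapply(1:3, function(t)
    out$S_heads[[t]] %*% X[, blocks[[t]], drop = FALSE]))
  expect_equal(out$X_out, manual, tolerance = 1e-12)
})

test_that("aggregation is the arithmetic mean and scale cannot reorder edges", {
  M <- 4
  mk <- function(v) matrix(v, M, M)
  heads <- list(list(mk(1), mk(2)), list(mk(3), mk(6)))  # 2 layers x 2 heads
  net <- aggregateAttention(heads, paste0("g", 1:M), zeroDiag = FALSE)
  expect_equal(unname(attentionMatrix(net)), mk(3))
  # single layer, single head: S equals that head's map
  one <- aggregateAttention(list(list(mk(7))), paste0("g", 1:M),
                            zeroDiag = FALSE)
  expect_equal(unname(attentionMatrix(one)), mk(7))
  # two identical maps: mean equals either
  two <- aggregateAttention(list(list(mk(4), mk(4))), paste0("g", 1:M),
                            zeroDiag = FALSE)
  expect_equal(unname(attentionMatrix(two)), mk(4))
  # printed denominator differs only by a positive global scale:
  # the ranked edge list is unchanged
  set.seed(31)
  rnd <- list(lapply(1:3, function(i) matrix(runif(M * M), M, M)),
              lapply(1:3, function(i) matrix(runif(M * M), M, M)))
  a <- attentionMatrix(aggregateAttention(rnd, paste0("g", 1:M)))
  b <- attentionMatrix(aggregateAttention(rnd, paste0("g", 1:M),
                                          denom = "printed"))
  expect_equal(order(a), order(b))
  expect_gt(cor(as.vector(a), as.vector(b)), 1 - 1e-12)
})
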