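# shared fixtures, all built in code at test time

# tiny deterministic expression container
makeTinySE <- function(M = 6, N = 9, seed = 101, logged = FALSE) {
  set.seed(seed)
  x <- matrix(rpois(M * N, 8), M, N,
              dimnames = list(sprintf("G%02d", 1:M), sprintf("s%02d", 1:N)))
  side <- ceiling(sqrt(N))
  co <- cbind(x = rep(seq_len(side), length.out = N),
              y = rep(seq_len(side), each = side)[seq_len(N)])
  se <- SpatialExpression(x, co, isLog = logged)
  se
}

# small two-TF planted network with an explicit activity pattern
makeTinyGRN <- function() {
  edges <- data.frame(
    regulator = c("TF1", "TF1", "TF2", "TF2"),
    target = c("G03", "G04", "G05", "G06"),
    sign = c(1, 1, 1, -1))
  act <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("TF1", "TF2"), NULL))
  PlantedGRN(edges, tfs = c("TF1", "TF2"),
             genes = c("TF1", "TF2", sprintf("G%02d", 3:6)), tfActivity = act)
}

# independent brute-force MMD (double loops, Gaussian kernel as printed)
bruteMMD <- function(X, Y) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1)
  n <- ncol(X); m <- ncol(Y)
  kern <- function(a, b) exp(-sum((a - b)^2) / 2)
  s1 <- 0; for (i in 1:n) for (j in 1:n) s1 <- s1 + kern(X[, i], X[, j])
  s2 <- 0; for (i in 1:m) for (j in 1:m) s2 <- s2 + kern(Y[, i], Y[, j])
  s3 <- 0; for (i in 1:n) for (j in 1:m) s3 <- s3 + kern(X[, i], Y[, j])
  s1 / n^2 + s2 / m^2 - 2 * s3 / (n * m)
}

# brute-force Moran's I by explicit double sum
bruteMoran <- function(x, W) {
  n <- length(x)
  xc <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * xc[i] * xc[j]
  (n / sum(W)) * num / sum(xc^2)
}

# brute-force AUROC/AUPRC by exhaustive threshold sweep
bruteROC <- function(score, y) {
  ths <- sort(unique(score), decreasing = TRUE)
  P <- sum(y); Ng <- sum(!y)
  tpr <- c(0); fpr <- c(0); prec <- c()
  recs <- c(0)
  for (t in ths) {
    pred <- score >= t
    tpr <- c(tpr, sum(pred & y) / P)
    fpr <- c(fpr, sum(pred & !y) / Ng)
    prec <- c(prec, sum(pred & y) / sum(pred))
    recs <- c(recs, sum(pred & y) / P)
  }
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  prec2 <- c(prec[1], prec)
  auprc <- sum(diff(recs) * (head(prec2, -1) + tail(prec2, -1)) / 2)
  list(auroc = auroc, auprc = auprc)
}

# brute-force recovery-curve AUC for one spot / one gene set
bruteAUCell <- function(exprVec, geneIds, members, frac) {
  M <- length(exprVec)
  Tcut <- ceiling(frac * M)
  ord <- order(-exprVec, geneIds)
  ranked <- geneIds[ord]
  cum <- cumsum(ranked %in% members)[seq_len(Tcut)]
  best <- cumsum(rep(1, Tcut))
  best[best > length(members)] <- length(members)
  sum(cum) / sum(best)
}

# quick fitted model on a small synthetic dataset (cached per session)
fitSmall <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    syn <- simulateSRTDataset(nGenes = 12, nTFs = 3, nSpots = 100,
                              cellsPerSpot = 3, seed = 5)
    se <- preprocessExpression(syn@experiment)
    fit <- fineTune(se, trainConfig(mode = "finetune", max_epochs = 15,
                                    seed = 5, k = 6, warmup_steps = 5))
    cache <<- list(syn = syn, se = se, fit = fit)
    cache
  }
})
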