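# The analytic backward pass is the package's engine; verify it against
# central finite differences of the full objective on a small model, for
# both attention value paths.

fdCheck <- function(valueMode, nprobe = 4, tol = 1e-4) {
  set.seed(42)
  M <- 5; N <- 12
  cfg <- trainConfig(mode = "pretrain", nLayers = 2, nHeads = 2, dHead = 3,
                     ffDim = 4, hidden = 6, latent = 2, peRank = 2, k = 3,
                     alpha = 0.7, lambda1 = 0.8, lambda2 = 0.3, mu = 0.2,
                     valueMode = valueMode)
  X1 <- matrix(abs(rnorm(M * N)), M, N,
               dimnames = list(paste0("g", 1:M), paste0("s", 1:N)))
  co <- cbind(runif(N), runif(N))
  g <- buildSpatialGraph(spotPCA(X1, 4), knnNeighbors(co, 3))
  A <- matrix(runif(M * M), M, M); A <- (A + t(A)) / 2; diag(A) <- 0
  A <- A / max(A)
  mdl <- regatta:::.initModel(X1, g, cfg, A = A)
  params <- mdl$params
  params$Z <- params$Z + matrix(rnorm(N * N, sd = 0.05), N, N)
  eps <- list(e1 = matrix(rnorm(cfg$latent * N), cfg$latent, N),
              e2 = matrix(rnorm(cfg$latent * N), cfg$latent, N))
  fw <- regatta:::gtlForward(params, mdl$const, cfg, eps)
  gr <- regatta:::gtlBackward(params, mdl$const, cfg, fw)
  lossAt <- function(p) regatta:::gtlForward(p, mdl$const, cfg, eps)$losses$total
  h <- 1e-6
  # walk the parameter tree and probe random entries of every leaf
  probe <- function(getter, setter, gleaf) {
    leaf <- getter(params)
    for (i in sample(length(leaf), min(nprobe, length(leaf)))) {
      pp <- params; l <- leaf; l[i] <- l[i] + h; pp <- setter(pp, l)
      fp <- lossAt(pp)
      pp <- params; l <- leaf; l[i] <- l[i] - h; pp <- setter(pp, l)
      fm <- lossAt(pp)
      num <- (fp - fm) / (2 * h)
      # relative error with an absolute floor: finite differences carry
      # ~1e-9 cancellation noise on a loss of order 50
      rel <- abs(num - gleaf[i]) / max(abs(num), abs(gleaf[i]), 1e-3)
      expect_lt(rel, tol, label = sprintf("analytic-vs-FD rel err [%d]", i))
    }
  }
  probe(function(p) p$Z, function(p, l) { p$Z <- l; p }, gr$Z)
  probe(function(p) p$Wpe, function(p, l) { p$Wpe <- l; p }, gr$Wpe)
  for (nm in c("W1", "Wmu", "Wlv", "W3", "W4", "b1", "b3"))
    probe(function(p) p$vae[[nm]],
          function(p, l) { p$vae[[nm]] <- l; p }, gr$vae[[nm]])
  probe(function(p) p$tr$layers[[1]]$heads[[1]]$Wq,
        function(p, l) { p$tr$layers[[1]]$heads[[1]]$Wq <- l; p },
        gr$tr$layers[[1]]$heads[[1]]$Wq)
  probe(function(p) p$tr$layers[[2]]$heads[[2]]$Wk,
        function(p, l) { p$tr$layers[[2]]$heads[[2]]$Wk <- l; p },
        gr$tr$layers[[2]]$heads[[2]]$Wk)
  if (valueMode == "identity") {
    probe(function(p) p$tr$layers[[1]]$gamma,
          function(p, l) { p$tr$layers[[1]]$gamma <- l; p },
          gr$tr$layers[[1]]$gamma)
    probe(function(p) p$tr$layers[[2]]$beta,
          function(p, l) { p$tr$layers[[2]]$beta <- l; p },
          gr$tr$layers[[2]]$beta)
  } else {
    probe(function(p) p$tr$layers[[1]]$heads[[2]]$Wv,
          function(p, l) { p$tr$layers[[1]]$heads[[2]]$Wv <- l; p },
          gr$tr$layers[[1]]$heads[[2]]$Wv)
    probe(function(p) p$tr$layers[[1]]$Wo,
          function(p, l) { p$tr$layers[[1]]$Wo <- l; p },
          gr$tr$layers[[1]]$Wo)
    probe(function(p) p$tr$layers[[2]]$W1,
          function(p, l) { p$tr$layers[[2]]$W1 <- l; p },
          gr$tr$layers[[2]]$W1)
    probe(function(p) p$tr$layers[[1]]$b2,
          function(p, l) { p$tr$layers[[1]]$b2 <- l; p },
          gr$tr$layers[[1]]$b2)
  }
  invisible(fw)
}

test_that("analytic gradients match finite differences (identity values)", {
  fw <- fdCheck("identity")
  # while we are here: the logged components recombine to the total
  comps <- fw$losses
  expect_equal(comps$total,
               totalLoss(comps[c("elbo1", "elbo2", "manifold", "align_gd",
                                 "align_sld", "contrastive")],
                         0.8, 0.3), tolerance = 1e-10)
})

test_that("analytic gradients match finite differences (learned values)", {
  fdCheck("learned")
})

test_that("every loss component is non-negative along a training run", {
  fs <- fitSmall()
  ll <- lossLog(fs$fit)
  for (cmp in c("elbo1", "elbo2", "manifold", "align_gd", "align_sld",
                "contrastive"))
    expect_true(all(ll[[cmp]] >= 0), label = cmp)
  expect_equal(ll$total,
               ll$elbo1 + ll$elbo2 + fs$fit@config$lambda1 * ll$manifold +
                 fs$fit@config$lambda2 *
                   (ll$contrastive + ll$align_gd + ll$align_sld),
               tolerance = 1e-8)
})
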