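#' Training configuration
#'
#' Collects every tunable of the joint model in one validated list.
#' Defaults follow the reference architecture (3 encoder units, 5 heads,
#' hidden 128, latent 10, Adam with decoupled weight decay at learning
#' rate 1e-3 under a linear-with-warmup schedule, token size 3000,
#' prior-constraint weight mu = 0.2 in pretraining and 0 in fine-tuning).
#'
#' @param mode `"finetune"` or `"pretrain"`.
#' @param learning_rate Adam learning rate (> 0).
#' @param warmup_steps linear warmup length in steps.
#' @param max_epochs maximum optimisation steps (full-batch, one step per
#'   epoch).
#' @param token_size spots per token dataset in pretraining (>= 2).
#' @param seed integer seed; every random draw of a run flows from it.
#' @param lambda1,lambda2 loss weights of the manifold constraint and the
#'   cross-dimension block.
#' @param alpha spatial-influence coefficient of the manifold constraint.
#' @param mu prior-constraint weight; forced to 0 in fine-tuning mode.
#' @param weight_decay decoupled weight decay on weight matrices.
#' @param scaleGenes standardize each gene row (z-score) of the model
#'   input before training (default TRUE); removes amplitude offsets so
#'   the attention mixture chases shape, not level.
#' @param nLayers,nHeads,dHead,ffDim transformer architecture.
#' @param valueMode attention value path: `"identity"` (head outputs are
#'   attention mixtures of the genes' own expression; the default, which
#'   makes the aggregated S an interpretable gene-mixing operator) or
#'   `"learned"` (per-head value projections + output projection +
#'   feed-forward sublayer).
#' @param hidden,latent autoencoder widths.
#' @param peRank truncation rank of the SVD positional encodings.
#' @param maskDiag mask self-attention logits (see [attentionLayer()]).
#' @param includeInput include the views themselves (layer-0
#'   representations) in the contrastive and alignment sums, anchoring
#'   the augmented view directly to the original (default TRUE).
#' @param k,nPcs,similarity spatial-graph construction (see
#'   [spatialGraph()]).
#' @param tol,patience convergence: stop when the relative total-loss
#'   change stays below `tol` for `patience` consecutive steps.
#' @param sTol pretraining: stop when the relative Frobenius change of S
#'   between passes drops below this.
#' @param maxPasses pretraining: maximum shuffled passes over the tokens.
#' @return a validated config list of class `"trainConfig"`.
#' @export
trainConfig <- function(mode = c("finetune", "pretrain"),
                        learning_rate = 1e-3, warmup_steps = 20L,
                        max_epochs = 300L, token_size = 3000L, seed = 1L,
                        lambda1 = 1, lambda2 = 1, alpha = 1, mu = 0.2,
                        weight_decay = 1e-4, scaleGenes = TRUE,
                        nLayers = 1L, nHeads = 5L, dHead = 8L, ffDim = 32L,
                        valueMode = c("identity", "learned"),
                        hidden = 128L, latent = 10L, peRank = 8L,
                        maskDiag = TRUE, includeInput = TRUE,
                        k = 10L, nPcs = 50L,
                        similarity = "distance",
                        tol = 1e-4, patience = 20L,
                        sTol = 1e-3, maxPasses = 5L) {
  mode <- match.arg(mode)
  valueMode <- match.arg(valueMode)
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (token_size < 2L) stop("token_size must be at least 2")
  if (nHeads < 1L || dHead < 1L) stop("need nHeads >= 1 and dHead >= 1")
  if (mode == "finetune") mu <- 0
  cfg <- list(mode = mode, learning_rate = learning_rate,
              warmup_steps = as.integer(warmup_steps),
              max_epochs = as.integer(max_epochs),
              token_size = as.integer(token_size), seed = as.integer(seed),
              lambda1 = lambda1, lambda2 = lambda2, alpha = alpha, mu = mu,
              weight_decay = weight_decay, scaleGenes = isTRUE(scaleGenes),
              nLayers = as.integer(nLayers), nHeads = as.integer(nHeads),
              dHead = as.integer(dHead), ffDim = as.integer(ffDim),
              valueMode = valueMode,
              hidden = as.integer(hidden), latent = as.integer(latent),
              peRank = as.integer(peRank), maskDiag = isTRUE(maskDiag),
              includeInput = isTRUE(includeInput),
              k = as.integer(k), nPcs = as.integer(nPcs),
              similarity = similarity,
              tol = tol, patience = as.integer(patience), sTol = sTol,
              maxPasses = as.integer(maxPasses))
  class(cfg) <- "trainConfig"
  cfg
}

# per-gene z-score of the model input; constant rows are left centred
.scaleRows <- function(X) {
  mu <- rowMeans(X)
  sd <- apply(X, 1L, sd)
  sd[sd == 0] <- 1
  (X - mu) / sd
}

.deriveSeed <- function(seed, tag) {
  as.integer((as.double(seed) * 7919 + tag * 104729) %% 2147483629)
}

# evaluate expr under its own temporary RNG stream, restoring the caller's
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  set.seed(seed)
  on.exit(if (had) assign(".Random.seed", old, envir = env)
          else rm(".Random.seed", envir = env))
  expr
}

# assemble the fixed tensors + freshly initialised parameters for one
# dataset.  Weight initialisation consumes the current RNG stream.
.initModel <- function(X1, graph, cfg, A = NULL) {
  M <- nrow(X1); N <- ncol(X1)
  Bd <- as.matrix(graph@B)
  IaB <- diag(N) + cfg$alpha * Bd
  const <- list(X1 = X1, A = A, B = Bd, IaB = IaB,
                pairW = .neighborPairWeights(graph@neighbors, N),
                peBasis = NULL)
  params <- list(tr = list(layers = initTransformerParams(
                   M, N, cfg$nLayers, cfg$nHeads, cfg$dHead,
                   cfg$ffDim, cfg$valueMode)$layers),
                 vae = initVAEParams(M, cfg$hidden, cfg$latent))
  params$vae$hidden <- NULL
  params$vae$latent <- NULL
  if (!is.null(A)) {
    r <- min(cfg$peRank, M)
    pe <- svdPositionalEncoding(A, r, N = N)
    const$peBasis <- cbind(pe$Utilde, pe$Vtilde)
    params$Wpe <- pe$W
  }
  params$Z <- IaB           # the manifold loss's fixed point
  list(params = params, const = const)
}

.lrAt <- function(step, cfg) {
  w <- max(cfg$warmup_steps, 1L)
  total <- max(cfg$max_epochs, w + 1L)
  if (step <= w) return(cfg$learning_rate * step / w)
  cfg$learning_rate * max(0, (total - step) / (total - w))
}

# one AdamW step, recursing over the parameter tree in place
.adamStep <- function(params, grads, state, lr, wd, path = "") {
  if (is.list(params)) {
    nm <- names(params)
    for (i in seq_along(params)) {
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      g <- if (!is.null(nm) && nzchar(nm[i])) grads[[nm[i]]] else grads[[i]]
      sub <- .adamStep(params[[i]], g, state,
                       lr, wd, paste0(path, ".", key))
      params[[i]] <- sub$p
      state <- sub$state
    }
    return(list(p = params, state = state))
  }
  m <- state$m[[path]]; v <- state$v[[path]]
  if (is.null(m)) { m <- params * 0; v <- params * 0 }
  m <- 0.9 * m + 0.1 * grads
  v <- 0.999 * v + 0.001 * grads^2
  t <- state$t
  mhat <- m / (1 - 0.9^t)
  vhat <- v / (1 - 0.999^t)
  decay <- if (is.matrix(params) && !grepl("\\.Z$|\\.b", path)) wd else 0
  params <- params - lr * (mhat / (sqrt(vhat) + 1e-8) + decay * params)
  state$m[[path]] <- m
  state$v[[path]] <- v
  list(p = params, state = state)
}

# core optimisation loop shared by fine-tuning and per-token pretraining
.optimise <- function(params, const, cfg, maxSteps, logEvery = 1L,
                      state = NULL, stepOffset = 0L) {
  if (is.null(state)) state <- list(m = list(), v = list(), t = 0L)
  M <- nrow(const$X1); N <- ncol(const$X1)
  log <- vector("list", maxSteps)
  prevTotal <- NA_real_
  calm <- 0L
  lastGood <- params
  steps <- 0L
  for (step in seq_len(maxSteps)) {
    eps <- list(e1 = matrix(rnorm(cfg$latent * N), cfg$latent, N),
                e2 = matrix(rnorm(cfg$latent * N), cfg$latent, N))
    fw <- gtlForward(params, const, cfg, eps)
    tot <- fw$losses$total
    if (!is.finite(tot)) {
      warning("non-finite loss at step ", step,
              "; aborting with the last good parameters")
      params <- lastGood
      break
    }
    lastGood <- params
    gr <- gtlBackward(params, const, cfg, fw)
    state$t <- state$t + 1L
    lr <- .lrAt(stepOffset + step, cfg)
    upd <- .adamStep(params, gr, state, lr, cfg$weight_decay)
    params <- upd$p
    state <- upd$state
    log[[step]] <- data.frame(step = stepOffset + step,
                              elbo1 = fw$losses$elbo1,
                              elbo2 = fw$losses$elbo2,
                              manifold = fw$losses$manifold,
                              align_gd = fw$losses$align_gd,
                              align_sld = fw$losses$align_sld,
                              contrastive = fw$losses$contrastive,
                              total = tot, lr = lr)
    steps <- step
    if (!is.na(prevTotal)) {
      rel <- abs(tot - prevTotal) / max(abs(prevTotal), 1e-12)
      calm <- if (rel < cfg$tol) calm + 1L else 0L
      if (calm >= cfg$patience) { prevTotal <- tot; break }
    }
    prevTotal <- tot
  }
  list(params = params, state = state,
       log = do.call(rbind, log[seq_len(steps)]))
}

# deterministic (noise-free) forward used to read out S and the final
# representations after training
.inferenceForward <- function(params, const, cfg) {
  N <- ncol(const$X1)
  eps0 <- list(e1 = matrix(0, cfg$latent, N), e2 = matrix(0, cfg$latent, N))
  gtlForward(params, const, cfg, eps0)
}

#' Fine-tune the joint model on one dataset
#'
#' Minimises the overall objective with the prior-constraint weight mu
#' fixed at zero, returning the aggregated attention network S, the
#' learned spot graph Z, and the per-step loss report.  With
#' `config$max_epochs = 0` the initial parameters are returned unchanged
#' (S and Z read off the initialisation).
#'
#' @param x a log-transformed [SpatialExpression-class], or a plain
#'   genes x spots matrix when `graph` is supplied.
#' @param config a [trainConfig()] with `mode = "finetune"`.
#' @param graph optional precomputed [SpatialGraph-class]; built from the
#'   stored coordinates otherwise.
#' @param prior optional prior adjacency (M x M) used only for the SVD
#'   positional encodings in fine-tuning.
#' @param checkpoint optional [loadCheckpoint()] result whose parameters
#'   (matching in dimensions) are copied as initial values.
#' @return a [GTLFit-class].
#' @export
fineTune <- function(x, config = trainConfig(mode = "finetune"),
                     graph = NULL, prior = NULL, checkpoint = NULL) {
  if (config$mode != "finetune") stop("config$mode must be 'finetune'")
  if (is(x, "SpatialExpression")) {
    if (!isLogged(x))
      stop("fine-tuning expects log-transformed input; run preprocessExpression()")
    X1 <- exprValues(x)
    if (is.null(graph))
      graph <- spatialGraph(x, k = config$k, nPcs = config$nPcs,
                            similarity = config$similarity)
  } else {
    X1 <- as.matrix(x)
    if (is.null(graph)) stop("supply a SpatialGraph when x is a matrix")
  }
  geneIds <- rownames(X1)
  spotIds <- colnames(X1)
  if (isTRUE(config$scaleGenes)) X1 <- .scaleRows(X1)
  set.seed(.deriveSeed(config$seed, 1L))   # weight-init + noise stream
  mdl <- .initModel(X1, graph, config, A = prior)
  if (!is.null(checkpoint)) {
    old <- checkpoint$params
    if (!identical(treeShapes(old), treeShapes(mdl$params)))
      stop("checkpoint parameter shapes do not match this dataset")
    mdl$params <- old
  }
  opt <- if (config$max_epochs > 0L)
    .optimise(mdl$params, mdl$const, config, config$max_epochs)
  else list(params = mdl$params, state = NULL, log = NULL)
  fw <- .inferenceForward(opt$params, mdl$const, config)
  net <- aggregateAttention(fw$S_heads, geneIds)
  lg <- if (is.null(opt$log))
    data.frame(step = integer(), elbo1 = numeric(), elbo2 = numeric(),
               manifold = numeric(), align_gd = numeric(),
               align_sld = numeric(), contrastive = numeric(),
               total = numeric(), lr = numeric())
  else opt$log
  new("GTLFit", params = opt$params, config = unclass(config),
      network = net,
      manifold = new("ManifoldGraph", Z = opt$params$Z,
                     alpha = config$alpha),
      graph = graph, lossLog = lg,
      geneIds = as.character(geneIds), spotIds = as.character(spotIds))
}

# shapes of every leaf, for checkpoint compatibility checks
treeShapes <- function(a) {
  if (is.list(a)) return(lapply(a, treeShapes))
  dim(a) %||% length(a)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition spots into token datasets
#'
#' Chunks the (optionally pre-shuffled) spot indices into consecutive
#' groups of `tokenSize`, the last group taking the remainder, so that
#' every spot is covered exactly once.
#'
#' @param n number of spots, or a vector of spot indices to chunk in the
#'   given order.
#' @param tokenSize spots per token.
#' @return list of integer index vectors.
#' @examples
#' lengths(tokenPartition(70, 30))   # 30 30 10
#' @export
tokenPartition <- function(n, tokenSize) {
  idx <- if (length(n) == 1L) seq_len(n) else as.integer(n)
  if (tokenSize < 2L) stop("tokenSize must be at least 2")
  unname(split(idx, ceiling(seq_along(idx) / tokenSize)))
}

#' Pretrain on a list of slices
#'
#' Token-batched training with the prior-network constraint active
#' (mu > 0): each slice is partitioned into token datasets covering all
#' its spots, the model is trained to convergence on each token in turn
#' with parameters carried forward, and after every full pass the token
#' order is reshuffled and training repeats until the aggregated network
#' S stabilises (relative Frobenius change below `config$sTol`) or
#' `config$maxPasses` is reached.  Because the spot-side projection
#' widths are token-size-dependent, a ragged final token is filled up to
#' `token_size` by resampling its own spots.
#'
#' @param slices list of log-transformed [SpatialExpression-class]
#'   objects (or lists with elements `X` and `coords`).
#' @param config a [trainConfig()] with `mode = "pretrain"`.
#' @param prior prior adjacency list as from [readPriorNetwork()] (or the
#'   M x M matrix itself); required when `config$mu > 0`.
#' @return a checkpoint list with elements `params`, `config`, `S`
#'   (final [AttentionNetwork-class]), `passes` and `sDelta` (relative
#'   change of S per pass).
#' @export
pretrainGTL <- function(slices, config = trainConfig(mode = "pretrain"),
                        prior = NULL) {
  if (config$mode != "pretrain") stop("config$mode must be 'pretrain'")
  if (!length(slices)) stop("empty slice list")
  A <- if (is.list(prior) && !is.null(prior$A)) prior$A else prior
  if (config$mu > 0 && is.null(A))
    stop("pretraining with mu > 0 requires a prior network")
  bundles <- lapply(slices, function(s) {
    if (is(s, "SpatialExpression"))
      list(X = exprValues(s), coords = spotCoords(s))
    else list(X = as.matrix(s$X), coords = as.matrix(s$coords))
  })
  geneIds <- rownames(bundles[[1L]]$X)
  tokSeed <- .deriveSeed(config$seed, 2L)   # data-order stream
  set.seed(.deriveSeed(config$seed, 1L))    # weight-init + noise stream
  params <- NULL
  state <- NULL
  Sprev <- NULL
  sDelta <- numeric()
  passes <- 0L
  lastNet <- NULL
  for (pass in seq_len(config$maxPasses)) {
    tokens <- list()
    for (si in seq_along(bundles)) {
      b <- bundles[[si]]
      # shuffle spot order from the dedicated data-order stream so the
      # weight/noise stream is untouched (seed isolation)
      shuffled <- .withSeed(.deriveSeed(tokSeed, pass * 131L + si),
                            sample.int(ncol(b$X)))
      for (idx in tokenPartition(shuffled, config$token_size))
        tokens[[length(tokens) + 1L]] <- list(slice = si, idx = idx)
    }
    for (tk in tokens) {
      b <- bundles[[tk$slice]]
      idx <- tk$idx
      if (length(idx) < config$token_size && !is.null(params)) {
        extra <- idx[1L + (seq_len(config$token_size - length(idx)) - 1L) %%
                       length(idx)]
        idx <- c(idx, extra)
      }
      X <- b$X[, idx, drop = FALSE]
      if (isTRUE(config$scaleGenes)) X <- .scaleRows(X)
      colnames(X) <- make.unique(colnames(X))
      co <- b$coords[idx, , drop = FALSE]
      kTok <- min(config$k, length(idx) - 1L)
      nb <- knnNeighbors(co, kTok)
      g <- buildSpatialGraph(spotPCA(X, config$nPcs), nb,
                             config$similarity)
      mdl <- .initModel(X, g, config, A = A)
      if (!is.null(params)) mdl$params <- params
      opt <- .optimise(mdl$params, mdl$const, config, config$max_epochs,
                       state = NULL)
      params <- opt$params
      fw <- .inferenceForward(params, mdl$const, config)
      lastNet <- aggregateAttention(fw$S_heads, geneIds)
    }
    passes <- pass
    Scur <- lastNet@S
    if (!is.null(Sprev)) {
      d <- frobNorm(Scur - Sprev) / max(frobNorm(Sprev), 1e-12)
      sDelta <- c(sDelta, d)
      if (d < config$sTol) break
    }
    Sprev <- Scur
  }
  list(params = params, config = unclass(config), S = lastNet,
       passes = passes, sDelta = sDelta)
}

#' Save / load a model checkpoint
#'
#' A checkpoint holds every learnable array plus the configuration; a
#' reloaded checkpoint reproduces the forward pass bit-identically.
#'
#' @param x a [GTLFit-class] or a checkpoint list with `params`.
#' @param path file to write (RDS).
#' @return `saveCheckpoint`: `path` invisibly; `loadCheckpoint`: the
#'   checkpoint list.
#' @export
saveCheckpoint <- function(x, path) {
  ck <- if (is(x, "GTLFit"))
    list(params = x@params, config = x@config,
         step = nrow(x@lossLog))
  else x
  ck$configHash <- .configHash(ck$config)
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!is.null(ck$configHash) &&
      !identical(ck$configHash, .configHash(ck$config)))
    stop("checkpoint config hash mismatch; file corrupted?")
  ck
}

.configHash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 17), collapse = ","), character(1)),
    collapse = ";")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 2147483647
}
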