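#' Construct a planted regulatory network
#'
#' @param edges data.frame with `regulator`, `target`, `sign` (+1/-1).
#' @param tfs transcription-factor symbols (regulator universe).
#' @param genes gene universe; defaults to the union of TFs and targets.
#' @param tfActivity TF x domain 0/1 matrix of basal activity regimes
#'   (rownames = TFs); defaults to a single always-on domain.
#' @return a [PlantedGRN-class].
#' @export
PlantedGRN <- function(edges, tfs, genes = NULL, tfActivity = NULL) {
  if (is.null(genes)) genes <- union(tfs, union(edges$regulator, edges$target))
  if (is.null(tfActivity))
    tfActivity <- matrix(1, length(tfs), 1L, dimnames = list(tfs, NULL))
  edges$sign <- as.numeric(edges$sign)
  new("PlantedGRN", genes = as.character(genes), tfs = as.character(tfs),
      edges = edges, tfActivity = tfActivity)
}

#' Sample a random planted network
#'
#' The first `nTFs` genes are transcription factors; every remaining gene
#' receives 1..`maxRegulators` TF regulators, activating with probability
#' `activationProb`.  Each TF gets a 0/1 basal-activity pattern over the
#' `nDomains` spatial domains such that patterns differ between domains,
#' every TF varies across domains, and every domain has an active TF —
#' this is what makes the domains transcriptionally (and hence
#' regulatorily) distinct.
#'
#' @param nGenes,nTFs,nDomains network size (defaults 20/5/3).
#' @param maxRegulators max TF regulators per target (default 2).
#' @param activationProb probability that an edge activates (default
#'   0.75).
#' @param seed RNG seed.
#' @return a [PlantedGRN-class].
#' @export
simulatePlantedGRN <- function(nGenes = 20L, nTFs = 5L, nDomains = 3L,
                               maxRegulators = 2L, activationProb = 0.75,
                               seed = 1L) {
  if (nTFs >= nGenes) stop("need nTFs < nGenes")
  .withSeed(.deriveSeed(seed, 11L), {
    tfs <- sprintf("TF%02d", seq_len(nTFs))
    tgt <- sprintf("G%02d", (nTFs + 1L):nGenes)
    genes <- c(tfs, tgt)
    edges <- do.call(rbind, lapply(tgt, function(g) {
      k <- sample.int(maxRegulators, 1L)
      regs <- sample(tfs, min(k, nTFs))
      data.frame(regulator = regs, target = g,
                 sign = ifelse(runif(length(regs)) < activationProb, 1, -1),
                 stringsAsFactors = FALSE)
    }))
    repeat {
      act <- matrix(rbinom(nTFs * nDomains, 1L, 0.5), nTFs, nDomains,
                    dimnames = list(tfs, NULL))
      ok <- !anyDuplicated(t(act)) &&
        all(apply(act, 1L, function(r) length(unique(r)) > 1L |
                    nDomains == 1L)) &&
        all(colSums(act) > 0L)
      if (ok) break
    }
    PlantedGRN(edges, tfs, genes, act)
  })
}

.hill <- function(x, sign) {
  h <- x^2 / (1 + x^2)
  ifelse(sign > 0, h, 1 - h)
}

#' Simulate single cells from a planted network
#'
#' Stochastic Hill-kinetics dynamics per cell: each transcription factor
#' relaxes towards its domain-specific basal production (`aHigh` when
#' active, `aLow` otherwise), each target towards `aHigh` times the mean
#' Hill response (coefficient 2, threshold 1) of its regulators, all with
#' unit decay and additive Gaussian noise, integrated by Euler-Maruyama
#' from varied initial states to near-stationarity.  Targets therefore
#' co-fluctuate with their regulators, both across domains and within a
#' domain.
#'
#' @param grn a [PlantedGRN-class].
#' @param nCells number of cells (>= 1).
#' @param noiseSd diffusion scale of the noise term (default 0.2; 0
#'   gives the deterministic ODE limit).
#' @param seed RNG seed.
#' @param cellDomain integer domain per cell (defaults to an equal
#'   split over the network's domains).
#' @param nSteps,dt integration grid (defaults 80 steps of 0.1).
#' @param aHigh,aLow active/inactive production rates (defaults 2, 0.1).
#' @return list with `cells` (genes x cells matrix, non-negative) and
#'   `cellDomain`.
#' @export
simulateCells <- function(grn, nCells, noiseSd = 0.2, seed = 1L,
                          cellDomain = NULL, nSteps = 80L, dt = 0.1,
                          aHigh = 2, aLow = 0.1) {
  if (nCells < 1L) stop("nCells must be at least 1")
  genes <- grn@genes
  nD <- ncol(grn@tfActivity)
  regOf <- split(seq_len(nrow(grn@edges)), grn@edges$target)
  nonTF <- setdiff(genes, grn@tfs)
  if (!all(nonTF %in% names(regOf)))
    stop("disconnected gene(s) with no rule: ",
         paste(setdiff(nonTF, names(regOf)), collapse = ", "))
  regIdx <- lapply(regOf, function(ii) match(grn@edges$regulator[ii], genes))
  regSign <- lapply(regOf, function(ii) grn@edges$sign[ii])
  tfIdx <- match(grn@tfs, genes)
  .withSeed(.deriveSeed(seed, 13L), {
    if (is.null(cellDomain))
      cellDomain <- rep(seq_len(nD), length.out = nCells)[order(runif(nCells))]
    cellDomain <- as.integer(cellDomain)
    x <- matrix(runif(length(genes) * nCells, 0, 1), length(genes), nCells,
                dimnames = list(genes, sprintf("cell%05d", seq_len(nCells))))
    # per-cell TF activity multipliers: cells occupy a spread of regulatory
    # states within a domain, so targets co-fluctuate with their own
    # regulators rather than with the domain mean only.  noiseSd = 0 is
    # the fully deterministic ODE limit, so the spread is off there.
    uTF <- if (noiseSd > 0)
      matrix(runif(length(grn@tfs) * nCells, 0.25, 1.75),
             length(grn@tfs), nCells)
    else matrix(1, length(grn@tfs), nCells)
    aTF <- (grn@tfActivity[, cellDomain, drop = FALSE] *
              (aHigh - aLow) + aLow) * uTF
    for (s in seq_len(nSteps)) {
      prod <- matrix(0, length(genes), nCells)
      prod[tfIdx, ] <- aTF
      for (g in names(regIdx)) {
        gi <- match(g, genes)
        H <- .hill(x[regIdx[[g]], , drop = FALSE],
                   rep(regSign[[g]], nCells))
        prod[gi, ] <- aHigh * colMeans(matrix(H, nrow = length(regIdx[[g]])))
      }
      x <- x + (prod - x) * dt
      if (noiseSd > 0)
        x <- x + matrix(rnorm(length(x), sd = noiseSd * sqrt(dt)),
                        nrow(x), ncol(x))
      x[x < 0] <- 0
    }
    list(cells = x, cellDomain = cellDomain)
  })
}

# square-grid coordinates and axis-aligned domain blocks
.gridLayout <- function(nSpots, nDomains) {
  side <- ceiling(sqrt(nSpots))
  pos <- expand.grid(x = seq_len(side) - 1L, y = seq_len(side) - 1L)
  pos <- pos[seq_len(nSpots), , drop = FALSE]
  block <- pmin(floor(pos$x / (side / nDomains)) + 1L, nDomains)
  list(coords = as.matrix(pos), block = as.integer(block), side = side)
}

#' Bin single cells into spatially arranged spots
#'
#' Spots sit on a square grid.  Under `grid_blocks` the grid is split
#' into axis-aligned domain blocks; each block's spots receive cells of
#' the matching regime, grouped by proximity in a 2-D PCA embedding of
#' the cells (consecutive chunks along the leading component), so
#' same-regime cells form contiguous spatial domains.  Under `gradient`
#' each spot draws its cells from regimes with probabilities varying
#' smoothly along x, and the spot's label is its majority regime.  A
#' spot's value vector is the sum of its member cells.
#'
#' @param cells genes x cells matrix.
#' @param cellDomain integer regime per cell.
#' @param grn the [PlantedGRN-class] the cells came from.
#' @param nSpots number of spots.
#' @param layout `"grid_blocks"` or `"gradient"`.
#' @param cellsPerSpot cells per spot (`nSpots * cellsPerSpot <=
#'   ncol(cells)`).
#' @param seed RNG seed.
#' @return a [SyntheticSRT-class].
#' @export
binToSpots <- function(cells, cellDomain, grn, nSpots,
                       layout = c("grid_blocks", "gradient"),
                       cellsPerSpot = 5L, seed = 1L) {
  layout <- match.arg(layout)
  nD <- ncol(grn@tfActivity)
  if (nSpots * cellsPerSpot > ncol(cells))
    stop("insufficient cells: need ", nSpots * cellsPerSpot, ", have ",
         ncol(cells))
  gl <- .gridLayout(nSpots, nD)
  emb <- prcomp(t(cells), rank. = 2L)$x
  members <- vector("list", nSpots)
  domain <- integer(nSpots)
  .withSeed(.deriveSeed(seed, 17L), {
    if (layout == "grid_blocks") {
      for (d in seq_len(nD)) {
        spotIdx <- which(gl$block == d)
        need <- length(spotIdx) * cellsPerSpot
        pool <- which(cellDomain == d)
        if (length(pool) < need)
          stop("insufficient cells of regime ", d, ": need ", need,
               ", have ", length(pool))
        pool <- pool[order(emb[pool, 1L], pool)]
        spotIdx <- spotIdx[order(gl$coords[spotIdx, 2L],
                                 gl$coords[spotIdx, 1L])]
        for (s in seq_along(spotIdx)) {
          members[[spotIdx[s]]] <-
            pool[((s - 1L) * cellsPerSpot + 1L):(s * cellsPerSpot)]
          domain[spotIdx[s]] <- d
        }
      }
    } else {
      pools <- lapply(seq_len(nD), function(d) {
        p <- which(cellDomain == d)
        p[order(emb[p, 1L], p)]
      })
      centers <- (seq_len(nD) - 0.5) * gl$side / nD
      for (s in seq_len(nSpots)) {
        w <- exp(-((gl$coords[s, 1L] - centers) / (gl$side / nD))^2)
        taken <- integer(0)
        for (cc in seq_len(cellsPerSpot)) {
          avail <- which(vapply(pools, length, integer(1)) > 0L)
          d <- avail[sample.int(length(avail), 1L,
                                prob = w[avail] / sum(w[avail]))]
          taken <- c(taken, pools[[d]][1L])
          pools[[d]] <- pools[[d]][-1L]
        }
        members[[s]] <- taken
        tabd <- tabulate(cellDomain[taken], nD)
        domain[s] <- which.max(tabd)
      }
    }
  })
  spotMat <- vapply(members, function(ii)
    rowSums(cells[, ii, drop = FALSE]), numeric(nrow(cells)))
  rownames(spotMat) <- rownames(cells)
  colnames(spotMat) <- sprintf("spot%04d", seq_len(nSpots))
  se <- SpatialExpression(spotMat, gl$coords)
  SummarizedExperiment::colData(se)$domain <- domain
  new("SyntheticSRT", experiment = se, truth = grn, cells = cells,
      cellDomain = as.integer(cellDomain), spotMembers = members,
      seed = as.integer(seed))
}

#' One-call synthetic SRT dataset
#'
#' Plants a network, simulates exactly the cells the layout needs per
#' regime, and bins them into spots; every random draw flows from the
#' single `seed`, so identical seeds give identical datasets.
#'
#' @param nGenes,nTFs,nDomains network size (defaults 20/5/3).
#' @param nSpots,cellsPerSpot spot grid size and occupancy (defaults
#'   500/5).
#' @param layout `"grid_blocks"` (default) or `"gradient"`.
#' @param noiseSd simulation noise (default 0.2).
#' @param seed RNG seed.
#' @return a [SyntheticSRT-class].
#' @export
simulateSRTDataset <- function(nGenes = 20L, nTFs = 5L, nDomains = 3L,
                               nSpots = 500L, cellsPerSpot = 5L,
                               layout = c("grid_blocks", "gradient"),
                               noiseSd = 0.2, seed = 1L) {
  layout <- match.arg(layout)
  grn <- simulatePlantedGRN(nGenes, nTFs, nDomains, seed = seed)
  gl <- .gridLayout(nSpots, nDomains)
  if (layout == "grid_blocks") {
    perDomain <- tabulate(gl$block, nbins = nDomains) * cellsPerSpot
    cellDomain <- rep(seq_len(nDomains), perDomain)
  } else {
    cellDomain <- rep(seq_len(nDomains),
                      length.out = nSpots * cellsPerSpot)
  }
  sim <- simulateCells(grn, length(cellDomain), noiseSd = noiseSd,
                       seed = seed, cellDomain = cellDomain)
  binToSpots(sim$cells, sim$cellDomain, grn, nSpots, layout,
             cellsPerSpot, seed = seed)
}

#' Write a synthetic dataset to disk
#'
#' Expression as MatrixMarket with id sidecars, coordinates, true edges
#' and domain labels as TSVs.
#'
#' @param x a [SyntheticSRT-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  se <- x@experiment
  writeExpression(se, file.path(dir, "expression"), "mtx")
  co <- spotCoords(se)
  write.table(data.frame(spot = rownames(co), co),
              file.path(dir, "coords.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(x@truth@edges, file.path(dir, "truth_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(spot = colnames(se), domain = domainLabels(x)),
              file.path(dir, "domains.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(x@truth@tfs, file.path(dir, "tfs.txt"))
  invisible(dir)
}

#' The planted regulon that marks a spatial block
#'
#' Among the network's TFs, picks the one active in exactly one domain
#' with the largest number of activated targets (falling back to the
#' largest activation regulon), and returns it with those targets: the
#' planted regulon whose activity regime defines one spatial block.
#'
#' @param grn a [PlantedGRN-class].
#' @return list with `tf` and `targets`.
#' @export
markerRegulon <- function(grn) {
  act <- grn@tfActivity
  nAct <- vapply(rownames(act), function(tf)
    sum(grn@edges$regulator == tf & grn@edges$sign > 0), numeric(1))
  oneDom <- rowSums(act) == 1
  cand <- if (any(oneDom & nAct >= 3)) rownames(act)[oneDom & nAct >= 3]
    else rownames(act)[nAct > 0]
  tf <- cand[which.max(nAct[cand])]
  list(tf = tf,
       targets = grn@edges$target[grn@edges$regulator == tf &
                                    grn@edges$sign > 0])
}
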