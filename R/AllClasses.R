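#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importClassesFrom Matrix Matrix
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats cor dist median prcomp quantile rnorm runif sd setNames var wilcox.test rbinom
#' @importFrom utils read.csv read.delim write.csv write.table head tail
NULL

#' Spatially resolved expression container
#'
#' `SpatialExpression` extends
#' [SingleCellExperiment::SingleCellExperiment] with per-spot spatial
#' coordinates stored in `colData` (columns `spatial_x`, `spatial_y` and,
#' for multi-slice data, `spatial_z` plus an integer `slice`).  Genes are
#' rows and spots are columns.  The logical metadata flag `isLog` records
#' whether the primary assay has already been log-transformed so that
#' preprocessing cannot be applied twice.
#'
#' @slot .. no additional slots; coordinates and flags live in the
#'   inherited `colData`/`metadata`.
#' @export
setClass("SpatialExpression", contains = "SingleCellExperiment")

setValidity("SpatialExpression", function(object) {
  msg <- character()
  x <- SummarizedExperiment::assay(object, 1L)
  if (nrow(object) < 2L || ncol(object) < 2L)
    msg <- c(msg, "need at least 2 genes and 2 spots")
  if (anyNA(x))
    msg <- c(msg, "expression values contain NA/NaN")
  ids <- rownames(object)
  if (is.null(ids) || anyDuplicated(toupper(trimws(ids))))
    msg <- c(msg, "gene ids must be present and unique after standardization")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("spatial_x", "spatial_y") %in% colnames(cd)))
    msg <- c(msg, "colData must contain spatial_x and spatial_y")
  else {
    co <- as.matrix(cd[, intersect(c("spatial_x", "spatial_y", "spatial_z"),
                                   colnames(cd)), drop = FALSE])
    if (!all(is.finite(co))) msg <- c(msg, "coordinates must be finite")
  }
  if ("spatial_z" %in% colnames(cd) && !("slice" %in% colnames(cd)))
    msg <- c(msg, "3D coordinates require a 'slice' column")
  if (length(msg)) msg else TRUE
})

#' Spatially local weighted graph over spots
#'
#' Holds the column-stochastic (on support) weight matrix `B`, the k-nearest
#' neighbour index sets it was built from, and `k`.
#'
#' @slot B sparse N x N non-negative weight matrix; each column sums to 1
#'   over its non-zero support.
#' @slot neighbors list of integer vectors, per spot its k nearest
#'   neighbour indices.
#' @slot k integer, the neighbourhood size.
#' @export
setClass("SpatialGraph",
  representation(B = "Matrix", neighbors = "list", k = "integer"))

setValidity("SpatialGraph", function(object) {
  B <- object@B
  msg <- character()
  if (nrow(B) != ncol(B)) msg <- c(msg, "B must be square")
  if (length(object@neighbors) != ncol(B))
    msg <- c(msg, "one neighbor set per spot required")
  v <- B@x
  if (length(v) && (!all(is.finite(v)) || any(v < 0)))
    msg <- c(msg, "B entries must be finite and non-negative")
  cs <- Matrix::colSums(B)
  if (length(cs) && any(abs(cs[cs > 0] - 1) > 1e-8))
    msg <- c(msg, "non-empty columns of B must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Aggregated gene-gene attention network
#'
#' The mean attention map over all transformer layers and heads; row i,
#' column j is read as the attention weight of gene i on gene j (gene i is
#' reconstructed from gene j), so rows index putative regulated genes and,
#' for a transcription factor row, the entries rank its candidate targets.
#'
#' @slot S numeric M x M matrix.
#' @slot geneIds character vector of length M.
#' @slot nLayers,nHeads integers recording the aggregation provenance.
#' @export
setClass("AttentionNetwork",
  representation(S = "matrix", geneIds = "character",
                 nLayers = "integer", nHeads = "integer"))

setValidity("AttentionNetwork", function(object) {
  msg <- character()
  if (nrow(object@S) != ncol(object@S)) msg <- c(msg, "S must be square")
  if (length(object@geneIds) != nrow(object@S))
    msg <- c(msg, "geneIds length must match S")
  if (!all(is.finite(object@S))) msg <- c(msg, "S must be finite")
  if (length(msg)) msg else TRUE
})

#' Learnable self-expressive spot graph
#'
#' @slot Z numeric N x N matrix expressing each spot's representation as a
#'   combination of the others'.
#' @slot alpha numeric, spatial-influence coefficient used in the manifold
#'   constraint `Z ~ I + alpha * B`.
#' @export
setClass("ManifoldGraph",
  representation(Z = "matrix", alpha = "numeric"))

setValidity("ManifoldGraph", function(object) {
  msg <- character()
  if (nrow(object@Z) != ncol(object@Z)) msg <- c(msg, "Z must be square")
  if (!all(is.finite(object@Z))) msg <- c(msg, "Z must be finite")
  if (length(object@alpha) != 1L || object@alpha < 0)
    msg <- c(msg, "alpha must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' A set of regulons
#'
#' Each regulon is a transcription factor together with its ranked direct
#' targets and the attention weights they were selected by.
#'
#' @slot regulons named list; each element is a list with fields `tf`,
#'   `targets` (character) and `weights` (numeric, same length).
#' @slot geneUniverse character, the gene ids the weights refer to.
#' @export
setClass("RegulonSet",
  representation(regulons = "list", geneUniverse = "character"))

setValidity("RegulonSet", function(object) {
  msg <- character()
  for (rg in object@regulons) {
    if (!all(c("tf", "targets", "weights") %in% names(rg))) {
      msg <- c(msg, "each regulon needs tf/targets/weights"); break
    }
    if (rg$tf %in% rg$targets) { msg <- c(msg, "tf must not be a target"); break }
    if (length(rg$targets) != length(rg$weights)) {
      msg <- c(msg, "targets and weights must align"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Planted ground-truth regulatory network
#'
#' @slot genes character, the gene universe.
#' @slot tfs character, the transcription factor subset.
#' @slot edges data.frame with columns `regulator`, `target`, `sign`
#'   (+1 activation, -1 repression).
#' @slot tfActivity numeric TF x domain matrix of basal activity regimes
#'   (rows named by TF); drives the domain structure of the simulation.
#' @export
setClass("PlantedGRN",
  representation(genes = "character", tfs = "character",
                 edges = "data.frame", tfActivity = "matrix"))

setValidity("PlantedGRN", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("regulator", "target", "sign") %in% colnames(e)))
    msg <- c(msg, "edges needs regulator/target/sign columns")
  else {
    if (any(e$regulator == e$target)) msg <- c(msg, "self-loops not allowed")
    if (!all(e$regulator %in% object@tfs))
      msg <- c(msg, "regulators must be TFs")
    if (!all(c(e$regulator, e$target) %in% object@genes))
      msg <- c(msg, "edge genes must be in the gene universe")
    nontf <- setdiff(object@genes, object@tfs)
    if (!all(nontf %in% e$target))
      msg <- c(msg, "every non-TF gene needs at least one regulator")
  }
  if (!all(object@tfs %in% object@genes)) msg <- c(msg, "tfs must be genes")
  if (length(msg)) msg else TRUE
})

#' Synthetic SRT dataset with known truth
#'
#' @slot experiment [SpatialExpression] of binned spots; domain labels in
#'   `colData(experiment)$domain`.
#' @slot truth the [PlantedGRN] the cells were simulated from.
#' @slot cells numeric genes x cells single-cell matrix.
#' @slot cellDomain integer regime label per cell.
#' @slot spotMembers list mapping each spot to its member cell indices.
#' @slot seed integer seed every random draw flowed from.
#' @export
setClass("SyntheticSRT",
  representation(experiment = "SpatialExpression", truth = "PlantedGRN",
                 cells = "matrix", cellDomain = "integer",
                 spotMembers = "list", seed = "integer"))

#' Fitted joint model
#'
#' Result of [fineTune()]: the trained parameters, the aggregated attention
#' network, the learned spot graph, and the per-step loss report.
#'
#' @slot params list of all learnable arrays.
#' @slot config the training configuration used.
#' @slot network [AttentionNetwork] aggregated from the final forward pass.
#' @slot manifold [ManifoldGraph] with the learned Z.
#' @slot graph the [SpatialGraph] the fit was constrained by.
#' @slot lossLog data.frame, one row per optimisation step with every loss
#'   component and the total.
#' @slot geneIds,spotIds character identifiers.
#' @export
setClass("GTLFit",
  representation(params = "list", config = "list",
                 network = "AttentionNetwork", manifold = "ManifoldGraph",
                 graph = "SpatialGraph", lossLog = "data.frame",
                 geneIds = "character", spotIds = "character"))

## ---- show methods ----

setMethod("show", "SpatialExpression", function(object) {
  cd <- SummarizedExperiment::colData(object)
  d <- if ("spatial_z" %in% colnames(cd)) 3L else 2L
  cat(sprintf("SpatialExpression: %d genes x %d spots (%dD coordinates%s)\n",
              nrow(object), ncol(object), d,
              if (isTRUE(S4Vectors::metadata(object)$isLog)) ", log-transformed" else ""))
  callNextMethod()
})

setMethod("show", "SpatialGraph", function(object) {
  cat(sprintf("SpatialGraph: %d spots, k = %d, %d non-zero weights\n",
              nrow(object@B), object@k, length(object@B@x)))
})

setMethod("show", "AttentionNetwork", function(object) {
  cat(sprintf(
    "AttentionNetwork: %d genes, aggregated over %d layer(s) x %d head(s)\n",
    nrow(object@S), object@nLayers, object@nHeads))
})

setMethod("show", "ManifoldGraph", function(object) {
  cat(sprintf("ManifoldGraph: %d spots, alpha = %g\n",
              nrow(object@Z), object@alpha))
})

setMethod("show", "RegulonSet", function(object) {
  sizes <- vapply(object@regulons, function(r) length(r$targets), integer(1))
  cat(sprintf("RegulonSet: %d regulons (target-set sizes %s)\n",
              length(object@regulons),
              if (length(sizes)) paste0(min(sizes), "-", max(sizes)) else "-"))
})

setMethod("show", "PlantedGRN", function(object) {
  cat(sprintf("PlantedGRN: %d genes (%d TFs), %d signed edges, %d domains\n",
              length(object@genes), length(object@tfs), nrow(object@edges),
              ncol(object@tfActivity)))
})

setMethod("show", "SyntheticSRT", function(object) {
  cat(sprintf("SyntheticSRT: %d genes x %d spots, %d cells, %d domains, seed %d\n",
              nrow(object@experiment), ncol(object@experiment),
              ncol(object@cells), ncol(object@truth@tfActivity), object@seed))
})

setMethod("show", "GTLFit", function(object) {
  n <- nrow(object@lossLog)
  cat(sprintf("GTLFit: %d genes x %d spots, %d optimisation steps, final loss %.4g\n",
              length(object@geneIds), length(object@spotIds), n,
              if (n) object@lossLog$total[n] else NA_real_))
})
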