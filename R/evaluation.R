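.pairKey <- function(df) paste(df$regulator, df$target, sep = "\r")

#' Candidate edge universe
#'
#' All directed regulator -> target pairs (self-pairs excluded); when a
#' TF list is given, regulators are restricted to it, mirroring the
#' regulon-oriented evaluation.
#'
#' @param genes gene universe.
#' @param tfs optional regulator subset.
#' @return data.frame with `regulator` and `target`.
#' @export
edgeUniverse <- function(genes, tfs = NULL) {
  regs <- if (is.null(tfs)) genes else intersect(tfs, genes)
  df <- expand.grid(target = genes, regulator = regs,
                    stringsAsFactors = FALSE)[, 2:1]
  df <- df[df$regulator != df$target, ]
  rownames(df) <- NULL
  df
}

#' Edge-ranking accuracy: AUROC and AUPRC
#'
#' Scores a ranked edge list against a ground-truth edge set over a
#' candidate universe.  Universe edges absent from the ranking are scored
#' 0; ties are handled by mid-rank (AUROC) and by grouping tied
#' thresholds (AUPRC, trapezoidal over the precision-recall points).
#'
#' @param ranking data.frame with `regulator`, `target`, `weight` (higher
#'   means more confident).
#' @param truth data.frame with `regulator`, `target` (directed true
#'   edges).
#' @param universe candidate pairs (see [edgeUniverse()]); defaults to
#'   the pairs present in `ranking`.
#' @return list with `auroc` and `auprc`.
#' @export
edgePredictionScores <- function(ranking, truth, universe = NULL) {
  if (is.null(universe))
    universe <- ranking[, c("regulator", "target")]
  ku <- .pairKey(universe)
  if (anyDuplicated(ku)) stop("duplicate pairs in the universe")
  kt <- unique(.pairKey(truth))
  if (!length(kt)) stop("empty ground-truth edge set")
  if (!all(kt %in% ku))
    stop("ground truth contains edges outside the candidate universe")
  score <- setNames(rep(0, length(ku)), ku)
  kr <- .pairKey(ranking)
  score[kr[kr %in% ku]] <- ranking$weight[kr %in% ku]
  y <- ku %in% kt
  auroc <- .rankAUROC(score, y)
  # threshold sweep over distinct scores, descending
  ord <- order(-score)
  s <- score[ord]; yy <- y[ord]
  cum_tp <- cumsum(yy); cum_fp <- cumsum(!yy)
  last <- which(diff(c(s, -Inf)) != 0)   # last index of each tied block
  tp <- cum_tp[last]; fp <- cum_fp[last]
  P <- sum(y)
  rec <- tp / P
  prec <- tp / (tp + fp)
  rec <- c(0, rec); prec <- c(prec[1L], prec)
  auprc <- sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
  list(auroc = auroc, auprc = auprc)
}

#' Run-to-run stability of edge rankings
#'
#' Spearman's correlation between consecutive runs over the full ranked
#' universe, and the Jaccard index of the top-k edge sets (k conventionally
#' the number of edges in the true network).
#'
#' @param rankings list (>= 2) of edge data.frames over identical
#'   universes (`regulator`, `target`, `weight`).
#' @param k top-k cutoff for the Jaccard overlap.
#' @return list with numeric vectors `spearman` and `jaccard`, one entry
#'   per consecutive pair.
#' @export
stabilityMetrics <- function(rankings, k) {
  if (length(rankings) < 2L) stop("need at least two runs")
  keys <- lapply(rankings, .pairKey)
  base <- sort(keys[[1L]])
  for (i in seq_along(keys))
    if (!identical(sort(keys[[i]]), base))
      stop("run ", i, " is ranked over a different universe")
  sp <- numeric(length(rankings) - 1L)
  jc <- numeric(length(rankings) - 1L)
  for (i in seq_len(length(rankings) - 1L)) {
    a <- rankings[[i]]; b <- rankings[[i + 1L]]
    wb <- setNames(b$weight, .pairKey(b))[.pairKey(a)]
    sp[i] <- cor(a$weight, wb, method = "spearman")
    topA <- .pairKey(a)[order(-a$weight, .pairKey(a))][seq_len(k)]
    topB <- .pairKey(b)[order(-b$weight, .pairKey(b))][seq_len(k)]
    jc[i] <- length(intersect(topA, topB)) / length(union(topA, topB))
  }
  list(spearman = sp, jaccard = jc)
}

#' Moran's I spatial autocorrelation
#'
#' `I = (N / sum(W)) * sum_ij W_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2`.  The default spatial weights are the binary
#' k-nearest-neighbour adjacency of the supplied graph; `weighted = TRUE`
#' uses the graph's B weights instead.
#'
#' @param values numeric vector, one value per spot (non-constant).
#' @param graph a [SpatialGraph-class], or an N x N weight matrix.
#' @param weighted use B weights instead of binary adjacency.
#' @return scalar Moran's I.
#' @export
moransI <- function(values, graph, weighted = FALSE) {
  values <- as.numeric(values)
  N <- length(values)
  if (var(values) == 0)
    stop("Moran's I is undefined for a constant field")
  if (is(graph, "SpatialGraph")) {
    if (weighted) {
      W <- as.matrix(graph@B)
    } else {
      nb <- graph@neighbors
      W <- matrix(0, N, N)
      for (i in seq_len(N)) W[i, nb[[i]]] <- 1
    }
  } else W <- as.matrix(graph)
  if (!identical(dim(W), c(N, N)))
    stop("weight matrix must be N x N with N = length(values)")
  xc <- values - mean(values)
  (N / sum(W)) * as.numeric(t(xc) %*% W %*% xc) / sum(xc^2)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement of two partitions of the same spots, from
#' the pair-counting contingency table.
#'
#' @param labels,truth two label vectors over the same spots.
#' @return scalar ARI (1 for identical partitions, ~0 at chance).
#' @export
clusteringARI <- function(labels, truth) {
  labels <- as.vector(labels); truth <- as.vector(truth)
  if (length(labels) != length(truth))
    stop("partitions must cover the same spots")
  n <- length(labels)
  if (n < 2L) stop("need at least two spots")
  tab <- table(labels, truth)
  sumij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expct <- a * b / choose(n, 2)
  mx <- (a + b) / 2
  if (mx == expct) return(if (sumij == expct) 1 else 0)
  (sumij - expct) / (mx - expct)
}

#' Degree-preserving shuffled truth
#'
#' Control baseline for edge recovery: every regulator keeps its
#' out-degree but its targets are resampled uniformly from the gene
#' universe (self excluded).  An informative ranking scores ~0.5 AUROC
#' against this shuffled truth.
#'
#' @param truth data.frame with `regulator`, `target`.
#' @param genes gene universe to resample targets from.
#' @param seed RNG seed.
#' @return data.frame with the same regulators and shuffled targets.
#' @export
shuffleTruth <- function(truth, genes, seed = 1L) {
  .withSeed(seed, {
    out <- lapply(split(truth$target, truth$regulator), function(tg) tg)
    regs <- names(out)
    df <- do.call(rbind, lapply(regs, function(rg) {
      pool <- setdiff(genes, rg)
      data.frame(regulator = rg,
                 target = sample(pool, length(out[[rg]])),
                 stringsAsFactors = FALSE)
    }))
    rownames(df) <- NULL
    df
  })
}

#' True edges of a planted network
#'
#' @param grn a [PlantedGRN-class].
#' @return data.frame with `regulator` and `target`.
#' @export
truthEdges <- function(grn) {
  grn@edges[, c("regulator", "target")]
}
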