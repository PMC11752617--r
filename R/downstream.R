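#' Extract regulons from the attention network
#'
#' For every transcription factor present in the network, the candidate
#' targets are the `topK` genes by the TF's incoming-attention weights
#' `S[target, tf]` (a gene attends to the genes it is reconstructed
#' from, i.e. its putative regulators; self excluded, ties broken by
#' gene id); regulons with fewer than `minTargets` members are dropped.
#' Extraction precedes any motif-based pruning.
#'
#' @param network an [AttentionNetwork-class] (or plain M x M matrix with
#'   dimnames).
#' @param tfList character vector of TF symbols.
#' @param topK number of targets to keep per TF (default 50).
#' @param minTargets minimum regulon size (default 10).
#' @return a [RegulonSet-class].
#' @export
extractRegulons <- function(network, tfList, topK = 50L, minTargets = 10L) {
  S <- if (is(network, "AttentionNetwork")) attentionMatrix(network)
    else as.matrix(network)
  genes <- rownames(S)
  tfs <- intersect(standardizeIds(tfList), standardizeIds(genes))
  if (!length(tfs)) stop("no TFs overlap the network gene ids")
  tfs <- genes[match(tfs, standardizeIds(genes))]
  regs <- list()
  for (tf in tfs) {
    w <- S[, tf]
    w <- w[setdiff(names(w), tf)]
    ord <- order(-w, names(w))
    keep <- ord[seq_len(min(topK, length(ord)))]
    if (length(keep) < minTargets) next
    regs[[paste0(tf, "(+)")]] <- list(tf = tf, targets = names(w)[keep],
                                      weights = unname(w[keep]))
  }
  new("RegulonSet", regulons = regs, geneUniverse = genes)
}

#' Motif-pruning backends
#'
#' `passthroughMotifBackend()` is the default stand-in for an external
#' cis-regulatory motif tool: it accepts every target and logs a notice.
#' A backend is a function `(tf, targets) -> character` returning the
#' targets with motif support.
#'
#' @return a backend function.
#' @export
passthroughMotifBackend <- function() {
  f <- function(tf, targets) targets
  attr(f, "label") <- "pass-through (no motif database)"
  f
}

#' Prune regulons with a motif backend
#'
#' Removes targets lacking motif support according to the backend;
#' regulons falling below `minTargets` afterwards are dropped.  With the
#' pass-through backend the input is returned unchanged (with a message).
#'
#' @param regulonSet a [RegulonSet-class].
#' @param backend backend function (see [passthroughMotifBackend()]).
#' @param minTargets minimum surviving regulon size (default 1).
#' @return a pruned [RegulonSet-class].
#' @export
pruneRegulons <- function(regulonSet, backend = passthroughMotifBackend(),
                          minTargets = 1L) {
  lbl <- attr(backend, "label")
  if (!is.null(lbl)) message("motif pruning backend: ", lbl)
  regs <- list()
  for (nm in names(regulonSet@regulons)) {
    rg <- regulonSet@regulons[[nm]]
    keepT <- tryCatch(backend(rg$tf, rg$targets),
                      error = function(e) stop(
                        "motif backend failed for ", rg$tf, ": ",
                        conditionMessage(e), call. = FALSE))
    sel <- rg$targets %in% keepT
    if (sum(sel) < minTargets) next
    regs[[nm]] <- list(tf = rg$tf, targets = rg$targets[sel],
                       weights = rg$weights[sel])
  }
  new("RegulonSet", regulons = regs,
      geneUniverse = regulonSet@geneUniverse)
}

# per-spot recovery-curve activity of one gene set given the spot's
# descending-expression gene ranking
.recoveryAUC <- function(rankOfGene, members, Tcut) {
  hits <- sort(rankOfGene[members])
  hits <- hits[hits <= Tcut]
  if (!length(hits)) return(0)
  # step function: after rank r, count of recovered members; area as the
  # discrete sum over ranks 1..Tcut
  counts <- findInterval(seq_len(Tcut), hits)
  auc <- sum(counts)
  maxauc <- sum(pmin(seq_len(Tcut), length(members)))
  auc / maxauc
}

#' Rank-based regulon activity (recovery-curve AUC)
#'
#' For every spot, genes are ranked by descending expression (ties broken
#' by gene id); the activity of a regulon is the area under the recovery
#' curve of its members across the top `ceiling(thresholdFrac * M)`
#' ranks, normalised by the maximum attainable area, giving a value in
#' `[0, 1]`.  The score depends on the ranking only, so it is invariant
#' to any strictly monotone transform of a spot's expression vector.
#'
#' @param x expression (`SpatialExpression`/`SingleCellExperiment`/matrix,
#'   genes x spots).
#' @param regulonSet a [RegulonSet-class].
#' @param thresholdFrac top fraction of the ranking integrated (default
#'   0.05, the conventional top-5% cutoff).
#' @return a `SummarizedExperiment` with assay `activity`
#'   (regulons x spots); the regulon's TF is included among the scored
#'   members.
#' @export
aucellActivity <- function(x, regulonSet, thresholdFrac = 0.05) {
  if (thresholdFrac <= 0 || thresholdFrac > 1)
    stop("thresholdFrac must be in (0, 1]")
  mat <- if (is.matrix(x)) x else exprValues(x)
  M <- nrow(mat)
  Tcut <- ceiling(thresholdFrac * M)
  genes <- rownames(mat)
  regs <- regulonSet@regulons
  act <- matrix(0, length(regs), ncol(mat),
                dimnames = list(names(regs), colnames(mat)))
  memberIdx <- lapply(regs, function(rg) {
    m <- match(unique(c(rg$tf, rg$targets)), genes)
    m[!is.na(m)]
  })
  empty <- vapply(memberIdx, length, integer(1)) == 0L
  if (any(empty))
    warning("regulon(s) with no genes in the expression matrix: ",
            paste(names(regs)[empty], collapse = ", "))
  for (j in seq_len(ncol(mat))) {
    ord <- order(-mat[, j], genes)
    rk <- integer(M)
    rk[ord] <- seq_len(M)
    for (r in seq_along(regs)) {
      if (empty[r]) next
      act[r, j] <- .recoveryAUC(rk, memberIdx[[r]], Tcut)
    }
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(activity = act),
    metadata = list(thresholdFrac = thresholdFrac))
}

#' Cluster spots from the learned graph
#'
#' Symmetrises Z (`(Z + t(Z)) / 2`, negatives clipped at zero, diagonal
#' dropped), builds a weighted undirected graph and runs Leiden community
#' detection (modularity objective).  Deterministic under a fixed seed.
#' With `nClusters` set, the resolution is searched by bisection so the
#' number of communities matches the requested count where attainable.
#'
#' @param Z a [ManifoldGraph-class], [GTLFit-class] or N x N matrix.
#' @param resolution Leiden resolution (default 1).
#' @param seed RNG seed for the community search.
#' @param nClusters optional target number of clusters (bisection on the
#'   resolution).
#' @return integer vector of cluster labels (1-based) with the resolution
#'   used stored in `attr(, "resolution")`.
#' @export
clusterSpots <- function(Z, resolution = 1, seed = 1L, nClusters = NULL) {
  Zm <- if (is(Z, "GTLFit")) manifoldMatrix(Z) else .asZ(Z)
  W <- (Zm + t(Zm)) / 2
  W[W < 0] <- 0
  diag(W) <- 0
  dimnames(W) <- NULL   # asymmetric dimnames would defeat isSymmetric()
  if (all(W == 0)) stop("all-zero spot graph: nothing to cluster")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  run <- function(res) {
    .withSeed(seed, igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = res,
      n_iterations = 5L))
  }
  if (is.null(nClusters)) {
    cl <- run(resolution)
  } else {
    lo <- 1e-4; hi <- resolution
    cl <- run(hi)
    while (max(igraph::membership(cl)) < nClusters && hi < 100) {
      hi <- hi * 2; cl <- run(hi)
    }
    for (it in seq_len(30L)) {
      mid <- (lo + hi) / 2
      cl <- run(mid)
      kk <- max(igraph::membership(cl))
      if (kk == nClusters) { resolution <- mid; break }
      if (kk < nClusters) lo <- mid else hi <- mid
      resolution <- mid
    }
  }
  lab <- as.integer(igraph::membership(cl))
  attr(lab, "resolution") <- resolution
  lab
}

# rank-sum AUROC of values for group membership (equals the scaled
# Mann-Whitney U statistic, with mid-rank tie handling)
.rankAUROC <- function(values, inGroup) {
  n1 <- sum(inGroup); n2 <- sum(!inGroup)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(values)
  (sum(r[inGroup]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Cluster-specific regulons
#'
#' One-vs-rest marker statistics per regulon per cluster: the log2 fold
#' change of mean activity `log2((mean_in + eps) / (mean_out + eps))` and
#' the rank-sum AUROC of activity against cluster membership.  Rows pass
#' when `log2FC > minLog2FC` and, if `minAUROC` is not `NULL`,
#' `AUROC > minAUROC`; the defaults (0.25 and 0.75) mirror the standard
#' filter, and `minAUROC = NULL` gives the fold-change-only mode used for
#' high-resolution platforms.  Singleton clusters get `NA` AUROC and are
#' flagged.
#'
#' @param activity result of [aucellActivity()] (or regulons x spots
#'   matrix).
#' @param labels cluster label per spot.
#' @param minLog2FC fold-change threshold (default 0.25).
#' @param minAUROC AUROC threshold (default 0.75) or `NULL` to disable.
#' @param eps pseudocount in the fold change (default 1e-9).
#' @param keepAll return all rows with a `pass` column instead of only
#'   the passing rows.
#' @return data.frame with columns `regulon`, `cluster`, `log2FC`,
#'   `auroc`, `flag`, `pass`.
#' @export
specificRegulons <- function(activity, labels, minLog2FC = 0.25,
                             minAUROC = 0.75, eps = 1e-9,
                             keepAll = FALSE) {
  act <- if (is.matrix(activity)) activity
    else SummarizedExperiment::assay(activity, "activity")
  labels <- as.vector(labels)
  if (length(labels) != ncol(act))
    stop("need one label per spot")
  cls <- sort(unique(labels))
  if (length(cls) < 2L) stop("need at least two clusters")
  rows <- list()
  for (r in rownames(act)) {
    v <- act[r, ]
    for (cl in cls) {
      inC <- labels == cl
      l2fc <- log2((mean(v[inC]) + eps) / (mean(v[!inC]) + eps))
      auroc <- .rankAUROC(v, inC)
      flag <- if (sum(inC) < 2L) "singleton-cluster" else ""
      pass <- l2fc > minLog2FC &&
        (is.null(minAUROC) || (!is.na(auroc) && auroc > minAUROC))
      rows[[length(rows) + 1L]] <- data.frame(
        regulon = r, cluster = cl, log2FC = l2fc, auroc = auroc,
        flag = flag, pass = pass, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (keepAll) out else out[out$pass, , drop = FALSE]
}

#' Export regulons as GMT
#'
#' One line per regulon: set name `TF(+)`, a description field, then the
#' member genes.
#'
#' @param regulonSet a [RegulonSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportRegulonsGMT <- function(regulonSet, path) {
  lines <- vapply(names(regulonSet@regulons), function(nm) {
    rg <- regulonSet@regulons[[nm]]
    paste(c(nm, paste0("tf=", rg$tf), rg$targets), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export the attention network as a ranked edge list
#'
#' The weight of a directed edge regulator -> target is the target's
#' attention on the regulator, `S[target, regulator]` (the regulator is
#' one of the genes the target is reconstructed from).
#'
#' @param network an [AttentionNetwork-class].
#' @param path output TSV (`regulator`, `target`, `weight`, descending).
#' @param tfList optional: restrict regulators to these genes.
#' @return the edge data.frame, invisibly.
#' @export
exportEdges <- function(network, path = NULL, tfList = NULL) {
  S <- attentionMatrix(network)
  regs <- rownames(S)
  if (!is.null(tfList))
    regs <- intersect(regs, regs[standardizeIds(regs) %in%
                                   standardizeIds(tfList)])
  df <- do.call(rbind, lapply(regs, function(g)
    data.frame(regulator = g, target = colnames(S),
               weight = S[, g], stringsAsFactors = FALSE)))
  df <- df[df$regulator != df$target, ]
  df <- df[order(-df$weight, df$regulator, df$target), ]
  rownames(df) <- NULL
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
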