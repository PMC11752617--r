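#' k-nearest spatial neighbours
#'
#' For 2D data, plain Euclidean k-nearest neighbours per spot.  For 3D
#' (multi-slice) data, all slices are projected along the z axis into a
#' common x-y plane and a spot's candidates are restricted to spots whose
#' slice index differs by at most one; the k nearest in the projected
#' plane are kept.  Distance ties are broken by spot index.
#'
#' @param coords N x 2 or N x 3 coordinate matrix; 3D input needs a
#'   `"slice"` attribute or a 3rd column from which slices are derived
#'   (one slice per distinct z).
#' @param k neighbourhood size, `1 <= k < N`.
#' @return list of length N of integer neighbour index vectors (self
#'   excluded), each of length `k`.
#' @examples
#' co <- cbind(c(0, 1, 2, 3), 0)
#' knnNeighbors(co, 1)[[1]]   # spot 1's neighbour is spot 2
#' @export
knnNeighbors <- function(coords, k) {
  coords <- as.matrix(coords)
  N <- nrow(coords)
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive")
  if (k >= N) stop("k (", k, ") must be smaller than the number of spots (",
                   N, ")")
  if (ncol(coords) == 3L) {
    slice <- attr(coords, "slice")
    if (is.null(slice))
      slice <- as.integer(factor(coords[, 3L], levels = unique(coords[, 3L])))
    xy <- coords[, 1:2, drop = FALSE]
  } else {
    slice <- NULL
    xy <- coords
  }
  D <- as.matrix(dist(xy))
  lapply(seq_len(N), function(i) {
    cand <- seq_len(N)[-i]
    if (!is.null(slice)) {
      cand <- cand[abs(slice[cand] - slice[i]) <= 1L]
      if (length(cand) < k)
        stop("spot ", i, " has fewer than k candidates within adjacent slices")
    }
    ord <- cand[order(D[i, cand], cand)]
    ord[seq_len(k)]
  })
}

#' PCA embedding of spots
#'
#' Top principal components of the (log) expression matrix with spots as
#' samples; used as the feature space for the spatial-graph weights.
#'
#' @param x `SpatialExpression`/`SingleCellExperiment` or genes x spots
#'   matrix.
#' @param nPcs number of components (default 50, capped at `min(M, N) - 1`).
#' @return numeric `nPcs x N` matrix (components x spots).
#' @export
spotPCA <- function(x, nPcs = 50) {
  mat <- if (is.matrix(x)) x else exprValues(x)
  nPcs <- min(nPcs, nrow(mat) - 1L, ncol(mat) - 1L)
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE, rank. = nPcs)
  U <- t(pc$x)
  colnames(U) <- colnames(mat)
  U
}

#' Build the spatially local weighted graph
#'
#' On each neighbour pair (i in neighbours of j) the unnormalised weight is
#' `D_ij = exp(2 - d(U_i, U_j) / (||U_i|| * ||U_j||))` with `d` the
#' Euclidean distance between the spots' embedding columns; elsewhere zero.
#' Columns are then normalised to sum to one over their support,
#' `B_ij = D_ij / sum_i D_ij`.  A `similarity = "cosine"` switch replaces
#' the scaled distance by the cosine similarity (so that identical
#' directions give the largest weight `e`); the default follows the
#' distance reading.
#'
#' @param embed `K x N` embedding matrix (see [spotPCA()]).
#' @param neighbors neighbour sets from [knnNeighbors()].
#' @param similarity `"distance"` (default) or `"cosine"`.
#' @return a [SpatialGraph-class].
#' @export
buildSpatialGraph <- function(embed, neighbors,
                              similarity = c("distance", "cosine")) {
  similarity <- match.arg(similarity)
  N <- ncol(embed)
  if (length(neighbors) != N)
    stop("neighbor sets (", length(neighbors),
         ") must align with embedding columns (", N, ")")
  nrms <- sqrt(colSums(embed^2))
  if (any(nrms == 0))
    stop("zero-norm embedding column for spot(s): ",
         paste(which(nrms == 0), collapse = ", "))
  ii <- unlist(neighbors)
  jj <- rep.int(seq_len(N), lengths(neighbors))
  diffs <- embed[, ii, drop = FALSE] - embed[, jj, drop = FALSE]
  dd <- sqrt(colSums(diffs^2))
  val <- switch(similarity,
    distance = exp(2 - dd / (nrms[ii] * nrms[jj])),
    cosine = exp(1 + colSums(embed[, ii, drop = FALSE] *
                             embed[, jj, drop = FALSE]) / (nrms[ii] * nrms[jj])))
  D <- Matrix::sparseMatrix(i = ii, j = jj, x = val, dims = c(N, N))
  cs <- Matrix::colSums(D)
  B <- D %*% Matrix::Diagonal(N, 1 / cs)
  new("SpatialGraph", B = methods::as(B, "CsparseMatrix"),
      neighbors = neighbors, k = length(neighbors[[1L]]))
}

#' One-call spatial graph from a SpatialExpression
#'
#' Convenience wrapper: PCA embedding, k-nearest neighbours from the
#' stored coordinates (3D-aware), and the weighted graph.
#'
#' @param se a [SpatialExpression-class] (log-transformed).
#' @param k neighbourhood size; the platform-style defaults are 10
#'   (Visium-like) and 30 (high-resolution).
#' @param nPcs number of principal components (default 50).
#' @param similarity passed to [buildSpatialGraph()].
#' @return a [SpatialGraph-class].
#' @export
spatialGraph <- function(se, k = 10, nPcs = 50,
                         similarity = c("distance", "cosine")) {
  co <- spotCoords(se)
  if (ncol(co) == 3L)
    attr(co, "slice") <- SummarizedExperiment::colData(se)$slice
  nb <- knnNeighbors(co, k)
  buildSpatialGraph(spotPCA(se, nPcs), nb, match.arg(similarity))
}
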