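#' Construct a SpatialExpression object
#'
#' Combines a genes x spots expression matrix (or an existing
#' SingleCellExperiment) with per-spot coordinates into the package's
#' central container.  Coordinates may be 2D (x, y) or 3D (x, y, z); for 3D
#' data a per-spot slice index is required and, when missing, is derived
#' from the distinct z values in order.
#'
#' @param x numeric matrix (genes x spots, with dimnames) or a
#'   `SingleCellExperiment`.
#' @param coords numeric N x 2 or N x 3 matrix of spot coordinates.
#' @param sliceId optional integer vector of slice indices (3D data).
#' @param isLog logical; whether the values are already log-transformed.
#' @return a [SpatialExpression-class] object.
#' @examples
#' x <- matrix(rpois(20, 5), 4, 5,
#'             dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
#' se <- SpatialExpression(x, cbind(1:5, 1))
#' spotCoords(se)
#' @export
SpatialExpression <- function(x, coords, sliceId = NULL, isLog = FALSE) {
  if (is(x, "SummarizedExperiment")) {
    mat <- SummarizedExperiment::assay(x, 1L)
    if (is.null(isLog) || missing(isLog))
      isLog <- isTRUE(S4Vectors::metadata(x)$isLog)
  } else mat <- as.matrix(x)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != ncol(mat))
    stop("coords must have one row per spot (", ncol(mat), "), got ",
         nrow(coords))
  if (!ncol(coords) %in% c(2L, 3L))
    stop("coords must have 2 or 3 columns")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  cd <- S4Vectors::DataFrame(spatial_x = coords[, 1L], spatial_y = coords[, 2L])
  if (ncol(coords) == 3L) {
    cd$spatial_z <- coords[, 3L]
    if (is.null(sliceId))
      sliceId <- as.integer(factor(coords[, 3L], levels = unique(coords[, 3L])))
    if (length(sliceId) != ncol(mat))
      stop("sliceId must have one entry per spot")
    if (anyNA(match(coords[, 3L], coords[, 3L])) ||
        any(tapply(sliceId, coords[, 3L], function(s) length(unique(s))) != 1L))
      stop("sliceId must be constant within each z value")
    cd$slice <- as.integer(sliceId)
  }
  if (is.null(rownames(mat))) stop("expression matrix needs gene ids as rownames")
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("spot", seq_len(ncol(mat)))
  rownames(cd) <- colnames(mat)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(X = mat), colData = cd)
  S4Vectors::metadata(sce)$isLog <- isTRUE(isLog)
  new("SpatialExpression", sce)
}

#' Extract the expression matrix
#'
#' @param x a `SpatialExpression` or any `SummarizedExperiment`.
#' @return dense numeric matrix, genes x spots.
#' @export
exprValues <- function(x) {
  m <- SummarizedExperiment::assay(x, 1L)
  as.matrix(m)
}

.collapseDuplicates <- function(mat) {
  ids <- standardizeIds(rownames(mat))
  if (anyDuplicated(ids)) {
    mat <- rowsum(mat, group = ids, reorder = FALSE)
  } else rownames(mat) <- ids
  mat
}

.detectFormat <- function(path) {
  if (dir.exists(path)) return("mtx")
  switch(tolower(tools::file_ext(path)),
         mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
         h5ad = "h5ad",
         stop("cannot infer format from '", path, "'; pass format="))
}

#' Read an expression matrix
#'
#' Reads dense CSV/TSV (genes x spots; first column gene ids, header row
#' spot ids), MatrixMarket `.mtx` with `genes.tsv`/`barcodes.tsv` sidecars,
#' or AnnData `.h5ad` (through the Python `anndata` bridge).  Whatever the
#' on-disk orientation, the result has genes on rows; orientation is
#' resolved by matching the id sidecars.  Duplicate gene symbols (after
#' case-folding and whitespace stripping) are collapsed by summation.
#'
#' @param path file (or, for mtx, file or directory) to read.
#' @param format one of `"auto"`, `"csv"`, `"tsv"`, `"mtx"`, `"h5ad"`.
#' @return a [SpatialExpression-class] when coordinates are embedded
#'   (h5ad with an `obsm[["spatial"]]` slot), otherwise a
#'   `SingleCellExperiment` with assay `X` and `metadata()$isLog`.
#' @export
readExpression <- function(path,
                           format = c("auto", "csv", "tsv", "mtx", "h5ad")) {
  format <- match.arg(format)
  if (format == "auto") format <- .detectFormat(path)
  if (!file.exists(path)) stop("file not found: ", path)
  out <- switch(format,
    csv = .readDense(path, sep = ","),
    tsv = .readDense(path, sep = "\t"),
    mtx = .readMtx(path),
    h5ad = return(.readH5ad(path)))
  mat <- .collapseDuplicates(out$mat)
  sce <- SingleCellExperiment::SingleCellExperiment(assays = list(X = mat))
  S4Vectors::metadata(sce)$isLog <- isTRUE(out$isLog)
  sce
}

.readDense <- function(path, sep) {
  df <- tryCatch(
    read.table(path, sep = sep, header = TRUE, row.names = 1,
               check.names = FALSE),
    error = function(e) stop("malformed dense file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  mat <- as.matrix(df)
  if (!is.numeric(mat))
    stop("malformed dense file '", path, "': non-numeric entries (first at ",
         "record ", which(!is.finite(suppressWarnings(as.numeric(mat))))[1L], ")")
  list(mat = mat, isLog = FALSE)
}

.readMtx <- function(path) {
  if (dir.exists(path)) {
    dirn <- path
    mtx <- list.files(dirn, pattern = "\\.mtx$", full.names = TRUE)[1L]
    if (is.na(mtx)) stop("no .mtx file in directory ", path)
  } else {
    mtx <- path
    dirn <- dirname(path)
  }
  m <- tryCatch(as.matrix(Matrix::readMM(mtx)),
                error = function(e) stop("malformed MatrixMarket file '", mtx,
                                         "': ", conditionMessage(e), call. = FALSE))
  gf <- file.path(dirn, c("genes.tsv", "features.tsv"))
  gf <- gf[file.exists(gf)][1L]
  bf <- file.path(dirn, "barcodes.tsv")
  if (is.na(gf) || !file.exists(bf))
    stop("ambiguous orientation: need genes.tsv/features.tsv and ",
         "barcodes.tsv beside ", mtx)
  genes <- read.delim(gf, header = FALSE)[[1L]]
  bars <- read.delim(bf, header = FALSE)[[1L]]
  if (nrow(m) == length(genes) && ncol(m) == length(bars)) {
    # genes already on rows
  } else if (nrow(m) == length(bars) && ncol(m) == length(genes)) {
    m <- t(m)
  } else {
    stop("matrix dimensions ", nrow(m), "x", ncol(m),
         " match neither orientation of the id sidecars")
  }
  dimnames(m) <- list(genes, bars)
  list(mat = m, isLog = FALSE)
}

#' Write an expression matrix
#'
#' Inverse of [readExpression()]; all formats round-trip values to full
#' double precision and ids exactly.
#'
#' @param x `SpatialExpression` / `SingleCellExperiment` / matrix.
#' @param path output file; for `"mtx"` a directory that will receive
#'   `matrix.mtx`, `genes.tsv` and `barcodes.tsv`.
#' @param format `"csv"`, `"tsv"`, `"mtx"` or `"h5ad"`.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path, format = c("csv", "tsv", "mtx", "h5ad")) {
  format <- match.arg(format)
  mat <- if (is.matrix(x)) x else exprValues(x)
  switch(format,
    csv = .writeDense(mat, path, ","),
    tsv = .writeDense(mat, path, "\t"),
    mtx = .writeMtx(mat, path),
    h5ad = .writeH5ad(x, path))
  invisible(path)
}

.writeDense <- function(mat, path, sep) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(mat)), collapse = sep), con)
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])), collapse = sep),
    character(1))
  writeLines(body, con)
}

.writeMtx <- function(mat, dirn) {
  if (!dir.exists(dirn)) dir.create(dirn, recursive = TRUE)
  sm <- Matrix::Matrix(mat, sparse = TRUE)
  tri <- Matrix::summary(sm)
  con <- file(file.path(dirn, "matrix.mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               sprintf("%d %d %d", nrow(mat), ncol(mat), nrow(tri))), con)
  writeLines(sprintf("%d %d %.17g", tri$i, tri$j, tri$x), con)
  close(con)
  writeLines(rownames(mat), file.path(dirn, "genes.tsv"))
  writeLines(colnames(mat), file.path(dirn, "barcodes.tsv"))
}

## ---- AnnData bridge (Python anndata over a temp-file exchange) ----

.python <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    stop("h5ad support needs a 'python' with the anndata package on PATH")
  p
}

.runPy <- function(code) {
  res <- suppressWarnings(system2(.python(), c("-c", shQuote(code)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop("python/anndata bridge failed:\n", paste(res, collapse = "\n"))
  invisible(res)
}

.readH5ad <- function(path) {
  tmp <- tempfile("h5ad_x")
  dir.create(tmp)
  code <- sprintf('
import anndata, numpy as np, os, scipy.sparse as sp
ad = anndata.read_h5ad(%s)
X = ad.X.toarray() if sp.issparse(ad.X) else np.asarray(ad.X)
out = %s
np.savetxt(os.path.join(out, "X.tsv"), X.T.astype(np.float64), fmt="%%.17g", delimiter="\\t")
open(os.path.join(out, "genes.tsv"), "w").write("\\n".join(map(str, ad.var_names)) + "\\n")
open(os.path.join(out, "barcodes.tsv"), "w").write("\\n".join(map(str, ad.obs_names)) + "\\n")
if "spatial" in ad.obsm:
    np.savetxt(os.path.join(out, "coords.tsv"), np.asarray(ad.obsm["spatial"], dtype=np.float64), fmt="%%.17g", delimiter="\\t")
open(os.path.join(out, "islog.txt"), "w").write(str(bool(ad.uns.get("is_log", False))) + "\\n")
', deparse(normalizePath(path)), deparse(tmp))
  .runPy(code)
  mat <- as.matrix(read.delim(file.path(tmp, "X.tsv"), header = FALSE))
  genes <- readLines(file.path(tmp, "genes.tsv"))
  bars <- readLines(file.path(tmp, "barcodes.tsv"))
  dimnames(mat) <- list(genes, bars)
  mat <- .collapseDuplicates(mat)
  isLog <- identical(readLines(file.path(tmp, "islog.txt")), "True")
  cf <- file.path(tmp, "coords.tsv")
  if (file.exists(cf)) {
    coords <- as.matrix(read.delim(cf, header = FALSE))
    SpatialExpression(mat, coords, isLog = isLog)
  } else {
    sce <- SingleCellExperiment::SingleCellExperiment(assays = list(X = mat))
    S4Vectors::metadata(sce)$isLog <- isLog
    sce
  }
}

.writeH5ad <- function(x, path) {
  mat <- if (is.matrix(x)) x else exprValues(x)
  tmp <- tempfile("h5ad_w")
  dir.create(tmp)
  .writeDense(mat, file.path(tmp, "X.tsv"), "\t")
  hasCoords <- is(x, "SpatialExpression")
  if (hasCoords)
    write.table(spotCoords(x), file.path(tmp, "coords.tsv"), sep = "\t",
                row.names = FALSE, col.names = FALSE)
  isLog <- if (is.matrix(x)) FALSE else isTRUE(S4Vectors::metadata(x)$isLog)
  code <- sprintf('
import anndata, numpy as np, pandas as pd, os
tmp = %s
df = pd.read_csv(os.path.join(tmp, "X.tsv"), sep="\\t", index_col=0)
ad = anndata.AnnData(X=df.values.T.astype(np.float64),
                     obs=pd.DataFrame(index=df.columns.astype(str)),
                     var=pd.DataFrame(index=df.index.astype(str)))
cf = os.path.join(tmp, "coords.tsv")
if os.path.exists(cf):
    ad.obsm["spatial"] = np.loadtxt(cf, delimiter="\\t", ndmin=2)
ad.uns["is_log"] = %s
ad.write_h5ad(%s)
', deparse(tmp), if (isLog) "True" else "False", deparse(path))
  .runPy(code)
}

#' Preprocess an expression matrix
#'
#' Optional highly-variable-gene selection followed by the natural-log
#' `log(x + pseudocount)` transform.  The HVG score is the normalised
#' dispersion of the pre-log values: dispersion = variance / mean, z-scored
#' within 20 equal-occupancy mean bins; ties are broken by gene id in
#' lexicographic order.  Refuses to run twice (guarded by the `isLog`
#' flag).
#'
#' @param x `SpatialExpression` or `SingleCellExperiment`.
#' @param nHVG keep the top `nHVG` genes (`NULL` keeps all).
#' @param pseudocount added before the log; default 1, so zeros stay zero.
#' @return the same class as `x`, subset and transformed, with
#'   `metadata()$isLog = TRUE`.
#' @export
preprocessExpression <- function(x, nHVG = NULL, pseudocount = 1) {
  if (isTRUE(S4Vectors::metadata(x)$isLog))
    stop("expression is already log-transformed; refusing to transform again")
  mat <- exprValues(x)
  if (!is.null(nHVG)) {
    if (nHVG > nrow(mat))
      stop("nHVG (", nHVG, ") exceeds the number of genes (", nrow(mat), ")")
    keep <- .selectHVG(mat, nHVG)
    x <- x[keep, ]
    mat <- mat[keep, , drop = FALSE]
  }
  SummarizedExperiment::assay(x, 1L) <- log(mat + pseudocount)
  S4Vectors::metadata(x)$isLog <- TRUE
  x
}

# normalised-dispersion HVG ranking on the raw matrix
.selectHVG <- function(mat, nHVG) {
  mu <- rowMeans(mat)
  v <- apply(mat, 1L, var)
  disp <- ifelse(mu > 0, v / mu, -Inf)
  nbins <- min(20L, max(1L, nrow(mat) %/% 2L))
  br <- unique(quantile(mu, probs = seq(0, 1, length.out = nbins + 1L)))
  bins <- if (length(br) > 2L)
    cut(mu, breaks = br, include.lowest = TRUE) else factor(rep(1L, length(mu)))
  score <- disp
  for (b in levels(bins)) {
    idx <- which(bins == b & is.finite(disp))
    if (length(idx) > 1L && sd(disp[idx]) > 0)
      score[idx] <- (disp[idx] - mean(disp[idx])) / sd(disp[idx])
    else if (length(idx)) score[idx] <- 0
  }
  ids <- rownames(mat)
  ord <- order(-score, ids)
  sort(ord[seq_len(nHVG)])
}

#' Read spot coordinates from TSV
#'
#' Expects columns `x`, `y` and optionally `z` and `slice` (header
#' required); an optional leading non-numeric column is taken as spot ids.
#'
#' @param path TSV file.
#' @return numeric matrix with 2 or 3 coordinate columns and, when
#'   present, a `"slice"` attribute.
#' @export
readCoordinates <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (!is.numeric(df[[1L]])) {
    rn <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
    rownames(df) <- rn
  }
  cols <- intersect(c("x", "y", "z"), colnames(df))
  if (length(cols) < 2L) stop("coordinate file needs x and y columns")
  co <- as.matrix(df[, cols, drop = FALSE])
  if ("slice" %in% colnames(df)) attr(co, "slice") <- as.integer(df$slice)
  co
}

#' Read a prior gene-interaction network
#'
#' Reads a 3-column (geneA, geneB, confidence) edge-list TSV, restricts it
#' to the supplied gene universe, rescales confidences to `[0, 1]` by the
#' maximum, and symmetrises (the prior is undirected).  Genes absent from
#' the edge list get zero rows/columns.
#'
#' @param path edge-list TSV (header optional).
#' @param geneIds gene universe the adjacency is indexed by.
#' @return list with `A` (M x M numeric, weights in `[0, 1]`) and `source`.
#' @export
readPriorNetwork <- function(path, geneIds) {
  first <- readLines(path, n = 1L)
  hasHeader <- length(first) == 1L &&
    is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1L]][3L])))
  df <- tryCatch(
    read.delim(path, header = hasHeader,
               col.names = c("geneA", "geneB", "confidence")),
    error = function(e) if (grepl("no lines available", conditionMessage(e)))
      data.frame(geneA = character(), geneB = character(),
                 confidence = numeric())
    else stop("malformed edge list '", path, "': ", conditionMessage(e),
              call. = FALSE))
  ids <- standardizeIds(geneIds)
  M <- length(ids)
  A <- matrix(0, M, M, dimnames = list(geneIds, geneIds))
  if (nrow(df) == 0L) {
    warning("empty prior network file: returning all-zero adjacency")
    return(list(A = A, source = path))
  }
  ga <- match(standardizeIds(df$geneA), ids)
  gb <- match(standardizeIds(df$geneB), ids)
  keep <- !is.na(ga) & !is.na(gb)
  if (!any(keep))
    stop("no genes in the edge list overlap the expression gene ids")
  w <- as.numeric(df$confidence[keep])
  w <- w / max(w)
  for (e in seq_along(w)) {
    i <- ga[keep][e]; j <- gb[keep][e]
    A[i, j] <- max(A[i, j], w[e])
    A[j, i] <- max(A[j, i], w[e])
  }
  list(A = A, source = path)
}

#' Read a transcription-factor list
#'
#' One symbol per line; symbols are case-folded and whitespace-stripped.
#'
#' @param path text file.
#' @return character vector.
#' @export
readTFList <- function(path) {
  tf <- readLines(path)
  tf <- standardizeIds(tf[nzchar(trimws(tf))])
  unique(tf)
}
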