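#' Accessors for regatta classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return the corresponding component (see Details of each class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spotCoords", function(x) standardGeneric("spotCoords"))

#' @rdname accessors
#' @export
setGeneric("isLogged", function(x) standardGeneric("isLogged"))

#' @rdname accessors
#' @export
setGeneric("graphWeights", function(x) standardGeneric("graphWeights"))

#' @rdname accessors
#' @export
setGeneric("neighborSets", function(x) standardGeneric("neighborSets"))

#' @rdname accessors
#' @export
setGeneric("attentionMatrix", function(x) standardGeneric("attentionMatrix"))

#' @rdname accessors
#' @export
setGeneric("manifoldMatrix", function(x) standardGeneric("manifoldMatrix"))

#' @rdname accessors
#' @export
setGeneric("regulons", function(x) standardGeneric("regulons"))

#' @rdname accessors
#' @export
setGeneric("lossLog", function(x) standardGeneric("lossLog"))

#' @rdname accessors
#' @export
setGeneric("truthNetwork", function(x) standardGeneric("truthNetwork"))

#' @rdname accessors
#' @export
setGeneric("domainLabels", function(x) standardGeneric("domainLabels"))

#' @rdname accessors
#' @export
setMethod("spotCoords", "SpatialExpression", function(x) {
  cd <- SummarizedExperiment::colData(x)
  co <- as.matrix(cd[, intersect(c("spatial_x", "spatial_y", "spatial_z"),
                                 colnames(cd)), drop = FALSE])
  colnames(co) <- c("x", "y", "z")[seq_len(ncol(co))]
  rownames(co) <- colnames(x)
  co
})

#' @rdname accessors
#' @export
setMethod("isLogged", "SpatialExpression", function(x)
  isTRUE(S4Vectors::metadata(x)$isLog))

#' @rdname accessors
#' @export
setMethod("graphWeights", "SpatialGraph", function(x) x@B)

#' @rdname accessors
#' @export
setMethod("neighborSets", "SpatialGraph", function(x) x@neighbors)

#' @rdname accessors
#' @export
setMethod("attentionMatrix", "AttentionNetwork", function(x) {
  S <- x@S
  dimnames(S) <- list(x@geneIds, x@geneIds)
  S
})

#' @rdname accessors
#' @export
setMethod("attentionMatrix", "GTLFit", function(x) attentionMatrix(x@network))

#' @rdname accessors
#' @export
setMethod("manifoldMatrix", "ManifoldGraph", function(x) x@Z)

#' @rdname accessors
#' @export
setMethod("manifoldMatrix", "GTLFit", function(x) x@manifold@Z)

#' @rdname accessors
#' @export
setMethod("regulons", "RegulonSet", function(x) x@regulons)

#' @rdname accessors
#' @export
setMethod("lossLog", "GTLFit", function(x) x@lossLog)

#' @rdname accessors
#' @export
setMethod("truthNetwork", "SyntheticSRT", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("domainLabels", "SyntheticSRT", function(x)
  SummarizedExperiment::colData(x@experiment)$domain)

#' @rdname accessors
#' @export
setMethod("spotCoords", "SyntheticSRT", function(x) spotCoords(x@experiment))
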