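#' Accessors for graphDTI S4 objects
#'
#' @param x an object.
#' @param ... ignored.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("drugs", function(x, ...) standardGeneric("drugs"))

#' @rdname accessors
#' @export
setGeneric("targets", function(x, ...) standardGeneric("targets"))

#' @rdname accessors
#' @export
setGeneric("interactions", function(x, ...) standardGeneric("interactions"))

#' @rdname accessors
#' @export
setGeneric("similarityValues", function(x, ...)
  standardGeneric("similarityValues"))

#' @rdname accessors
#' @export
setGeneric("entityIds", function(x, ...) standardGeneric("entityIds"))

#' @rdname accessors
#' @export
setGeneric("nNodes", function(x, ...) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setGeneric("nodeFeatures", function(x, ...) standardGeneric("nodeFeatures"))

#' @rdname accessors
#' @export
setGeneric("rawAdjacency", function(x, ...) standardGeneric("rawAdjacency"))

#' @rdname accessors
#' @export
setGeneric("normAdjacency", function(x, ...) standardGeneric("normAdjacency"))

#' @rdname accessors
#' @export
setMethod("drugs", "DTIBundle", function(x, ...) x@drugs)

#' @rdname accessors
#' @export
setMethod("targets", "DTIBundle", function(x, ...) x@targets)

#' @rdname accessors
#' @export
setMethod("interactions", "DTIBundle", function(x, ...) x@interactions)

#' @rdname accessors
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(x, ...) {
  v <- x@values
  dimnames(v) <- list(x@ids, x@ids)
  v
})

#' @rdname accessors
#' @export
setMethod("entityIds", "SimilarityMatrix", function(x, ...) x@ids)

#' @rdname accessors
#' @export
setMethod("nNodes", "ProteinGraph", function(x, ...) nrow(x@nodeFeatures))

#' @rdname accessors
#' @export
setMethod("nodeFeatures", "ProteinGraph", function(x, ...) x@nodeFeatures)

#' @rdname accessors
#' @export
setMethod("rawAdjacency", "ProteinGraph", function(x, ...) x@rawAdjacency)

#' @rdname accessors
#' @export
setMethod("normAdjacency", "ProteinGraph", function(x, ...) x@normAdjacency)

setMethod("show", "ProteinGraph", function(object) {
  n <- nNodes(object)
  cat(sprintf("ProteinGraph '%s': %d residues, %d contact edges, %d features/node\n",
              object@targetId, n, sum(object@rawAdjacency) / 2,
              ncol(object@nodeFeatures)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s): %d x %d\n", object@kind,
              length(object@ids), length(object@ids)))
})

setMethod("show", "DTIBundle", function(object) {
  i <- object@interactions
  cat(sprintf("DTIBundle: %d drugs, %d targets, %d interactions (%d+/%d-)\n",
              nrow(object@drugs), nrow(object@targets), nrow(i),
              sum(i$label == 1), sum(i$label == 0)))
  extras <- c(coords = length(object@coords),
              fingerprints = length(object@fingerprints),
              drugEmbeddings = length(object@drugEmbeddings),
              residueEmbeddings = length(object@residueEmbeddings))
  extras <- extras[extras > 0]
  if (length(extras))
    cat("  payloads:", paste(names(extras), extras, sep = "=", collapse = ", "),
        "\n")
})

setMethod("show", "EmbeddingProvider", function(object) {
  cat(sprintf("EmbeddingProvider '%s': dDrug=%d, dRes=%d, deterministic=%s\n",
              object@name, object@dDrug, object@dRes, object@deterministic))
})

setMethod("show", "DTIModel", function(object) {
  np <- sum(vapply(object@params, length, numeric(1)))
  abl <- if (length(object@config@ablation))
    paste(object@config@ablation, collapse = ",") else "none"
  cat(sprintf("DTIModel: hidden=%d, gcnLayers=%d, %d parameters, ablation=%s\n",
              object@config@hiddenDim, object@config@gcnLayers, np, abl))
})
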