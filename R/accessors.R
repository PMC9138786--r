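#' Drug identifiers of an object
#'
#' Canonical drug ordering carried by feature containers. All matrices in a
#' container are row-aligned on this ordering.
#'
#' @param x a [DrugFeatureSet-class], [ReceptorProfileSet-class],
#'   [FusedSimilarity-class] or [PlantedWorld-class] object.
#' @return character vector of drug ids.
#' @name drugIds
NULL

#' @rdname drugIds
#' @export
setMethod("drugIds", "DrugFeatureSet", function(x) x@drugIds)

#' @rdname drugIds
#' @export
setMethod("drugIds", "ReceptorProfileSet", function(x) x@drugIds)

#' @rdname drugIds
#' @export
setMethod("drugIds", "FusedSimilarity", function(x) rownames(x@matrix))

#' @rdname drugIds
#' @export
setMethod("drugIds", "PlantedWorld", function(x) x@drugs$drug_id)

#' Node identifiers of a graph
#'
#' @param x an [InteractionGraph-class] or [NodeEmbedding-class] object.
#' @return character vector of node ids (for graphs: the full universe,
#'   including isolated drugs).
#' @name nodeIds
NULL

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "InteractionGraph", function(x) x@nodes)

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "NodeEmbedding", function(x) rownames(x@vertexVectors))

#' Vertex and context vector tables of a node embedding
#'
#' @param x a [NodeEmbedding-class] object.
#' @return numeric matrix with one row per embedded node.
#' @name vertexVectors
NULL

#' @rdname vertexVectors
#' @export
setMethod("vertexVectors", "NodeEmbedding", function(x) x@vertexVectors)

#' @rdname vertexVectors
#' @export
setMethod("contextVectors", "NodeEmbedding", function(x) x@contextVectors)

#' Fused similarity matrix
#'
#' @param x a [FusedSimilarity-class] object.
#' @return the symmetric nonnegative N x N matrix.
#' @name fusedMatrix
NULL

#' @rdname fusedMatrix
#' @export
setMethod("fusedMatrix", "FusedSimilarity", function(x) x@matrix)

#' Coarsening hierarchy accessors
#'
#' @param x a [CoarseningHierarchy-class] object.
#' @param k level index: levels are numbered 0 (original graph) to
#'   \code{nLevels(x) - 1} (coarsest); \code{levelMap(x, k)} returns the map
#'   from level \code{k - 1} nodes to level \code{k} supernodes.
#' @return \code{nLevels}: integer; \code{levelGraph}: an
#'   [InteractionGraph-class]; \code{levelMap}: a named character vector.
#' @name nLevels
NULL

#' @rdname nLevels
#' @export
setMethod("nLevels", "CoarseningHierarchy", function(x) length(x@levels))

#' @rdname nLevels
#' @export
setMethod("levelGraph", "CoarseningHierarchy", function(x, k) {
  stopifnot(k >= 0, k < length(x@levels))
  x@levels[[k + 1L]]
})

#' @rdname nLevels
#' @export
setMethod("levelMap", "CoarseningHierarchy", function(x, k) {
  stopifnot(k >= 1, k <= length(x@maps))
  x@maps[[k]]
})

#' Profile matrix of one function type
#'
#' @param x a [ReceptorProfileSet-class] object.
#' @param type function type label (e.g. "target").
#' @return binary N x R matrix.
#' @name profileMatrix
NULL

#' @rdname profileMatrix
#' @export
setMethod("profileMatrix", "ReceptorProfileSet", function(x, type) {
  if (!type %in% names(x@profiles))
    stop("unknown function type: ", type)
  x@profiles[[type]]
})

#' Embedding vector of a single token
#'
#' @param x a [TokenEmbeddingTable-class] object.
#' @param token token string.
#' @return numeric d-vector (input-weight row).
#' @name tokenVector
NULL

#' @rdname tokenVector
#' @export
setMethod("tokenVector", "TokenEmbeddingTable", function(x, token) {
  i <- match(token, x@vocab)
  if (is.na(i)) stop("token not in vocabulary: ", token)
  x@inputWeights[i, ]
})

setMethod("show", "TokenEmbeddingTable", function(object) {
  cat("TokenEmbeddingTable:", length(object@vocab), "tokens, dim",
      ncol(object@inputWeights), "(window", object@window, ")\n")
})

setMethod("show", "InteractionGraph", function(object) {
  cat("InteractionGraph:", length(object@nodes), "drugs,",
      igraph::ecount(object@graph), "interactions\n")
})

setMethod("show", "CoarseningHierarchy", function(object) {
  sizes <- vapply(object@levels, function(g) length(g@nodes), integer(1))
  cat("CoarseningHierarchy:", length(sizes), "levels |V| =",
      paste(sizes, collapse = " -> "), "\n")
})

setMethod("show", "NodeEmbedding", function(object) {
  cat("NodeEmbedding:", nrow(object@vertexVectors), "nodes, dim",
      ncol(object@vertexVectors), "\n")
})

setMethod("show", "ReceptorProfileSet", function(object) {
  cat("ReceptorProfileSet:", length(object@drugIds), "drugs,",
      length(object@profiles), "function types\n")
  for (ty in names(object@profiles))
    cat("  ", ty, ": ", ncol(object@profiles[[ty]]), " receptors\n", sep = "")
})

setMethod("show", "FusedSimilarity", function(object) {
  cat("FusedSimilarity:", nrow(object@matrix), "drugs,",
      object@viewsUsed, "views fused (K =", object@params$K,
      ", T =", object@params$T, ", mu =", object@params$mu, ")\n")
})

setMethod("show", "DrugFeatureSet", function(object) {
  cat("DrugFeatureSet:", length(object@drugIds), "drugs\n")
  cat("  chem:", ncol(object@chemPatches), "patch columns |",
      "net:", ncol(object@net), "dims |",
      "bio:", ncol(object@bio), "dims\n")
})

setMethod("show", "DDIModel", function(object) {
  cat("DDIModel: attention-fusion DDI classifier\n")
  cat("  drugs:", length(object@features@drugIds),
      "| channels:", paste(c("chem", "net", "bio")[c(
        object@config$useChem, object@config$useNet, object@config$useBio)],
        collapse = "+"),
      "| attention:", object@config$useAttention, "\n")
  if (nrow(object@history))
    cat("  epochs trained:", nrow(object@history),
        "| best val loss:", signif(min(object@history$val), 4), "\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport over", nrow(object@perFold), "folds\n")
  print(round(object@summary, 4))
})

setMethod("show", "PlantedWorld", function(object) {
  p <- object@params
  cat("PlantedWorld:", nrow(object@drugs), "drugs,",
      nrow(object@edges), "interactions,",
      p$nCommunities, "communities (pIn =", p$pIn, ", pOut =", p$pOut, ")\n")
})
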