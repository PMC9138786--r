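#' Hierarchical (coarsen-embed-refine) graph embedding
#'
#' Embeds a graph by the hierarchical scheme: the graph is coarsened level by
#' level ([coarsenGraph()]), the coarsest level is embedded from random
#' initialization with [line2Embed()], and each finer level is then
#' initialized by prolongation -- every node starts from its supernode's
#' vertex and context vectors -- and refined with the same objective. The
#' coarse solve anchors the embedding in the graph's global structure while
#' the refinements recover local detail.
#'
#' @param g an [InteractionGraph-class] with at least one edge.
#' @param dim embedding dimension, default 64.
#' @param threshold coarsening stop size; default
#'   \code{max(100, ceiling(|V|/32))}.
#' @param epochs,negK,lr LINE training controls per level, see
#'   [line2Embed()].
#' @param seed integer seed; level refinements draw from consecutive seeds.
#' @return a [NodeEmbedding-class] over the non-isolated nodes of \code{g}.
#' @export
harpEmbed <- function(g, dim = 64L, threshold = NULL, epochs = 100L,
                      negK = 5L, lr = 0.025, seed = 1L) {
  stopifnot(is(g, "InteractionGraph"))
  if (!nrow(graphEdges(g))) stop("cannot embed: no edges")
  if (is.null(threshold))
    threshold <- max(100L, ceiling(length(g@nodes) / 32))
  hier <- coarsenGraph(g, threshold = threshold)
  L <- nLevels(hier)

  emb <- line2Embed(levelGraph(hier, L - 1L), dim = dim, epochs = epochs,
                    negK = negK, lr = lr, seed = seed)
  if (L == 1L) return(emb)

  for (k in (L - 1L):1L) {
    fine <- levelGraph(hier, k - 1L)
    map <- levelMap(hier, k)                 # fine node -> supernode
    fineNodes <- .embeddedNodes(fine)
    init <- .prolong(emb, map, fineNodes, dim)
    emb <- line2Embed(fine, dim = dim, init = init, epochs = epochs,
                      negK = negK, lr = lr, seed = seed + (L - k))
  }
  emb
}

# non-isolated nodes of a graph, i.e. those line2Embed will cover
.embeddedNodes <- function(g) {
  ed <- graphEdges(g)
  sort(unique(c(ed$from, ed$to)))
}

# copy supernode vectors down to the finer level's nodes
.prolong <- function(emb, map, fineNodes, dim) {
  sup <- map[fineNodes]
  U <- matrix(0, length(fineNodes), dim, dimnames = list(fineNodes, NULL))
  Uc <- U
  hit <- sup %in% rownames(emb@vertexVectors)
  U[hit, ] <- emb@vertexVectors[sup[hit], , drop = FALSE]
  Uc[hit, ] <- emb@contextVectors[sup[hit], , drop = FALSE]
  new("NodeEmbedding", vertexVectors = U, contextVectors = Uc)
}

#' Embedding vector of a drug, with the missing-node fallback
#'
#' Drugs absent from the training graph cannot be embedded. The fallback
#' rule: an embedded drug returns its own vector; an unembedded drug with at
#' least one embedded neighbour in the training graph returns a copy of the
#' lexicographically smallest such neighbour's vector (a deterministic
#' "nearest neighbour"); a fully isolated drug returns the zero vector.
#'
#' @param drug drug id.
#' @param g the training [InteractionGraph-class].
#' @param emb a [NodeEmbedding-class] of \code{g}.
#' @return numeric d-vector.
#' @export
embedOrFallback <- function(drug, g, emb) {
  d <- ncol(emb@vertexVectors)
  if (drug %in% rownames(emb@vertexVectors))
    return(emb@vertexVectors[drug, ])
  if (drug %in% g@nodes) {
    nb <- igraph::neighbors(g@graph, drug)
    nb <- sort(igraph::V(g@graph)$name[nb])
    nb <- nb[nb %in% rownames(emb@vertexVectors)]
    if (length(nb))
      return(emb@vertexVectors[nb[1L], ])
  }
  numeric(d)
}
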