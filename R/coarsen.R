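#' Coarsen an interaction graph into a hierarchy
#'
#' Repeatedly shrinks the graph by one coarsening step per level until the
#' node count reaches \code{threshold} or a step yields no reduction. Each
#' step applies the two collapsing passes of the hierarchical (HARP) scheme:
#' \describe{
#'   \item{star collapsing}{visiting hubs in decreasing degree order, pairs
#'     of a hub's still-unmatched neighbours are merged two at a time --
#'     this shrinks star-like regions whose leaves share the hub as context;}
#'   \item{edge collapsing}{a maximal matching over the remaining edges is
#'     contracted, merging each matched edge's endpoints.}
#' }
#' Merged parallel edges sum their weights; edges internal to a merged group
#' become self-loops and are removed. Supernodes take the lexicographically
#' smallest member id, which makes the hierarchy deterministic.
#'
#' Isolated nodes take no part in collapsing and are carried through
#' unchanged (they can keep the graph above \code{threshold}; coarsening
#' still stops once no pass reduces the graph).
#'
#' @param g an [InteractionGraph-class].
#' @param threshold stop once the level has at most this many nodes.
#' @return a [CoarseningHierarchy-class]; level 0 is \code{g} itself.
#' @export
coarsenGraph <- function(g, threshold = 100L) {
  stopifnot(is(g, "InteractionGraph"), threshold >= 1)
  levels <- list(g)
  maps <- list()
  repeat {
    cur <- levels[[length(levels)]]
    if (length(cur@nodes) <= threshold) break
    res <- .coarsenStep(cur)
    if (is.null(res) || length(res$graph@nodes) >= length(cur@nodes)) break
    levels[[length(levels) + 1L]] <- res$graph
    maps[[length(maps) + 1L]] <- res$map
  }
  new("CoarseningHierarchy", levels = levels, maps = maps)
}

# one star-collapsing + edge-collapsing pass; returns NULL if nothing merged
.coarsenStep <- function(g) {
  ig <- g@graph
  nodes <- igraph::V(ig)$name              # igraph vertex order
  n <- length(nodes)
  group <- seq_len(n)                      # group label per vertex
  names(group) <- nodes
  matched <- rep(FALSE, n)
  adj <- lapply(igraph::adjacent_vertices(ig, igraph::V(ig)),
                function(v) igraph::V(ig)$name[v])
  names(adj) <- nodes

  deg <- vapply(adj, length, integer(1))[nodes]
  ord <- order(-deg, nodes)                # hubs first; ties by id

  # star collapsing: merge pairs of a hub's unmatched neighbours
  for (hub in nodes[ord]) {
    nb <- sort(adj[[hub]])
    nb <- nb[!matched[match(nb, nodes)]]
    nb <- setdiff(nb, hub)
    while (length(nb) >= 2L) {
      u <- nb[1L]; v <- nb[2L]; nb <- nb[-c(1L, 2L)]
      iu <- match(u, nodes); iv <- match(v, nodes)
      group[iv] <- group[iu]
      matched[c(iu, iv)] <- TRUE
    }
  }

  # edge collapsing: maximal matching over edges in deterministic order
  ed <- igraph::as_data_frame(ig, what = "edges")
  if (nrow(ed)) {
    lo <- pmin(ed$from, ed$to); hi <- pmax(ed$from, ed$to)
    eord <- order(lo, hi)
    for (k in eord) {
      iu <- match(ed$from[k], nodes); iv <- match(ed$to[k], nodes)
      if (!matched[iu] && !matched[iv]) {
        group[iv] <- group[iu]
        matched[c(iu, iv)] <- TRUE
      }
    }
  }

  if (!any(matched)) return(NULL)

  # supernode id = lexicographically smallest member
  super <- vapply(split(nodes, group), min, character(1))
  mapping <- match(group, sort(unique(group)))
  superIds <- super[as.character(sort(unique(group)))]
  cg <- igraph::contract(ig, mapping)
  cg <- igraph::simplify(cg, remove.multiple = TRUE, remove.loops = TRUE,
                         edge.attr.comb = list(weight = "sum", "ignore"))
  igraph::V(cg)$name <- unname(superIds)
  nodeMap <- stats::setNames(unname(superIds[mapping]), nodes)
  newNodes <- sort(unname(superIds))
  cg <- igraph::permute(cg, match(igraph::V(cg)$name, newNodes))
  list(graph = new("InteractionGraph", graph = cg, nodes = newNodes),
       map = nodeMap)
}

#' Total edge weight of a graph
#'
#' @param g an [InteractionGraph-class].
#' @return sum of edge weights (0 for edgeless graphs).
#' @export
totalEdgeWeight <- function(g) {
  w <- igraph::E(g@graph)$weight
  if (length(w)) sum(w) else 0
}
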