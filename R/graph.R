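#' Build the drug-drug interaction graph
#'
#' Constructs a simple weighted undirected graph from an edge list of drug-id
#' pairs. Duplicate and reversed pairs are merged (weights summed when given,
#' else the merged edge keeps weight 1); self-pairs are dropped with a
#' warning. Drugs named in \code{nodes} but absent from any edge are retained
#' as isolated vertices, so the embedding fallback can see them.
#'
#' @param edges two-column data.frame or matrix of drug-id pairs; an optional
#'   third numeric column gives edge weights (default 1).
#' @param nodes character vector, the drug universe; defaults to the drugs
#'   appearing in \code{edges}. Edges naming drugs outside the universe are
#'   an error.
#' @param sumDuplicates when TRUE, duplicated pairs add their weights;
#'   default FALSE (duplicates collapse to a single unit edge).
#' @return an [InteractionGraph-class].
#' @examples
#' g <- buildGraph(data.frame(a = c("A", "B"), b = c("B", "A")),
#'                 nodes = c("A", "B", "C"))
#' nodeIds(g)
#' @export
buildGraph <- function(edges, nodes = NULL, sumDuplicates = FALSE) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) stop("edge list needs two drug-id columns")
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  w <- if (ncol(edges) >= 3L && is.numeric(edges[[3L]])) as.numeric(edges[[3L]])
       else rep(1, length(a))
  if (is.null(nodes)) nodes <- sort(unique(c(a, b)))
  nodes <- as.character(nodes)
  bad <- setdiff(c(a, b), nodes)
  if (length(bad))
    stop("edges reference drugs outside the universe: ",
         paste(utils::head(bad, 5L), collapse = ", "))

  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped")
    a <- a[!self]; b <- b[!self]; w <- w[!self]
  }
  if (!length(a)) {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(nodes)
    return(new("InteractionGraph", graph = g, nodes = nodes))
  }
  # canonical unordered orientation, then merge duplicates
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  ww <- if (sumDuplicates) tapply(w, key, sum)
        else tapply(w, key, function(x) x[1L])
  parts <- strsplit(names(ww), "\r", fixed = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = vapply(parts, `[[`, "", 1L),
               to = vapply(parts, `[[`, "", 2L),
               weight = as.numeric(ww)),
    directed = FALSE, vertices = nodes
  )
  new("InteractionGraph", graph = g, nodes = nodes)
}

#' Edge table of an interaction graph
#'
#' @param g an [InteractionGraph-class].
#' @return data.frame(from, to, weight), one row per undirected edge.
#' @export
graphEdges <- function(g) {
  stopifnot(is(g, "InteractionGraph"))
  df <- igraph::as_data_frame(g@graph, what = "edges")
  if (!nrow(df)) return(data.frame(from = character(0), to = character(0),
                                   weight = numeric(0)))
  df[, c("from", "to", "weight")]
}

#' Weighted node degrees
#'
#' @param g an [InteractionGraph-class].
#' @return named numeric vector: sum of incident edge weights per node, over
#'   the full node universe (isolated drugs have degree 0).
#' @export
graphDegrees <- function(g) {
  stopifnot(is(g, "InteractionGraph"))
  s <- igraph::strength(g@graph, weights = igraph::E(g@graph)$weight)
  s[g@nodes]
}
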