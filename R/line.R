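#' Second-order LINE embedding of a weighted graph
#'
#' Learns vertex vectors u and context vectors u' minimizing the
#' second-order proximity objective
#' \deqn{O_2 = -\sum_{(i,j)} w_{ij} \log p_2(v_j | v_i)}
#' where \eqn{p_2(v_j|v_i)} is the softmax of \eqn{u'_j \cdot u_i} over all
#' context vertices: nodes that share neighbours end up with nearby vertex
#' vectors. Each undirected edge contributes in both directions.
#'
#' Training uses edge-sampling stochastic gradient descent: edges are drawn
#' with probability proportional to their weight, and the intractable softmax
#' normalizer is replaced during training by negative sampling with
#' \code{negK} noise vertices drawn proportionally to (weighted) degree to
#' the 3/4 power. Updates are applied strictly one sample at a time (the
#' compiled inner loop), each against the current parameter values, with the
#' learning rate decaying linearly to 1e-4 of its initial value. The exact
#' softmax objective is available separately as [lineObjective()] for
#' verification on small graphs. Deterministic per seed in single-threaded
#' mode.
#'
#' Only vertices incident to at least one edge are embedded; isolated
#' vertices have no second-order context and are handled downstream by
#' [embedOrFallback()].
#'
#' @param g an [InteractionGraph-class] with at least one edge.
#' @param dim embedding dimension, default 64.
#' @param init optional [NodeEmbedding-class] used as warm start (vectors are
#'   copied for every embedded node present in \code{init}).
#' @param epochs sampling passes; one epoch draws as many edge samples as
#'   there are directed edges.
#' @param negK negative samples per edge sample, default 5.
#' @param lr initial learning rate (LINE convention), default 0.025.
#' @param seed integer seed.
#' @return a [NodeEmbedding-class] over the embedded (non-isolated) nodes.
#' @export
line2Embed <- function(g, dim = 64L, init = NULL, epochs = 100L, negK = 5L,
                       lr = 0.025, seed = 1L) {
  stopifnot(is(g, "InteractionGraph"))
  ed <- graphEdges(g)
  if (!nrow(ed)) stop("cannot embed: no edges")
  nodes <- sort(unique(c(ed$from, ed$to)))
  n <- length(nodes)
  # directed edge list: both orientations of every undirected edge
  src <- match(c(ed$from, ed$to), nodes)
  dst <- match(c(ed$to, ed$from), nodes)
  w <- c(ed$weight, ed$weight)
  m <- length(src)

  set.seed(seed)
  U <- matrix(stats::runif(n * dim, -0.5, 0.5) / dim, n, dim)
  Uc <- matrix(0, n, dim)
  if (!is.null(init)) {
    stopifnot(is(init, "NodeEmbedding"))
    hit <- intersect(nodes, rownames(init@vertexVectors))
    U[match(hit, nodes), ] <- init@vertexVectors[hit, , drop = FALSE]
    Uc[match(hit, nodes), ] <- init@contextVectors[hit, , drop = FALSE]
  }

  strength <- as.numeric(rowsum(c(w, w), c(src, dst))[, 1L])
  noiseCum <- cumsum(strength^0.75); noiseCum <- noiseCum / noiseCum[length(noiseCum)]
  edgeCum <- cumsum(w); edgeCum <- edgeCum / edgeCum[m]

  # samples are pre-drawn with R's RNG (seeded), then consumed strictly
  # sequentially by the compiled SGD loop
  totalSamples <- epochs * m
  e <- findInterval(stats::runif(totalSamples), edgeCum) + 1L
  neg <- findInterval(stats::runif(totalSamples * negK), noiseCum) + 1L
  fit <- .lineSgdCpp(U, Uc, src[e], dst[e], neg, as.integer(negK), lr)
  U <- fit$U
  Uc <- fit$Uc
  rownames(U) <- rownames(Uc) <- nodes
  new("NodeEmbedding", vertexVectors = U, contextVectors = Uc)
}

#' Exact second-order co-occurrence distribution
#'
#' Evaluates the full softmax \eqn{p_2(\cdot|v_i)} for every source vertex:
#' row i holds the probability of each vertex being a context of i. Every row
#' sums to 1 for any parameterization. Intended for verification on small
#' graphs (cost is quadratic in the number of nodes).
#'
#' @param emb a [NodeEmbedding-class].
#' @return n x n matrix of probabilities, dimnames = node ids.
#' @export
lineSoftmax <- function(emb) {
  S <- tcrossprod(emb@vertexVectors, emb@contextVectors)
  P <- .softmaxRows(S)
  dimnames(P) <- list(rownames(emb@vertexVectors), rownames(emb@vertexVectors))
  P
}

#' Exact second-order LINE objective
#'
#' The weighted negative log-likelihood
#' \eqn{O_2 = -\sum_{(i,j)} w_{ij} \log p_2(v_j|v_i)} evaluated with the
#' exact softmax, summing both directions of every undirected edge. This is
#' the quantity [line2Embed()] minimizes (negative sampling is its training
#' surrogate only).
#'
#' @param g an [InteractionGraph-class].
#' @param emb a [NodeEmbedding-class] covering all non-isolated nodes of g.
#' @return scalar objective value.
#' @export
lineObjective <- function(g, emb) {
  ed <- graphEdges(g)
  if (!nrow(ed)) stop("cannot evaluate: no edges")
  P <- lineSoftmax(emb)
  ids <- rownames(P)
  i <- match(c(ed$from, ed$to), ids)
  j <- match(c(ed$to, ed$from), ids)
  if (anyNA(i) || anyNA(j)) stop("embedding does not cover all edge endpoints")
  w <- c(ed$weight, ed$weight)
  -sum(w * log(P[cbind(i, j)]))
}
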