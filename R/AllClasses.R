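#' @import methods
NULL

#' Token embedding table learned by CBOW
#'
#' Holds the vocabulary and the two weight matrices of a continuous
#' bag-of-words (CBOW) model trained on tokenized SMILES strings: the input
#' weights (one embedding row per token, the representation used downstream)
#' and the output weights (the softmax layer used to score center tokens).
#'
#' @slot vocab character vector of tokens; position defines the token index.
#' @slot inputWeights numeric matrix (V x d), the token embeddings.
#' @slot outputWeights numeric matrix (V x d), the output (softmax) weights.
#' @slot window integer, context half-window used in training.
#' @slot counts integer vector of training-corpus token counts.
#'
#' @exportClass TokenEmbeddingTable
setClass("TokenEmbeddingTable",
  representation(
    vocab = "character",
    inputWeights = "matrix",
    outputWeights = "matrix",
    window = "integer",
    counts = "integer"
  )
)

setValidity("TokenEmbeddingTable", function(object) {
  msg <- NULL
  V <- length(object@vocab)
  if (nrow(object@inputWeights) != V)
    msg <- c(msg, "inputWeights must have one row per vocabulary token")
  if (!identical(dim(object@inputWeights), dim(object@outputWeights)))
    msg <- c(msg, "inputWeights and outputWeights must share dimensions")
  if (anyDuplicated(object@vocab))
    msg <- c(msg, "vocabulary tokens must be unique")
  if (is.null(msg)) TRUE else msg
})

#' Undirected drug-drug interaction graph
#'
#' A simple weighted undirected graph over a fixed drug universe. Drugs with
#' no known interaction are kept in the universe but carry no edges, so the
#' downstream embedding fallback (nearest neighbour, else zero vector) can
#' distinguish "isolated" from "absent".
#'
#' @slot graph an \pkg{igraph} object (undirected, simple, weighted).
#' @slot nodes character vector: the full drug universe, in canonical order.
#'
#' @exportClass InteractionGraph
setClass("InteractionGraph",
  representation(graph = "ANY", nodes = "character")
)

setValidity("InteractionGraph", function(object) {
  g <- object@graph
  msg <- NULL
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "graph must have no self-loops")
  w <- igraph::E(g)$weight
  if (length(w) && any(w <= 0)) msg <- c(msg, "edge weights must be positive")
  if (!all(igraph::V(g)$name %in% object@nodes))
    msg <- c(msg, "all graph vertices must belong to the node universe")
  if (is.null(msg)) TRUE else msg
})

#' Graph coarsening hierarchy
#'
#' Ordered sequence of graphs from the original (level 0) down to the
#' coarsest level, together with the surjective node-to-supernode map of each
#' coarsening step. Level sizes are strictly decreasing.
#'
#' @slot levels list of [InteractionGraph-class] objects, finest first.
#' @slot maps list of named character vectors; \code{maps[[k]]} sends each
#'   node of level k-1 to its supernode in level k.
#'
#' @exportClass CoarseningHierarchy
setClass("CoarseningHierarchy",
  representation(levels = "list", maps = "list")
)

setValidity("CoarseningHierarchy", function(object) {
  msg <- NULL
  sizes <- vapply(object@levels, function(g) length(g@nodes), integer(1))
  if (length(object@maps) != length(object@levels) - 1L)
    msg <- c(msg, "need exactly one map per coarsening step")
  if (length(sizes) > 1 && any(diff(sizes) >= 0))
    msg <- c(msg, "level sizes must strictly decrease")
  for (k in seq_along(object@maps)) {
    m <- object@maps[[k]]
    if (!setequal(names(m), object@levels[[k]]@nodes))
      msg <- c(msg, sprintf("map %d must be defined on every level-%d node", k, k - 1L))
    if (!setequal(unique(unname(m)), object@levels[[k + 1L]]@nodes))
      msg <- c(msg, sprintf("map %d must be surjective onto level %d", k, k))
  }
  if (is.null(msg)) TRUE else msg
})

#' Node embedding (second-order LINE)
#'
#' Vertex and context vector tables produced by the second-order LINE
#' objective: nodes sharing neighbours obtain nearby vertex vectors.
#'
#' @slot vertexVectors numeric matrix (n x d), rownames are node ids.
#' @slot contextVectors numeric matrix (n x d), rownames are node ids.
#'
#' @exportClass NodeEmbedding
setClass("NodeEmbedding",
  representation(vertexVectors = "matrix", contextVectors = "matrix")
)

setValidity("NodeEmbedding", function(object) {
  msg <- NULL
  if (!identical(dim(object@vertexVectors), dim(object@contextVectors)))
    msg <- c(msg, "vertex and context tables must share dimensions")
  if (!identical(rownames(object@vertexVectors), rownames(object@contextVectors)))
    msg <- c(msg, "vertex and context tables must cover the same nodes")
  if (nrow(object@vertexVectors) > 0L && is.null(rownames(object@vertexVectors)))
    msg <- c(msg, "embeddings must be indexed by node id (rownames)")
  if (is.null(msg)) TRUE else msg
})

#' Per-receptor-type binary drug profiles
#'
#' One binary incidence matrix per biological function type (carrier, target,
#' enzyme, transporter, ...): entry (i, r) is 1 when drug i is associated with
#' receptor r of that type. The number of columns of each view equals the
#' number of distinct receptors of that type.
#'
#' @slot drugIds character vector, canonical drug ordering shared by all views.
#' @slot profiles named list of binary matrices (N x R_type).
#'
#' @exportClass ReceptorProfileSet
setClass("ReceptorProfileSet",
  representation(drugIds = "character", profiles = "list")
)

setValidity("ReceptorProfileSet", function(object) {
  msg <- NULL
  for (ty in names(object@profiles)) {
    m <- object@profiles[[ty]]
    if (nrow(m) != length(object@drugIds))
      msg <- c(msg, sprintf("view '%s' must have one row per drug", ty))
    if (length(m) && !all(m %in% c(0, 1)))
      msg <- c(msg, sprintf("view '%s' must be binary", ty))
  }
  if (is.null(msg)) TRUE else msg
})

#' Fused drug-drug similarity (SNF output)
#'
#' The single N x N similarity matrix obtained by similarity network fusion
#' of the per-function-type affinity views, plus the fusion parameters.
#'
#' @slot matrix numeric N x N matrix, symmetric, nonnegative; dimnames are
#'   drug ids in canonical order.
#' @slot viewsUsed integer, number of views that entered the fusion.
#' @slot params list with elements K (neighbours), T (iterations), mu.
#'
#' @exportClass FusedSimilarity
setClass("FusedSimilarity",
  representation(matrix = "matrix", viewsUsed = "integer", params = "list")
)

setValidity("FusedSimilarity", function(object) {
  m <- object@matrix
  msg <- NULL
  if (nrow(m) != ncol(m)) msg <- c(msg, "fused matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    msg <- c(msg, "fused matrix must carry identical drug-id dimnames")
  if (length(m) && max(abs(m - t(m))) > 1e-8)
    msg <- c(msg, "fused matrix must be symmetric")
  if (length(m) && min(m) < -1e-12) msg <- c(msg, "fused matrix must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' Per-drug feature channels for the fusion model
#'
#' Precomputed inputs of the attention-fusion classifier, aligned on a shared
#' canonical drug ordering: the chemical-sequence matrices (stored in the
#' sparse patch layout consumed by the convolutional reducer), the network
#' embedding vectors, and the fused biological-similarity rows. Channels that
#' cannot be computed for a drug are all-zero, never missing.
#'
#' @slot drugIds character, canonical drug ordering.
#' @slot chemPatches numeric matrix, stacked 3x3 patch rows of all drug
#'   matrices (input of the convolutional reducer).
#' @slot chemOffsets integer vector (n+1), row offsets of each drug's patch
#'   block within \code{chemPatches}.
#' @slot chemZeroPatches integer vector (n), count of all-zero patch positions
#'   of each drug (accounted for analytically by the reducer).
#' @slot net numeric matrix (n x d), network-channel vectors.
#' @slot bio numeric matrix (n x N), fused biological-similarity rows.
#' @slot cbow the [TokenEmbeddingTable-class] used to build the matrices.
#' @slot embedding the [NodeEmbedding-class] of the training graph.
#' @slot fused the [FusedSimilarity-class] behind the bio channel.
#' @slot graph the training [InteractionGraph-class].
#'
#' @exportClass DrugFeatureSet
setClass("DrugFeatureSet",
  representation(
    drugIds = "character",
    chemPatches = "matrix",
    chemOffsets = "integer",
    chemZeroPatches = "integer",
    net = "matrix",
    bio = "matrix",
    cbow = "TokenEmbeddingTable",
    embedding = "NodeEmbedding",
    fused = "FusedSimilarity",
    graph = "InteractionGraph",
    cache = "environment"
  )
)

# every instance gets its own scratch environment (holds the single-precision
# patch cache used by the compiled reducer; rebuilt on demand, never saved)
setMethod("initialize", "DrugFeatureSet", function(.Object, ...) {
  .Object <- callNextMethod(.Object, ...)
  .Object@cache <- new.env(parent = emptyenv())
  .Object
})

setValidity("DrugFeatureSet", function(object) {
  n <- length(object@drugIds)
  msg <- NULL
  if (length(object@chemOffsets) != n + 1L)
    msg <- c(msg, "chemOffsets must have n+1 entries")
  if (nrow(object@net) != n) msg <- c(msg, "net must have one row per drug")
  if (nrow(object@bio) != n) msg <- c(msg, "bio must have one row per drug")
  if (is.null(msg)) TRUE else msg
})

#' Trained attention-fusion DDI classifier
#'
#' End-to-end trained model: the channel reducers (convolutional chem reducer,
#' dense net reducer, two-layer bio reducer), the scaled dot-product attention
#' block, and the three-hidden-layer classifier head, together with the
#' feature set they were trained against and the training history.
#'
#' @slot weights named list of weight matrices and bias vectors.
#' @slot config resolved training configuration (see [ddiConfig()]).
#' @slot features the [DrugFeatureSet-class] used at training time.
#' @slot history data.frame with per-epoch train/validation loss.
#'
#' @exportClass DDIModel
setClass("DDIModel",
  representation(
    weights = "list",
    config = "list",
    features = "DrugFeatureSet",
    history = "data.frame"
  )
)

#' Cross-validated evaluation report
#'
#' Per-fold classification metrics (Acc, Prec, Sen, F1, MCC, AUC, AUPR) and
#' their mean and standard deviation across folds.
#'
#' @slot perFold data.frame, one row per fold.
#' @slot summary data.frame with rows "mean" and "sd".
#'
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(perFold = "data.frame", summary = "data.frame")
)

#' Synthetic planted-community world
#'
#' A fully synthetic dataset in the pipeline's input formats: drugs with
#' SMILES-like strings, a community-structured interaction edge list, and
#' block-structured drug-receptor associations. In signal worlds
#' (\code{pIn > pOut}) interacting pairs are statistically recoverable from
#' all three channels; in null worlds (\code{pIn == pOut}) there is no signal.
#'
#' @slot drugs data.frame(drug_id, smiles).
#' @slot edges data.frame(drug_id_a, drug_id_b).
#' @slot associations data.frame(drug_id, receptor_id, function_type).
#' @slot community named integer vector, community of each drug.
#' @slot params generator parameters, including the master seed.
#'
#' @exportClass PlantedWorld
setClass("PlantedWorld",
  representation(
    drugs = "data.frame",
    edges = "data.frame",
    associations = "data.frame",
    community = "integer",
    params = "list"
  )
)
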