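#' Build the per-drug feature channels
#'
#' Computes the three precomputed channel inputs of the fusion classifier
#' over a canonical (sorted) drug ordering:
#' \enumerate{
#'   \item chem: SMILES are tokenized and a CBOW table is trained on the
#'     whole corpus (unsupervised, label-free); each drug's token vectors are
#'     stacked into its \code{lMax x d} sequence matrix, stored in the patch
#'     layout consumed by the convolutional reducer;
#'   \item net: the training-fold interaction graph is embedded with
#'     [harpEmbed()] and every drug receives a vector via
#'     [embedOrFallback()] (so drugs unseen in the training graph degrade
#'     gracefully to a neighbour's vector or zero);
#'   \item bio: receptor profiles are built per function type, fused with
#'     [snfFuse()], and each drug takes its row of the fused matrix.
#' }
#' Only the training-fold positive edges may enter \code{trainEdges}; the
#' chem and bio channels use no interaction labels at all, so the split
#' protocol's leakage rule is enforced here by construction.
#'
#' @param drugs data.frame(drug_id, smiles).
#' @param trainEdges two-column data.frame of training-fold positive pairs
#'   (may be empty).
#' @param associations data.frame(drug_id, receptor_id, function_type);
#'   may be empty, in which case the bio channel is all zero.
#' @param config list from [ddiConfig()].
#' @param seed integer seed (CBOW and graph-embedding training).
#' @return a [DrugFeatureSet-class].
#' @export
buildFeatureSet <- function(drugs, trainEdges, associations,
                            config = ddiConfig(), seed = 1L) {
  drugs <- as.data.frame(drugs)
  stopifnot(all(c("drug_id", "smiles") %in% names(drugs)))
  ids <- sort(as.character(drugs$drug_id))
  n <- length(ids)
  smiles <- stats::setNames(as.character(drugs$smiles),
                            as.character(drugs$drug_id))[ids]

  # --- chem channel -------------------------------------------------------
  corpus <- tokenizeCorpus(smiles, mode = config$tokenizer)
  cbow <- trainCbow(corpus, dim = config$cbowDim, window = config$cbowWindow,
                    minCount = config$cbowMinCount,
                    epochs = config$cbowEpochs, lr = config$cbowLr,
                    batchSize = config$cbowBatch, seed = seed)
  patchList <- vector("list", n)
  nzero <- integer(n)
  for (i in seq_len(n)) {
    M <- buildDrugMatrix(corpus[[ids[i]]], cbow, lMax = config$lMax)
    p <- .drugPatches(M, size = config$convSize)
    patchList[[i]] <- p$X
    nzero[i] <- p$nzero
  }
  rows <- vapply(patchList, nrow, integer(1))
  offsets <- as.integer(c(0L, cumsum(rows)))
  patches <- do.call(rbind, patchList)

  # --- net channel --------------------------------------------------------
  graph <- buildGraph(trainEdges, nodes = ids)
  d <- config$embedDim
  if (nrow(graphEdges(graph))) {
    emb <- harpEmbed(graph, dim = d, threshold = config$coarsenThreshold,
                     epochs = config$lineEpochs, negK = config$lineNegK,
                     lr = config$lineLr, seed = seed + 101L)
  } else {
    emb <- new("NodeEmbedding",
               vertexVectors = matrix(0, 0L, d,
                                      dimnames = list(character(0), NULL)),
               contextVectors = matrix(0, 0L, d,
                                       dimnames = list(character(0), NULL)))
  }
  net <- t(vapply(ids, function(id) embedOrFallback(id, graph, emb),
                  numeric(d)))
  rownames(net) <- ids

  # --- bio channel --------------------------------------------------------
  associations <- as.data.frame(associations)
  if (nrow(associations)) {
    profiles <- buildProfiles(associations, ids)
  } else {
    profiles <- new("ReceptorProfileSet", drugIds = ids, profiles = list())
  }
  if (length(profiles@profiles)) {
    fused <- snfFuse(profiles, K = config$snfK, T = config$snfT,
                     mu = config$snfMu)
    bio <- fusedMatrix(fused)
  } else {
    zm <- matrix(0, n, n, dimnames = list(ids, ids))
    fused <- new("FusedSimilarity", matrix = zm, viewsUsed = 0L,
                 params = list(K = config$snfK, T = config$snfT,
                               mu = config$snfMu))
    bio <- zm
  }

  # --- channel standardization -------------------------------------------
  # the three raw channels live on very different scales (CBOW embeddings,
  # LINE coordinates, row-stochastic similarities); bringing them to unit
  # scale conditions the joint optimization. The chem patches are scaled by
  # one global factor so that zero padding stays exactly zero; net and bio
  # are column z-scored (constant columns left alone).
  if (nrow(patches)) {
    s <- stats::sd(patches)
    if (is.finite(s) && s > 1e-12) patches <- patches / s
  }
  net <- .zscoreCols(net)
  bio <- .zscoreCols(bio)

  new("DrugFeatureSet",
      drugIds = ids,
      chemPatches = patches, chemOffsets = offsets,
      chemZeroPatches = as.integer(nzero),
      net = net, bio = bio,
      cbow = cbow, embedding = emb, fused = fused, graph = graph)
}

.zscoreCols <- function(m) {
  if (!nrow(m)) return(m)
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  keep <- is.finite(sd) & sd > 1e-12
  m[, keep] <- sweep(sweep(m[, keep, drop = FALSE], 2L, mu[keep], "-"),
                     2L, sd[keep], "/")
  m
}
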