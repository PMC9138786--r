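#' Generate a synthetic planted-community world
#'
#' Builds a fully synthetic dataset in the pipeline's three input formats,
#' with a planted community structure that every feature channel can partly
#' recover:
#' \itemize{
#'   \item interactions: each unordered drug pair is an edge independently
#'     with probability \code{pIn} (same community) or \code{pOut}
#'     (different communities);
#'   \item biological function: each function type's receptor set is split
#'     into one block per community; a drug is associated with an in-block
#'     receptor with probability 0.8 and with an off-block receptor with
#'     probability 0.05;
#'   \item chemistry: SMILES-like strings over a 20-symbol alphabet whose
#'     symbol frequencies are biased per community (each community favours
#'     its own symbol subset).
#' }
#' With \code{pIn == pOut} the world carries no interaction signal (the null
#' world). Everything is reproducible from the master seed; with a fixed
#' seed [writeWorld()] emits byte-identical files.
#'
#' @param nDrugs number of drugs, default 200.
#' @param nCommunities number of planted communities, default 4.
#' @param pIn within-community interaction probability, default 0.2.
#' @param pOut between-community interaction probability, default 0.02.
#' @param nTypes number of receptor function types, default 3.
#' @param receptorsPerType receptors per function type, default 50.
#' @param seed master seed.
#' @param tokenRange min/max token count of the SMILES-like strings.
#' @return a [PlantedWorld-class].
#' @export
genWorld <- function(nDrugs = 200L, nCommunities = 4L, pIn = 0.2, pOut = 0.02,
                     nTypes = 3L, receptorsPerType = 50L, seed = 1L,
                     tokenRange = c(16L, 48L)) {
  if (!(pOut >= 0 && pOut <= pIn && pIn <= 1))
    stop("need 0 <= pOut <= pIn <= 1")
  stopifnot(nDrugs >= 2L, nCommunities >= 1L)
  set.seed(seed)
  ids <- sprintf("D%04d", seq_len(nDrugs))
  comm <- stats::setNames(rep(seq_len(nCommunities), length.out = nDrugs), ids)
  # deterministic round-robin assignment keeps communities balanced; the
  # random stream is reserved for the stochastic parts below

  # --- SMILES-like strings (community-biased symbol frequencies) ----------
  alphabet <- c("C", "N", "O", "S", "P", "F", "I", "c", "n", "o", "s",
                "(", ")", "=", "#", "1", "2", "Cl", "Br", "[H]")
  ownSets <- split(seq_along(alphabet),
                   rep(seq_len(nCommunities), length.out = length(alphabet)))
  lens <- sample(tokenRange[1L]:tokenRange[2L], nDrugs, replace = TRUE)
  smiles <- character(nDrugs)
  for (i in seq_len(nDrugs)) {
    wgt <- rep(1, length(alphabet))
    wgt[ownSets[[((comm[i] - 1L) %% length(ownSets)) + 1L]]] <- 3
    smiles[i] <- paste(sample(alphabet, lens[i], replace = TRUE,
                              prob = wgt / sum(wgt)), collapse = "")
  }
  drugs <- data.frame(drug_id = ids, smiles = smiles, stringsAsFactors = FALSE)

  # --- interaction edges (planted stochastic block model) -----------------
  idx <- utils::combn(nDrugs, 2L)
  same <- comm[idx[1L, ]] == comm[idx[2L, ]]
  p <- ifelse(same, pIn, pOut)
  hit <- stats::runif(ncol(idx)) < p
  edges <- data.frame(drug_id_a = ids[idx[1L, hit]],
                      drug_id_b = ids[idx[2L, hit]],
                      stringsAsFactors = FALSE)

  # --- block-structured receptor associations -----------------------------
  assoc <- list()
  for (t in seq_len(nTypes)) {
    rty <- sprintf("T%d", t)
    receptors <- sprintf("%s_R%03d", rty, seq_len(receptorsPerType))
    block <- rep(seq_len(nCommunities), length.out = receptorsPerType)
    pm <- ifelse(outer(unname(comm), block, "=="), 0.8, 0.05)
    hits <- matrix(stats::runif(nDrugs * receptorsPerType) < pm,
                   nDrugs, receptorsPerType)
    wh <- which(hits, arr.ind = TRUE)
    assoc[[t]] <- data.frame(drug_id = ids[wh[, 1L]],
                             receptor_id = receptors[wh[, 2L]],
                             function_type = rty,
                             stringsAsFactors = FALSE)
  }
  associations <- do.call(rbind, assoc)
  ord <- order(associations$function_type, associations$drug_id,
               associations$receptor_id)
  associations <- associations[ord, , drop = FALSE]
  rownames(associations) <- NULL

  new("PlantedWorld",
      drugs = drugs, edges = edges, associations = associations,
      community = comm,
      params = list(nDrugs = nDrugs, nCommunities = nCommunities,
                    pIn = pIn, pOut = pOut, nTypes = nTypes,
                    receptorsPerType = receptorsPerType, seed = seed,
                    tokenRange = tokenRange))
}

#' Permute the labels of a sample table
#'
#' Shuffles the label column over the pairs, preserving the class balance:
#' the permutation-null control in which any association between pairs and
#' labels is destroyed. Reproducible per seed.
#'
#' @param samples data.frame with a \code{label} column
#'   (see [balancedSamples()]).
#' @param seed integer seed.
#' @return the same data.frame with permuted labels.
#' @export
permuteLabels <- function(samples, seed = 1L) {
  stopifnot("label" %in% names(samples))
  set.seed(seed)
  samples$label <- samples$label[sample.int(nrow(samples))]
  samples
}

#' Write a world to disk in the pipeline's input formats
#'
#' Emits \code{drugs.tsv} (drug_id, smiles), \code{edges.tsv}
#' (drug_id_a, drug_id_b) and \code{associations.tsv}
#' (drug_id, receptor_id, function_type), plus \code{world.json} with the
#' generator parameters and community assignment. Byte-identical for a fixed
#' seed.
#'
#' @param world a [PlantedWorld-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeWorld <- function(world, dir) {
  stopifnot(is(world, "PlantedWorld"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("drugs.tsv", "edges.tsv", "associations.tsv",
                            "world.json"))
  .writeTsv(world@drugs, paths[1L])
  .writeTsv(world@edges, paths[2L])
  .writeTsv(world@associations, paths[3L])
  jsonlite::write_json(
    list(params = world@params,
         community = as.list(world@community)),
    paths[4L], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
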