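#' Run the full evaluation protocol on one dataset
#'
#' End-to-end experiment: known interactions become positive samples, an
#' equal number of negatives is drawn, and the balanced set is evaluated
#' under the configured protocol:
#' \describe{
#'   \item{split_70_20_10}{one random 70/20/10 train/test/validation split;
#'     the training-fold positives build the interaction graph, the model
#'     trains on the train portion with early stopping on the validation
#'     portion, and metrics are reported on the held-out test portion.}
#'   \item{cv5}{k-fold cross-validation (default k = 5): per fold, the
#'     graph is rebuilt from that fold's training positives only (test
#'     edges are never seen), the model trains with an inner validation
#'     split, and per-fold metrics are summarized as mean and sd.}
#' }
#'
#' @param drugs data.frame(drug_id, smiles).
#' @param edges two-column data.frame of known interacting pairs.
#' @param associations data.frame(drug_id, receptor_id, function_type).
#' @param config list from [ddiConfig()].
#' @param seed integer master seed for sampling, splitting and training.
#' @param samples optional pre-built labelled sample table (e.g. a permuted
#'   null set); when given, negative sampling is skipped.
#' @return for split_70_20_10: list with elements \code{metrics} (named
#'   vector), \code{model}, \code{samples}, \code{assignment};
#'   for cv5: list with \code{report} (a [MetricsReport-class]),
#'   \code{samples}, \code{folds} and \code{foldGraphEdges} (the pair keys
#'   of each fold's training graph, for leakage auditing).
#' @export
runExperiment <- function(drugs, edges, associations,
                          config = ddiConfig(), seed = 1L, samples = NULL) {
  drugs <- as.data.frame(drugs)
  edges <- as.data.frame(edges)
  if (is.null(samples)) {
    positives <- .canonicalPairs(edges)
    samples <- balancedSamples(positives, drugs$drug_id, seed = seed)
  }
  if (config$protocol == "split_70_20_10") {
    assignment <- splitAssign(nrow(samples), seed = seed + 2L)
    trainPos <- samples[assignment == "train" & samples$label == 1L,
                        c("drug_id_a", "drug_id_b")]
    features <- buildFeatureSet(drugs, trainPos, associations,
                                config = config, seed = seed + 3L)
    model <- trainDdiModel(features,
                           trainSamples = samples[assignment == "train", ],
                           valSamples = samples[assignment == "val", ],
                           config = config, seed = seed + 4L)
    test <- samples[assignment == "test", ]
    scores <- predictScores(model, test[, c("drug_id_a", "drug_id_b")])
    metrics <- computeMetrics(test$label, as.numeric(scores),
                              threshold = config$threshold)
    list(metrics = metrics, model = model, samples = samples,
         assignment = assignment)
  } else if (config$protocol == "cv5") {
    folds <- foldAssign(nrow(samples), k = config$k, seed = seed + 2L)
    perFold <- NULL
    foldGraphs <- vector("list", config$k)
    for (f in seq_len(config$k)) {
      trainS <- samples[folds != f, , drop = FALSE]
      testS <- samples[folds == f, , drop = FALSE]
      if (length(unique(testS$label)) < 2L || length(unique(trainS$label)) < 2L)
        stop("fold ", f, " has a single class; use more samples or fewer folds")
      trainPos <- trainS[trainS$label == 1L, c("drug_id_a", "drug_id_b")]
      features <- buildFeatureSet(drugs, trainPos, associations,
                                  config = config, seed = seed + 3L + f)
      model <- trainDdiModel(features, trainSamples = trainS,
                             valSamples = NULL, config = config,
                             seed = seed + 40L + f)
      scores <- predictScores(model, testS[, c("drug_id_a", "drug_id_b")])
      m <- computeMetrics(testS$label, as.numeric(scores),
                          threshold = config$threshold)
      perFold <- rbind(perFold, data.frame(fold = f, t(m)))
      ed <- graphEdges(model@features@graph)
      foldGraphs[[f]] <- pairKey(ed$from, ed$to)
    }
    list(report = metricsReport(perFold), samples = samples, folds = folds,
         foldGraphEdges = foldGraphs)
  } else {
    stop("unknown protocol: ", config$protocol)
  }
}

# unordered dedup of an edge table
.canonicalPairs <- function(edges) {
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "|"))
  data.frame(drug_id_a = lo[!dup], drug_id_b = hi[!dup],
             stringsAsFactors = FALSE)
}

#' Channel and attention ablation study
#'
#' Trains the classifier under several ablation configurations on identical
#' data, split and seeds: the full model, each channel zeroed in turn
#' (\code{noChem}, \code{noNet}, \code{noBio}), and attention replaced by
#' plain concatenation (\code{noAttention}). The balanced sample set, the
#' 70/20/10 split and the precomputed feature channels are shared across
#' configurations, so differences reflect only the ablated component.
#'
#' @param drugs,edges,associations dataset tables, see [runExperiment()].
#' @param config base configuration; the ablation toggles are overridden
#'   per run.
#' @param seed integer master seed (shared across configurations).
#' @return data.frame with one row per configuration and the test-fold
#'   metrics.
#' @export
ablationStudy <- function(drugs, edges, associations,
                          config = ddiConfig(), seed = 1L) {
  positives <- .canonicalPairs(as.data.frame(edges))
  samples <- balancedSamples(positives, as.data.frame(drugs)$drug_id,
                             seed = seed)
  assignment <- splitAssign(nrow(samples), seed = seed + 2L)
  trainPos <- samples[assignment == "train" & samples$label == 1L,
                      c("drug_id_a", "drug_id_b")]
  features <- buildFeatureSet(drugs, trainPos, associations,
                              config = config, seed = seed + 3L)
  test <- samples[assignment == "test", ]
  setups <- list(
    full = list(),
    noChem = list(useChem = FALSE),
    noNet = list(useNet = FALSE),
    noBio = list(useBio = FALSE),
    noAttention = list(useAttention = FALSE)
  )
  out <- NULL
  for (nm in names(setups)) {
    cfg <- config
    cfg[names(setups[[nm]])] <- setups[[nm]]
    model <- trainDdiModel(features,
                           trainSamples = samples[assignment == "train", ],
                           valSamples = samples[assignment == "val", ],
                           config = cfg, seed = seed + 4L)
    p <- predictScores(model, test[, c("drug_id_a", "drug_id_b")])
    m <- computeMetrics(test$label, as.numeric(p),
                        threshold = cfg$threshold)
    out <- rbind(out, data.frame(config = nm, t(m)))
  }
  out
}

#' Rank candidate interaction partners for one drug
#'
#' Scores the query drug against every other drug in the model's universe
#' except the excluded partners (typically its known interactions, matching
#' the case-study protocol where the query's true pairs are withheld from
#' training and then recovered by rank). Results are sorted by descending
#' score.
#'
#' @param model a [DDIModel-class].
#' @param queryDrug drug id present in the model's feature set.
#' @param exclude character vector of partner ids to omit (e.g. known
#'   interactions of the query).
#' @return data.frame(rank, drug_id, score), sorted by score.
#' @export
rankCandidates <- function(model, queryDrug, exclude = character(0)) {
  ids <- model@features@drugIds
  if (!queryDrug %in% ids) stop("unknown query drug: ", queryDrug)
  partners <- setdiff(ids, c(queryDrug, exclude))
  if (!length(partners)) stop("no candidate partners left after exclusion")
  pairs <- data.frame(drug_id_a = queryDrug, drug_id_b = partners)
  p <- as.numeric(predictScores(model, pairs))
  ord <- order(-p, partners)
  data.frame(rank = seq_along(partners), drug_id = partners[ord],
             score = p[ord], stringsAsFactors = FALSE)
}
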