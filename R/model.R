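#' Train the attention-fusion DDI classifier
#'
#' Jointly optimizes the channel reducers, the attention block and the
#' classifier head with Adam against binary cross-entropy. Each labelled
#' unordered pair enters training in both orderings, so the learned scorer
#' is approximately symmetric before the symmetrized inference of
#' [predictScores()] makes it exact. The channel inputs (CBOW table, node
#' embedding, fused similarity) are precomputed in \code{features} and held
#' fixed. After every epoch the validation loss is evaluated; training stops
#' early once it has not improved for \code{config$patience} epochs, and the
#' best-validation weights are restored. Deterministic per seed in
#' single-threaded mode.
#'
#' @param features a [DrugFeatureSet-class] built on the training-fold graph.
#' @param trainSamples data.frame(drug_id_a, drug_id_b, label).
#' @param valSamples optional validation samples in the same format; when
#'   NULL, \code{config$valFraction} of \code{trainSamples} is split off.
#' @param config list from [ddiConfig()].
#' @param seed integer seed (weight init, shuffling, dropout).
#' @return a [DDIModel-class].
#' @export
trainDdiModel <- function(features, trainSamples, valSamples = NULL,
                          config = ddiConfig(), seed = 1L) {
  stopifnot(is(features, "DrugFeatureSet"))
  trainSamples <- as.data.frame(trainSamples)
  if (!all(c(0L, 1L) %in% trainSamples$label))
    stop("training samples must contain both classes")
  if (is.null(valSamples)) {
    set.seed(seed + 7L)
    nVal <- max(1L, round(nrow(trainSamples) * config$valFraction))
    vi <- sample.int(nrow(trainSamples), nVal)
    valSamples <- trainSamples[vi, , drop = FALSE]
    trainSamples <- trainSamples[-vi, , drop = FALSE]
  }
  ids <- features@drugIds

  # both orderings of every pair
  expand <- function(s) {
    data.frame(
      a = match(c(s$drug_id_a, s$drug_id_b), ids),
      b = match(c(s$drug_id_b, s$drug_id_a), ids),
      y = rep(s$label, 2L)
    )
  }
  tr <- expand(trainSamples)
  va <- expand(valSamples)
  if (anyNA(tr$a) || anyNA(tr$b) || anyNA(va$a) || anyNA(va$b))
    stop("samples reference drugs absent from the feature set")

  nBio <- ncol(features@bio)
  w <- .initFusionWeights(config, nBio, seed)
  state <- .adamInit(w)

  nTr <- nrow(tr)
  nBatch <- ceiling(nTr / config$batchSize)
  bestLoss <- Inf
  bestW <- w
  history <- data.frame(epoch = integer(0), train = numeric(0),
                        val = numeric(0))
  wait <- 0L
  set.seed(seed)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(nTr)
    epLoss <- 0
    for (bi in seq_len(nBatch)) {
      rows <- ord[((bi - 1L) * config$batchSize + 1L):min(bi * config$batchSize, nTr)]
      a <- tr$a[rows]; b <- tr$b[rows]; y <- tr$y[rows]
      uIdx <- sort(unique(c(a, b)))
      fw <- .fusionForward(w, features, uIdx, config)
      pa <- match(a, uIdx); pb <- match(b, uIdx)
      Z <- cbind(fw$fused[pa, , drop = FALSE], fw$fused[pb, , drop = FALSE])
      hf <- .headForward(w, Z, config, dropout = TRUE)
      B <- length(y)
      epLoss <- epLoss + .bceLoss(hf$p, y) * B
      dLogit <- matrix((hf$p - y) / B, ncol = 1L)
      grads <- .headBackward(w, hf, dLogit, list())
      dZ <- grads$dZ
      grads$dZ <- NULL
      occ <- c(pa, pb)
      dFused <- rowsum(rbind(dZ[, 1:192, drop = FALSE],
                             dZ[, 193:384, drop = FALSE]), occ)
      # rowsum orders groups 1..m; every uIdx position occurs by construction
      grads <- .fusionBackward(w, features, fw, dFused, config, grads)
      upd <- .adamStep(w, grads, state, config$adamLr)
      w <- upd$w; state <- upd$state
    }
    valLoss <- .modelLoss(w, features, va, config)
    history <- rbind(history,
                     data.frame(epoch = ep, train = epLoss / nTr,
                                val = valLoss))
    if (valLoss < bestLoss - 1e-6) {
      bestLoss <- valLoss
      bestW <- w
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  new("DDIModel", weights = bestW, config = config, features = features,
      history = history)
}

# mean BCE of (a, b, y) index triples under fixed weights, no dropout
.modelLoss <- function(w, features, s, config) {
  uIdx <- sort(unique(c(s$a, s$b)))
  fw <- .fusionForward(w, features, uIdx, config)
  Z <- cbind(fw$fused[match(s$a, uIdx), , drop = FALSE],
             fw$fused[match(s$b, uIdx), , drop = FALSE])
  hf <- .headForward(w, Z, config, dropout = FALSE)
  .bceLoss(hf$p, s$y)
}

#' Predict interaction probabilities for drug pairs
#'
#' Scores each pair in input order as the mean of the model's score for the
#' two orderings, so reversed pairs receive identical probabilities. Drugs
#' absent from the model's feature set are scored with zero channel vectors
#' and flagged in the \code{"ghost"} attribute.
#'
#' @param model a [DDIModel-class].
#' @param pairs data.frame or matrix whose first two columns are drug ids.
#' @return numeric vector of probabilities in (0, 1), one per pair, with
#'   attribute \code{"ghost"} marking pairs containing unknown drugs.
#' @export
predictScores <- function(model, pairs) {
  pairs <- as.data.frame(pairs)
  a <- as.character(pairs[[1L]])
  b <- as.character(pairs[[2L]])
  feat <- model@features
  ids <- feat@drugIds
  known <- c(ids, NA_character_)
  ia <- match(a, ids); ib <- match(b, ids)
  ghostPair <- is.na(ia) | is.na(ib)
  if (any(ghostPair))
    warning(sum(ghostPair), " pair(s) involve drugs absent from every ",
            "channel; scored with zero feature bundles")
  # unknown drugs map to index 0: an all-zero feature bundle
  ia[is.na(ia)] <- 0L
  ib[is.na(ib)] <- 0L

  scoreOrder <- function(x, y) {
    uIdx <- sort(unique(c(x, y)))
    uIdx <- uIdx[uIdx > 0L]
    fused <- if (length(uIdx))
      .fusionForward(model@weights, feat, uIdx, model@config)$fused
    else matrix(0, 0L, 192L)
    getRows <- function(ix) {
      out <- matrix(0, length(ix), 192L)
      hit <- ix > 0L
      out[hit, ] <- fused[match(ix[hit], uIdx), , drop = FALSE]
      out
    }
    Z <- cbind(getRows(x), getRows(y))
    hf <- .headForward(model@weights, Z, model@config, dropout = FALSE)
    hf$p
  }
  p <- (scoreOrder(ia, ib) + scoreOrder(ib, ia)) / 2
  attr(p, "ghost") <- ghostPair
  p
}
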