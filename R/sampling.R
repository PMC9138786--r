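#' Canonical unordered-pair keys
#'
#' @param a,b character vectors of drug ids.
#' @return character vector: the pair in sorted order joined by "|", so
#'   (a, b) and (b, a) share a key.
#' @export
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Balanced negative sampling
#'
#' Draws unordered drug pairs uniformly without replacement from the
#' complement of the positive set (excluding self-pairs), one negative per
#' positive by default, so the resulting sample set is class balanced.
#' Reproducible per seed.
#'
#' @param positives two-column data.frame/matrix of positive pairs.
#' @param drugs character vector, the drug universe.
#' @param seed integer seed.
#' @param n number of negatives, default \code{nrow(positives)}.
#' @return data.frame(drug_id_a, drug_id_b) of negative pairs, disjoint from
#'   the positives.
#' @export
sampleNegatives <- function(positives, drugs, seed = 1L, n = NULL) {
  positives <- as.data.frame(positives)
  drugs <- sort(as.character(drugs))
  if (is.null(n)) n <- nrow(positives)
  posKey <- unique(pairKey(as.character(positives[[1L]]),
                           as.character(positives[[2L]])))
  idx <- utils::combn(length(drugs), 2L)
  allKey <- pairKey(drugs[idx[1L, ]], drugs[idx[2L, ]])
  candidates <- which(!(allKey %in% posKey))
  if (length(candidates) < n)
    stop("not enough non-interacting pairs: need ", n, ", have ",
         length(candidates), " (deficit ", n - length(candidates), ")")
  set.seed(seed)
  pick <- sample(candidates, n)
  data.frame(drug_id_a = drugs[idx[1L, pick]],
             drug_id_b = drugs[idx[2L, pick]],
             stringsAsFactors = FALSE)
}

#' Build the balanced labelled sample table
#'
#' Positives (label 1) plus an equal number of sampled negatives (label 0),
#' shuffled. This is the fixed sample set that the split or the folds then
#' partition.
#'
#' @param positives two-column data.frame of known interacting pairs.
#' @param drugs drug universe.
#' @param seed integer seed (negative sampling and shuffling).
#' @return data.frame(drug_id_a, drug_id_b, label).
#' @export
balancedSamples <- function(positives, drugs, seed = 1L) {
  positives <- as.data.frame(positives)
  neg <- sampleNegatives(positives, drugs, seed = seed)
  samples <- data.frame(
    drug_id_a = c(as.character(positives[[1L]]), neg$drug_id_a),
    drug_id_b = c(as.character(positives[[2L]]), neg$drug_id_b),
    label = rep(c(1L, 0L), c(nrow(positives), nrow(neg))),
    stringsAsFactors = FALSE
  )
  set.seed(seed + 1L)
  samples[sample.int(nrow(samples)), , drop = FALSE]
}

#' Train/test/validation split assignment
#'
#' Random partition of n samples into train/test/validation at the given
#' fractions (default 70/20/10).
#'
#' @param n number of samples.
#' @param fractions named numeric vector summing to 1.
#' @param seed integer seed.
#' @return character vector of length n with values
#'   \code{"train"}, \code{"test"}, \code{"val"}.
#' @export
splitAssign <- function(n, fractions = c(train = 0.7, test = 0.2, val = 0.1),
                        seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  set.seed(seed)
  ord <- sample.int(n)
  nTrain <- round(n * fractions[["train"]])
  nTest <- round(n * fractions[["test"]])
  out <- character(n)
  out[ord[seq_len(nTrain)]] <- "train"
  out[ord[nTrain + seq_len(min(nTest, n - nTrain))]] <- "test"
  out[out == ""] <- "val"
  out
}

#' k-fold assignment
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k) partitioning the samples into
#'   folds of near-equal size.
#' @export
foldAssign <- function(n, k = 5L, seed = 1L) {
  stopifnot(k >= 2L, n >= k)
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}
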