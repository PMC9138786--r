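#' Train CBOW token embeddings on a SMILES corpus
#'
#' Learns a d-dimensional vector per token with the continuous bag-of-words
#' model: the hidden vector is the arithmetic average of the context tokens'
#' input embeddings, and the center token is predicted through a full softmax
#' over the vocabulary. Training minimizes the negative log-probability of
#' the observed center token by mini-batch gradient descent with a linearly
#' decaying step size. SMILES alphabets are tiny (tens of symbols), so the
#' full softmax is exact and cheap; no sampling approximation is involved.
#'
#' Deterministic for a fixed (corpus, seed, epochs) in single-threaded mode.
#'
#' @param corpus list of token vectors (see [tokenizeCorpus()]).
#' @param dim embedding dimension, default 64.
#' @param window context half-window: tokens up to \code{window} positions
#'   either side of the center are context.
#' @param minCount minimum corpus count for a token to be retained, default 1.
#' @param epochs full passes over the corpus.
#' @param lr initial learning rate, decayed linearly to 1e-4 of its value.
#' @param batchSize mini-batch size (number of center-token examples).
#' @param seed integer seed.
#' @return a [TokenEmbeddingTable-class].
#' @export
trainCbow <- function(corpus, dim = 64L, window = 5L, minCount = 1L,
                      epochs = 15L, lr = 0.1, batchSize = 512L, seed = 1L) {
  stopifnot(length(corpus) > 0, dim >= 1)
  toks <- unlist(corpus, use.names = FALSE)
  counts <- table(toks)
  vocab <- sort(names(counts)[counts >= minCount])
  if (length(vocab) == 0L) stop("no tokens retained at minCount = ", minCount)
  V <- length(vocab)

  # (center, context-list) examples; out-of-vocabulary tokens are dropped
  # from the sentence before windowing, as in standard word2vec pipelines
  ex <- .cbowExamples(corpus, vocab, window)
  if (length(ex$center) == 0L)
    stop("corpus yields no context windows (all sentences length <= 1?)")
  nEx <- length(ex$center)
  # sparse context-average operator: row t spreads weight 1/|context_t|
  Cmat <- Matrix::sparseMatrix(
    i = ex$row, j = ex$ctx, x = ex$w, dims = c(nEx, V)
  )

  set.seed(seed)
  Win <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, V, dim)
  Wout <- matrix(0, V, dim)

  nBatch <- ceiling(nEx / batchSize)
  totalSteps <- epochs * nBatch
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nEx)
    for (b in seq_len(nBatch)) {
      idx <- ord[((b - 1L) * batchSize + 1L):min(b * batchSize, nEx)]
      rate <- max(lr * (1 - step / totalSteps), lr * 1e-4)
      step <- step + 1L
      Cb <- Cmat[idx, , drop = FALSE]
      H <- as.matrix(Cb %*% Win)                    # B x d hidden (Eq. 1)
      S <- tcrossprod(H, Wout)                      # B x V scores
      P <- .softmaxRows(S)
      B <- length(idx)
      P[cbind(seq_len(B), ex$center[idx])] <-
        P[cbind(seq_len(B), ex$center[idx])] - 1
      dS <- P / B
      dWout <- crossprod(dS, H)
      dH <- dS %*% Wout
      dWin <- as.matrix(Matrix::crossprod(Cb, dH))
      Wout <- Wout - rate * dWout
      Win <- Win - rate * dWin
    }
  }
  rownames(Win) <- rownames(Wout) <- vocab
  new("TokenEmbeddingTable",
      vocab = vocab, inputWeights = Win, outputWeights = Wout,
      window = as.integer(window),
      counts = stats::setNames(as.integer(counts[vocab]), vocab))
}

# enumerate (center, context) windows over a corpus, vocabulary-filtered
.cbowExamples <- function(corpus, vocab, window) {
  centerL <- list(); ctxL <- list(); lenL <- list()
  for (sent in corpus) {
    s <- match(sent, vocab)
    s <- s[!is.na(s)]
    L <- length(s)
    if (L < 2L) next
    lo <- pmax(1L, seq_len(L) - window)
    hi <- pmin(L, seq_len(L) + window)
    ctx <- lapply(seq_len(L), function(t) s[setdiff(lo[t]:hi[t], t)])
    keep <- lengths(ctx) > 0L
    centerL[[length(centerL) + 1L]] <- s[keep]
    ctxL[[length(ctxL) + 1L]] <- unlist(ctx[keep], use.names = FALSE)
    lenL[[length(lenL) + 1L]] <- lengths(ctx)[keep]
  }
  centers <- unlist(centerL, use.names = FALSE)
  lens <- unlist(lenL, use.names = FALSE)
  list(center = as.integer(centers),
       row = rep.int(seq_along(centers), lens),
       ctx = as.integer(unlist(ctxL, use.names = FALSE)),
       w = rep.int(1 / lens, lens))
}

.softmaxRows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Predicted center-token distribution given a context
#'
#' Evaluates the CBOW softmax: the probability of each vocabulary token being
#' the center token, given the average of the context tokens' embeddings.
#' Probabilities sum to 1 over the vocabulary.
#'
#' @param table a trained [TokenEmbeddingTable-class].
#' @param context character vector of context tokens (unknown tokens are
#'   ignored; at least one must be known).
#' @return named numeric vector of probabilities over the vocabulary.
#' @export
cbowProbability <- function(table, context) {
  idx <- match(context, table@vocab)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("no context token is in the vocabulary")
  h <- colMeans(table@inputWeights[idx, , drop = FALSE])
  s <- drop(table@outputWeights %*% h)
  s <- s - max(s)
  p <- exp(s) / sum(exp(s))
  stats::setNames(p, table@vocab)
}

#' Mean CBOW objective over a corpus
#'
#' Mean negative log-probability of the observed center tokens under the
#' model's full softmax; the quantity minimized by [trainCbow()].
#'
#' @param table a [TokenEmbeddingTable-class].
#' @param corpus list of token vectors.
#' @return mean loss (scalar).
#' @export
cbowObjective <- function(table, corpus) {
  ex <- .cbowExamples(corpus, table@vocab, table@window)
  if (!length(ex$center)) stop("corpus yields no context windows")
  nEx <- length(ex$center)
  Cmat <- Matrix::sparseMatrix(i = ex$row, j = ex$ctx, x = ex$w,
                               dims = c(nEx, length(table@vocab)))
  H <- as.matrix(Cmat %*% table@inputWeights)
  S <- tcrossprod(H, table@outputWeights)
  S <- S - apply(S, 1L, max)
  logZ <- log(rowSums(exp(S)))
  mean(logZ - S[cbind(seq_len(nEx), ex$center)])
}

#' Build the fixed-size drug matrix from a token sequence
#'
#' Stacks the embedding vectors of the drug's tokens into an
#' \code{lMax x d} matrix: row t is the t-th token's vector. Sequences
#' shorter than \code{lMax} are zero-padded below; longer sequences are
#' truncated to the first \code{lMax} tokens. Tokens absent from the
#' vocabulary map to a zero row.
#'
#' @param tokens character vector of tokens for one drug.
#' @param table a trained [TokenEmbeddingTable-class].
#' @param lMax number of rows of the output matrix, default 64.
#' @param verbose report unknown tokens via [message()].
#' @return numeric \code{lMax x d} matrix.
#' @export
buildDrugMatrix <- function(tokens, table, lMax = 64L, verbose = FALSE) {
  d <- ncol(table@inputWeights)
  out <- matrix(0, lMax, d)
  use <- tokens[seq_len(min(length(tokens), lMax))]
  idx <- match(use, table@vocab)
  if (verbose && anyNA(idx))
    message("unknown tokens mapped to zero rows: ",
            paste(unique(use[is.na(idx)]), collapse = ", "))
  known <- which(!is.na(idx))
  if (length(known))
    out[known, ] <- table@inputWeights[idx[known], , drop = FALSE]
  out
}
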