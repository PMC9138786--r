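#' @useDynLib DDIfuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Patch (im2col) extraction for one drug sequence matrix. Only rows whose
# 3x3 receptive field can touch a nonzero row of M are materialized; the
# remaining positions have an all-zero field and are counted in nzero (the
# reducer adds their relu(bias) contribution analytically). For the usual
# prefix-occupied matrices (tokens then zero padding) this is exact and
# skips most of the grid.
.drugPatches <- function(M, size = 3L) {
  lMax <- nrow(M)
  d <- ncol(M)
  half <- (size - 1L) %/% 2L
  nz <- which(rowSums(abs(M)) > 0)
  if (!length(nz))
    return(list(X = matrix(0, 0L, size * size), nzero = lMax * d))
  active <- max(1L, min(nz) - half):min(lMax, max(nz) + half)
  pad <- matrix(0, lMax + 2L * half, d + 2L * half)
  pad[half + seq_len(lMax), half + seq_len(d)] <- M
  cols <- matrix(0, length(active) * d, size * size)
  k <- 0L
  for (dr in -half:half) {
    for (dc in -half:half) {
      k <- k + 1L
      cols[, k] <- as.vector(pad[half + active + dr, half + seq_len(d) + dc])
    }
  }
  list(X = cols, nzero = (lMax - length(active)) * d)
}

#' Convolutional reduction of a drug sequence matrix
#'
#' Applies one 2-D convolution layer (\code{kernels} filters of size
#' \code{size x size}, stride 1, zero padding) to the \code{lMax x d} drug
#' matrix treated as a one-channel image, a nonlinearity, then global
#' average pooling over both spatial axes, yielding one value per kernel.
#'
#' @param m numeric drug sequence matrix (from [buildDrugMatrix()]).
#' @param W kernel weight matrix (\code{size^2 x kernels}); columns are
#'   flattened kernels (row-offset major).
#' @param b bias vector, one per kernel.
#' @param activation \code{"relu"} (default) or \code{"linear"}.
#' @return numeric vector of length \code{ncol(W)}.
#' @export
cnnReduce <- function(m, W, b = numeric(ncol(W)),
                      activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  size <- as.integer(sqrt(nrow(W)))
  if (size * size != nrow(W)) stop("nrow(W) must be a square kernel size")
  if (nrow(m) != ncol(m)) stop("drug matrix must be square (lMax x d)")
  p <- .drugPatches(m, size)
  totalPos <- nrow(m) * ncol(m)
  act <- if (activation == "relu") function(x) pmax(x, 0) else identity
  pooled <- if (nrow(p$X)) {
    A <- act(sweep(p$X %*% W, 2L, b, "+"))
    colSums(A)
  } else numeric(ncol(W))
  (pooled + p$nzero * act(b)) / totalPos
}

#' Random attention block
#'
#' Creates the three learned projection matrices of a scaled dot-product
#' attention block with Glorot-uniform initialization.
#'
#' @param dim token dimension (and projection size), default 64.
#' @param dk normalization coefficient; attention logits are divided by
#'   \code{sqrt(dk)}. Default \code{dim}.
#' @param seed integer seed.
#' @return list with elements \code{Wq}, \code{Wk}, \code{Wv}, \code{dk}.
#' @export
newAttentionBlock <- function(dim = 64L, dk = dim, seed = 1L) {
  set.seed(seed)
  lim <- sqrt(6 / (dim + dim))
  rand <- function() matrix(stats::runif(dim * dim, -lim, lim), dim, dim)
  list(Wq = rand(), Wk = rand(), Wv = rand(), dk = dk)
}

#' Fuse feature tokens with scaled dot-product attention
#'
#' Treats the rows of \code{tokens} as a short sequence (the three channel
#' vectors of one drug), projects them to queries, keys and values, and
#' returns the attention-enhanced tokens
#' \deqn{\tilde\theta = \mathrm{softmax}(QK^\top/\sqrt{d_k})\,V}
#' concatenated into a single vector. Attention-weight rows sum to 1.
#'
#' @param tokens numeric matrix (nTokens x dim); typically 3 x 64.
#' @param block attention block, see [newAttentionBlock()].
#' @return numeric vector of length \code{nTokens * dim}, with the
#'   attention-weight matrix attached as attribute \code{"weights"}.
#' @export
attentionFuse <- function(tokens, block) {
  tokens <- rbind(tokens)
  Q <- tokens %*% block$Wq
  K <- tokens %*% block$Wk
  V <- tokens %*% block$Wv
  S <- tcrossprod(Q, K) / sqrt(block$dk)
  A <- .softmaxRows(S)
  out <- as.vector(t(A %*% V))
  attr(out, "weights") <- A
  out
}
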