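#' Scaled-exponential affinity kernel
#'
#' Converts a distance matrix into a nonnegative affinity matrix with the
#' locally scaled Gaussian kernel used by similarity network fusion:
#' \deqn{W_{ij} = \exp(-D_{ij}^2 / (\mu\,\varepsilon_{ij})),\quad
#'   \varepsilon_{ij} = (\bar d_i + \bar d_j + D_{ij}) / 3}
#' where \eqn{\bar d_i} is the mean distance from i to its K nearest
#' neighbours. The local scale makes the affinity insensitive to the overall
#' scale of the distances.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param K neighbourhood size for the local scale.
#' @param mu bandwidth multiplier (typically 0.3-0.8).
#' @return symmetric affinity matrix, unit diagonal.
#' @export
affinityKernel <- function(D, K = 20L, mu = 0.5) {
  n <- nrow(D)
  stopifnot(ncol(D) == n, n >= 2)
  K <- min(K, n - 1L)
  # mean distance to the K nearest neighbours (self excluded)
  dbar <- vapply(seq_len(n), function(i) {
    mean(sort(D[i, -i])[seq_len(K)])
  }, numeric(1))
  eps <- (outer(dbar, dbar, "+") + D) / 3
  eps <- pmax(eps, .Machine$double.eps)
  W <- exp(-D^2 / (mu * eps))
  (W + t(W)) / 2
}

# row-stochastic renormalization: off-diagonal mass 1/2, diagonal 1/2
.snfNormalize <- function(W) {
  n <- nrow(W)
  off <- W
  diag(off) <- 0
  rs <- rowSums(off)
  rs[rs == 0] <- 1
  P <- off / (2 * rs)
  diag(P) <- 0.5
  P
}

# K-nearest-neighbour sparse kernel, row-normalized over the neighbourhood
.snfLocalKernel <- function(W, D, K) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    ord <- ord[ord != i][seq_len(K)]
    S[i, ord] <- W[i, ord] / sum(W[i, ord])
  }
  S
}

#' Fuse similarity views by similarity network fusion
#'
#' Integrates M per-function-type views into one N x N similarity matrix by
#' cross-diffusion. Each view's distances become affinities with
#' [affinityKernel()]; each view keeps a full row-stochastic kernel P and a
#' K-nearest-neighbour sparse kernel S; then for T rounds every view diffuses
#' the average of the other views' full kernels through its own local
#' geometry, \eqn{P_v \leftarrow S_v \,\mathrm{mean}(P_{u \ne v})\, S_v^\top},
#' followed by row renormalization. The fused output is the symmetrized mean
#' of the final kernels. With a single view the diffusion runs against the
#' view itself, so fusing M identical views equals the single-view result.
#'
#' @param views a [ReceptorProfileSet-class] (distances computed per view
#'   with [euclidDistance()]) or a named list of N x N distance matrices
#'   sharing one drug ordering.
#' @param K neighbourhood size (clamped to N-1 with a warning if too large).
#' @param T diffusion iterations.
#' @param mu kernel bandwidth multiplier.
#' @return a [FusedSimilarity-class].
#' @export
snfFuse <- function(views, K = 20L, T = 20L, mu = 0.5) {
  ids <- NULL
  if (is(views, "ReceptorProfileSet")) {
    ids <- views@drugIds
    views <- lapply(views@profiles, function(m) euclidDistance(m))
  } else {
    stopifnot(is.list(views))
  }
  M <- length(views)
  if (M == 0L) stop("no similarity views to fuse")
  if (is.null(ids)) ids <- rownames(views[[1L]])
  n <- nrow(views[[1L]])
  if (is.null(ids)) ids <- paste0("drug", seq_len(n))
  for (D in views)
    stopifnot(identical(dim(D), as.integer(c(n, n))))
  if (K >= n) {
    warning("K >= N; clamped to N - 1")
    K <- n - 1L
  }
  K <- max(1L, as.integer(K))

  P <- vector("list", M)
  S <- vector("list", M)
  for (v in seq_len(M)) {
    W <- affinityKernel(views[[v]], K = K, mu = mu)
    P[[v]] <- .snfNormalize(W)
    S[[v]] <- .snfLocalKernel(W, views[[v]], K)
  }

  for (t in seq_len(T)) {
    Pnew <- vector("list", M)
    for (v in seq_len(M)) {
      others <- if (M == 1L) P else P[-v]
      Pbar <- Reduce(`+`, others) / length(others)
      Q <- S[[v]] %*% Pbar %*% t(S[[v]])
      Pnew[[v]] <- .snfNormalize((Q + t(Q)) / 2)
    }
    P <- Pnew
  }
  fused <- Reduce(`+`, P) / M
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- list(ids, ids)
  new("FusedSimilarity", matrix = fused, viewsUsed = as.integer(M),
      params = list(K = K, T = T, mu = mu))
}

#' Biological-function feature of one drug
#'
#' The drug's row of the fused similarity matrix, in the canonical drug
#' order: its similarity profile against every drug. Unknown drugs return
#' the zero vector with a warning, mirroring the pipeline's tolerance for
#' missing information.
#'
#' @param fused a [FusedSimilarity-class].
#' @param drug drug id.
#' @return numeric N-vector.
#' @export
bioFeature <- function(fused, drug) {
  ids <- drugIds(fused)
  if (!drug %in% ids) {
    warning("drug not in fused similarity: ", drug, "; zero vector returned")
    return(stats::setNames(numeric(length(ids)), ids))
  }
  fused@matrix[drug, ]
}
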