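# Shared fixtures and independent reference implementations used as oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force pairwise AUC: fraction of (pos, neg) pairs ranked correctly,
# ties counted one half
refPairwiseAuc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# plain-loop confusion counts at a threshold
refConfusion <- function(labels, scores, thr = 0.5) {
  pred <- as.integer(scores >= thr)
  c(tp = sum(pred == 1 & labels == 1), fp = sum(pred == 1 & labels == 0),
    tn = sum(pred == 0 & labels == 0), fn = sum(pred == 0 & labels == 1))
}

# independent SNF reference: naive loop translation of the cross-diffusion
# scheme (full kernel P, KNN kernel S, T rounds against the mean of the
# other views, symmetrized mean output)
refSnf <- function(dists, K, T, mu) {
  n <- nrow(dists[[1]])
  kern <- function(D) {
    dbar <- numeric(n)
    for (i in 1:n) dbar[i] <- mean(sort(D[i, -i])[1:K])
    W <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      eps <- max((dbar[i] + dbar[j] + D[i, j]) / 3, .Machine$double.eps)
      W[i, j] <- exp(-D[i, j]^2 / (mu * eps))
    }
    (W + t(W)) / 2
  }
  normP <- function(W) {
    P <- matrix(0, n, n)
    for (i in 1:n) {
      s <- sum(W[i, -i])
      if (s == 0) s <- 1
      for (j in 1:n) P[i, j] <- if (i == j) 0.5 else W[i, j] / (2 * s)
    }
    P
  }
  localS <- function(W, D) {
    S <- matrix(0, n, n)
    for (i in 1:n) {
      ord <- order(D[i, ], 1:n)
      ord <- ord[ord != i][1:K]
      S[i, ord] <- W[i, ord] / sum(W[i, ord])
    }
    S
  }
  M <- length(dists)
  P <- list(); S <- list()
  for (v in 1:M) {
    W <- kern(dists[[v]])
    P[[v]] <- normP(W)
    S[[v]] <- localS(W, dists[[v]])
  }
  for (t in 1:T) {
    Pn <- list()
    for (v in 1:M) {
      others <- if (M == 1) P else P[-v]
      Pbar <- Reduce(`+`, others) / length(others)
      Q <- S[[v]] %*% Pbar %*% t(S[[v]])
      Pn[[v]] <- normP((Q + t(Q)) / 2)
    }
    P <- Pn
  }
  out <- Reduce(`+`, P) / M
  (out + t(out)) / 2
}

# cosine similarity of two vectors
cosSim <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

# mean pairwise cosine within / between two node groups of an embedding
groupCosines <- function(emb, groupA, groupB) {
  V <- vertexVectors(emb)
  within <- c()
  for (g in list(groupA, groupB)) {
    g <- intersect(g, rownames(V))
    cmb <- combn(g, 2)
    within <- c(within, vapply(seq_len(ncol(cmb)), function(k)
      cosSim(V[cmb[1, k], ], V[cmb[2, k], ]), numeric(1)))
  }
  between <- c()
  for (u in intersect(groupA, rownames(V)))
    for (v in intersect(groupB, rownames(V)))
      between <- c(between, cosSim(V[u, ], V[v, ]))
  c(within = mean(within), between = mean(between))
}

# graph fixtures
pathGraph <- function(n) {
  buildGraph(data.frame(a = sprintf("n%02d", 1:(n - 1)),
                        b = sprintf("n%02d", 2:n)))
}

starGraph <- function(nLeaves) {
  buildGraph(data.frame(a = "hub", b = sprintf("leaf%02d", 1:nLeaves)))
}

# two cliques of size k joined by one bridge edge
bridgedCliques <- function(k) {
  cl <- function(pref) {
    ids <- sprintf("%s%02d", pref, 1:k)
    cmb <- combn(ids, 2)
    data.frame(a = cmb[1, ], b = cmb[2, ])
  }
  e <- rbind(cl("a"), cl("b"),
             data.frame(a = sprintf("a%02d", k), b = "b01"))
  buildGraph(e)
}

# barbell: two cliques of size k joined by a path of length 3
barbellGraph <- function(k) {
  cl <- function(pref) {
    ids <- sprintf("%s%02d", pref, 1:k)
    cmb <- combn(ids, 2)
    data.frame(a = cmb[1, ], b = cmb[2, ])
  }
  e <- rbind(cl("a"), cl("b"),
             data.frame(a = c(sprintf("a%02d", k), "p1", "p2"),
                        b = c("p1", "p2", "b01")))
  buildGraph(e)
}

# tiny feature set with random channels, for trainer-level tests
randomFeatureSet <- function(n = 10, seed = 1, lMax = 8) {
  set.seed(seed)
  ids <- sprintf("d%02d", 1:n)
  pl <- list(); nz <- integer(n)
  for (i in 1:n) {
    M <- matrix(0, lMax, lMax)
    M[1:(lMax / 2), ] <- rnorm(lMax * lMax / 2)
    p <- DDIfuse:::.drugPatches(M, 3L)
    pl[[i]] <- p$X; nz[i] <- p$nzero
  }
  rows <- vapply(pl, nrow, 1L)
  emptyEmb <- new("NodeEmbedding",
                  vertexVectors = matrix(0, 0, 64),
                  contextVectors = matrix(0, 0, 64))
  new("DrugFeatureSet", drugIds = ids,
      chemPatches = do.call(rbind, pl),
      chemOffsets = as.integer(c(0, cumsum(rows))),
      chemZeroPatches = as.integer(nz),
      net = matrix(rnorm(n * 64), n, 64, dimnames = list(ids, NULL)),
      bio = matrix(rnorm(n * n), n, n, dimnames = list(ids, ids)),
      cbow = new("TokenEmbeddingTable", vocab = "A",
                 inputWeights = matrix(0, 1, 2),
                 outputWeights = matrix(0, 1, 2),
                 window = 2L, counts = c(A = 1L)),
      embedding = emptyEmb,
      fused = new("FusedSimilarity",
                  matrix = matrix(0, n, n, dimnames = list(ids, ids)),
                  viewsUsed = 1L, params = list(K = 1, T = 1, mu = 0.5)),
      graph = buildGraph(data.frame(a = ids[1], b = ids[2]), nodes = ids))
}

# a small, fast training configuration for protocol-level tests
cheapConfig <- function(...) {
  ddiConfig(cbowEpochs = 3L, cbowDim = 64L, lineEpochs = 30L,
            epochs = 4L, patience = 4L, batchSize = 128L, ...)
}
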