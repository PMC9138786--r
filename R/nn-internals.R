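# Internal machinery of the end-to-end fusion classifier: weight
# initialization, forward/backward passes and the Adam optimizer. The
# channel reducers (conv+GAP chem reducer, dense net reducer, 300-64 bio
# reducer), the attention block and the classifier head are trained jointly
# against binary cross-entropy; the CBOW table, node embedding and fused
# similarity behind the channels are precomputed and held fixed.

# memoized single-precision patch cache behind an external pointer;
# invalidated pointers (e.g. after deserialization) are rebuilt
.convCache <- function(feat) {
  env <- feat@cache
  if (is.null(env$conv) || !.convCacheValidCpp(env$conv))
    env$conv <- .convCacheCreateCpp(feat@chemPatches, feat@chemOffsets,
                                    feat@chemZeroPatches)
  env$conv
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

.initFusionWeights <- function(config, nBio, seed) {
  set.seed(seed)
  d <- 64L
  s2 <- config$convSize^2
  h <- config$hiddenSizes
  w <- list(
    Wc = .glorot(s2, config$convKernels), bc = numeric(config$convKernels),
    Wn = .glorot(d, d), bn = numeric(d),
    Wb1 = .glorot(nBio, 300L), bb1 = numeric(300L),
    Wb2 = .glorot(300L, d), bb2 = numeric(d),
    Wq = .glorot(d, d), Wk = .glorot(d, d), Wv = .glorot(d, d),
    Wh1 = .glorot(6L * d, h[1L]), bh1 = numeric(h[1L]),
    Wh2 = .glorot(h[1L], h[2L]), bh2 = numeric(h[2L]),
    Wh3 = .glorot(h[2L], h[3L]), bh3 = numeric(h[3L]),
    Wo = .glorot(h[3L], 1L), bo = numeric(1L)
  )
  w
}

# per-drug channel tokens + attention fusion for the unique drugs of a batch
# uIdx: indices into feat@drugIds; ghost: logical, drugs scored with zero
# bundles (absent from every channel)
.fusionForward <- function(w, feat, uIdx, config, ghost = NULL) {
  m <- length(uIdx)
  d <- 64L
  zero <- matrix(0, m, d)
  totalPos <- config$lMax^2

  chem <- if (config$useChem)
    .convGapForwardCpp(.convCache(feat), w$Wc, w$bc, uIdx, totalPos)
  else zero

  if (config$useNet) {
    netPre <- sweep(feat@net[uIdx, , drop = FALSE] %*% w$Wn, 2L, w$bn, "+")
    netH <- pmax(netPre, 0)
  } else {
    netPre <- netH <- zero
  }

  if (config$useBio) {
    bioPre1 <- sweep(feat@bio[uIdx, , drop = FALSE] %*% w$Wb1, 2L, w$bb1, "+")
    bioH1 <- pmax(bioPre1, 0)
    bioPre2 <- sweep(bioH1 %*% w$Wb2, 2L, w$bb2, "+")
    bioH2 <- pmax(bioPre2, 0)
  } else {
    bioPre1 <- bioH1 <- NULL
    bioPre2 <- bioH2 <- zero
  }

  Tk <- list(chem, netH, bioH2)
  if (!is.null(ghost) && any(ghost))
    for (t in 1:3) Tk[[t]][ghost, ] <- 0

  if (config$useAttention) {
    scale <- 1 / sqrt(64)
    Q <- lapply(Tk, function(x) x %*% w$Wq)
    K <- lapply(Tk, function(x) x %*% w$Wk)
    V <- lapply(Tk, function(x) x %*% w$Wv)
    A <- vector("list", 3L)
    for (a in 1:3) {
      S <- cbind(rowSums(Q[[a]] * K[[1L]]),
                 rowSums(Q[[a]] * K[[2L]]),
                 rowSums(Q[[a]] * K[[3L]])) * scale
      A[[a]] <- .softmaxRows(S)
    }
    O <- vector("list", 3L)
    for (a in 1:3)
      O[[a]] <- A[[a]][, 1L] * V[[1L]] + A[[a]][, 2L] * V[[2L]] +
                A[[a]][, 3L] * V[[3L]]
    fused <- cbind(O[[1L]], O[[2L]], O[[3L]])
  } else {
    Q <- K <- V <- A <- O <- NULL
    fused <- cbind(Tk[[1L]], Tk[[2L]], Tk[[3L]])
  }

  list(uIdx = uIdx, ghost = ghost, chem = chem,
       netPre = netPre, bioPre1 = bioPre1, bioH1 = bioH1, bioPre2 = bioPre2,
       tokens = Tk, Q = Q, K = K, V = V, A = A, fused = fused)
}

# gradients of the channel reducers + attention given dFused (m x 192)
.fusionBackward <- function(w, feat, fw, dFused, config, grads) {
  uIdx <- fw$uIdx
  d <- 64L
  Tk <- fw$tokens

  if (config$useAttention) {
    scale <- 1 / sqrt(64)
    dO <- list(dFused[, 1:64, drop = FALSE],
               dFused[, 65:128, drop = FALSE],
               dFused[, 129:192, drop = FALSE])
    A <- fw$A; Q <- fw$Q; K <- fw$K; V <- fw$V
    dV <- list(0, 0, 0); dQ <- vector("list", 3L); dK <- list(0, 0, 0)
    dS <- vector("list", 3L)
    for (a in 1:3) {
      dA <- cbind(rowSums(dO[[a]] * V[[1L]]),
                  rowSums(dO[[a]] * V[[2L]]),
                  rowSums(dO[[a]] * V[[3L]]))
      dS[[a]] <- A[[a]] * (dA - rowSums(A[[a]] * dA)) * scale
      for (b in 1:3)
        dV[[b]] <- dV[[b]] + A[[a]][, b] * dO[[a]]
    }
    for (a in 1:3)
      dQ[[a]] <- dS[[a]][, 1L] * K[[1L]] + dS[[a]][, 2L] * K[[2L]] +
                 dS[[a]][, 3L] * K[[3L]]
    for (b in 1:3)
      dK[[b]] <- dS[[1L]][, b] * Q[[1L]] + dS[[2L]][, b] * Q[[2L]] +
                 dS[[3L]][, b] * Q[[3L]]
    grads$Wq <- Reduce(`+`, lapply(1:3, function(a) crossprod(Tk[[a]], dQ[[a]])))
    grads$Wk <- Reduce(`+`, lapply(1:3, function(a) crossprod(Tk[[a]], dK[[a]])))
    grads$Wv <- Reduce(`+`, lapply(1:3, function(a) crossprod(Tk[[a]], dV[[a]])))
    dT <- lapply(1:3, function(a)
      tcrossprod(dQ[[a]], w$Wq) + tcrossprod(dK[[a]], w$Wk) +
      tcrossprod(dV[[a]], w$Wv))
  } else {
    dT <- list(dFused[, 1:64, drop = FALSE],
               dFused[, 65:128, drop = FALSE],
               dFused[, 129:192, drop = FALSE])
  }

  if (!is.null(fw$ghost) && any(fw$ghost))
    for (t in 1:3) dT[[t]][fw$ghost, ] <- 0

  if (config$useChem) {
    cb <- .convGapBackwardCpp(.convCache(feat), w$Wc, w$bc, uIdx,
                              config$lMax^2, dT[[1L]])
    grads$Wc <- cb$dW
    grads$bc <- as.numeric(cb$db)
  }
  if (config$useNet) {
    dPre <- dT[[2L]] * (fw$netPre > 0)
    grads$Wn <- crossprod(feat@net[uIdx, , drop = FALSE], dPre)
    grads$bn <- colSums(dPre)
  }
  if (config$useBio) {
    dPre2 <- dT[[3L]] * (fw$bioPre2 > 0)
    grads$Wb2 <- crossprod(fw$bioH1, dPre2)
    grads$bb2 <- colSums(dPre2)
    dH1 <- tcrossprod(dPre2, w$Wb2) * (fw$bioPre1 > 0)
    grads$Wb1 <- crossprod(feat@bio[uIdx, , drop = FALSE], dH1)
    grads$bb1 <- colSums(dH1)
  }
  grads
}

# classifier head: three ReLU hidden layers with dropout, sigmoid output
.headForward <- function(w, Z, config, dropout = FALSE) {
  keep <- 1 - config$dropout
  mask <- function(dim1, dim2) {
    if (dropout && config$dropout > 0)
      matrix(stats::rbinom(dim1 * dim2, 1L, keep) / keep, dim1, dim2)
    else NULL
  }
  P1 <- sweep(Z %*% w$Wh1, 2L, w$bh1, "+"); H1 <- pmax(P1, 0)
  m1 <- mask(nrow(H1), ncol(H1)); if (!is.null(m1)) H1 <- H1 * m1
  P2 <- sweep(H1 %*% w$Wh2, 2L, w$bh2, "+"); H2 <- pmax(P2, 0)
  m2 <- mask(nrow(H2), ncol(H2)); if (!is.null(m2)) H2 <- H2 * m2
  P3 <- sweep(H2 %*% w$Wh3, 2L, w$bh3, "+"); H3 <- pmax(P3, 0)
  m3 <- mask(nrow(H3), ncol(H3)); if (!is.null(m3)) H3 <- H3 * m3
  logit <- drop(H3 %*% w$Wo) + w$bo
  list(Z = Z, P1 = P1, H1 = H1, P2 = P2, H2 = H2, P3 = P3, H3 = H3,
       m1 = m1, m2 = m2, m3 = m3,
       logit = logit, p = stats::plogis(logit))
}

.headBackward <- function(w, hf, dLogit, grads) {
  grads$Wo <- crossprod(hf$H3, dLogit)
  grads$bo <- sum(dLogit)
  dH3 <- dLogit %*% t(w$Wo)
  if (!is.null(hf$m3)) dH3 <- dH3 * hf$m3
  dP3 <- dH3 * (hf$P3 > 0)
  grads$Wh3 <- crossprod(hf$H2, dP3); grads$bh3 <- colSums(dP3)
  dH2 <- tcrossprod(dP3, w$Wh3)
  if (!is.null(hf$m2)) dH2 <- dH2 * hf$m2
  dP2 <- dH2 * (hf$P2 > 0)
  grads$Wh2 <- crossprod(hf$H1, dP2); grads$bh2 <- colSums(dP2)
  dH1 <- tcrossprod(dP2, w$Wh2)
  if (!is.null(hf$m1)) dH1 <- dH1 * hf$m1
  dP1 <- dH1 * (hf$P1 > 0)
  grads$Wh1 <- crossprod(hf$Z, dP1); grads$bh1 <- colSums(dP1)
  grads$dZ <- tcrossprod(dP1, w$Wh1)
  grads
}

# Adam with bias correction; state kept alongside the weights
.adamInit <- function(w) {
  list(m = lapply(w, function(x) x * 0), v = lapply(w, function(x) x * 0),
       t = 0L)
}

.adamStep <- function(w, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(w)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    w[[nm]] <- w[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(w = w, state = state)
}

# mean binary cross-entropy with clamped probabilities
.bceLoss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
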