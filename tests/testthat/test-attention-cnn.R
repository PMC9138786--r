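test_that("convolutional reduction collapses to one value per kernel", {
  set.seed(41)
  m <- matrix(0, 16, 16)
  m[1:5, ] <- rnorm(80)
  for (k in c(8L, 64L)) {
    W <- matrix(rnorm(9 * k, sd = 0.1), 9, k)
    out <- cnnReduce(m, W, numeric(k))
    expect_length(out, k)
  }
  W5 <- matrix(rnorm(25 * 8, sd = 0.1), 25, 8)
  expect_length(cnnReduce(m, W5, numeric(8)), 8L)
})

test_that("all-zero input with zero bias pools to zero", {
  W <- matrix(rnorm(9 * 16), 9, 16)
  out <- cnnReduce(matrix(0, 12, 12), W, numeric(16))
  expect_identical(unname(out), numeric(16))
})

test_that("linear-activation reduction is homogeneous of degree one", {
  set.seed(42)
  m <- matrix(0, 16, 16); m[1:6, ] <- rnorm(96)
  W <- matrix(rnorm(9 * 8), 9, 8)
  b <- numeric(8)
  one <- cnnReduce(m, W, b, activation = "linear")
  two <- cnnReduce(2 * m, W, b, activation = "linear")
  expect_equal(two, 2 * one, tolerance = 1e-12)
  # and with ReLU on a nonnegative configuration
  Wp <- abs(matrix(rnorm(9 * 8), 9, 8))
  oneR <- cnnReduce(abs(m), Wp, b)
  twoR <- cnnReduce(2 * abs(m), Wp, b)
  expect_equal(twoR, 2 * oneR, tolerance = 1e-12)
})

test_that("the R reducer and the compiled training kernel agree", {
  set.seed(43)
  lMax <- 16L
  W <- matrix(rnorm(9 * 32, sd = 0.2), 9, 32)
  b <- rnorm(32, sd = 0.1)
  pl <- list(); nz <- integer(3)
  ms <- list()
  for (i in 1:3) {
    M <- matrix(0, lMax, lMax)
    M[1:(3 * i), ] <- rnorm(3 * i * lMax)
    ms[[i]] <- M
    p <- DDIfuse:::.drugPatches(M, 3L)
    pl[[i]] <- p$X; nz[i] <- p$nzero
  }
  rows <- vapply(pl, nrow, 1L)
  cache <- DDIfuse:::.convCacheCreateCpp(do.call(rbind, pl),
                                         as.integer(c(0, cumsum(rows))),
                                         as.integer(nz))
  got <- DDIfuse:::.convGapForwardCpp(cache, W, b, 1:3, lMax * lMax)
  # the training kernel runs in single precision; the R reducer in double
  for (i in 1:3)
    expect_equal(got[i, ], unname(cnnReduce(ms[[i]], W, b)),
                 tolerance = 1e-5)
})

test_that("attention rows sum to one for random inputs", {
  set.seed(44)
  blk <- newAttentionBlock(dim = 16, seed = 2)
  for (r in 1:5) {
    tok <- matrix(rnorm(3 * 16), 3, 16)
    out <- attentionFuse(tok, blk)
    A <- attr(out, "weights")
    expect_equal(unname(rowSums(A)), rep(1, 3), tolerance = 1e-6)
    expect_length(as.numeric(out), 48L)
  }
})

test_that("constant logits return the unweighted token mean", {
  set.seed(45)
  d <- 16
  blk <- list(Wq = matrix(0, d, d), Wk = matrix(0, d, d),
              Wv = diag(d), dk = d)
  tok <- matrix(rnorm(3 * d), 3, d)
  out <- attentionFuse(tok, blk)
  mu <- colMeans(tok)
  for (a in 1:3)
    expect_equal(as.numeric(out)[(a - 1) * d + 1:d], mu, tolerance = 1e-12)
})

test_that("a single token attends only to itself", {
  set.seed(46)
  d <- 8
  blk <- newAttentionBlock(dim = d, seed = 3)
  tok <- matrix(rnorm(d), 1, d)
  out <- attentionFuse(tok, blk)
  expect_equal(unname(attr(out, "weights")[1, 1]), 1)
  expect_equal(as.numeric(out), as.numeric(tok %*% blk$Wv), tolerance = 1e-12)
})

test_that("the batched training attention agrees with the single-drug operator", {
  set.seed(47)
  feat <- randomFeatureSet(n = 6, seed = 5)
  cfg <- ddiConfig(lMax = 8L)
  w <- DDIfuse:::.initFusionWeights(cfg, 6L, seed = 6)
  fw <- DDIfuse:::.fusionForward(w, feat, 1:6, cfg)
  blk <- list(Wq = w$Wq, Wk = w$Wk, Wv = w$Wv, dk = 64)
  for (i in c(1L, 4L)) {
    tok <- rbind(fw$tokens[[1]][i, ], fw$tokens[[2]][i, ], fw$tokens[[3]][i, ])
    expect_equal(unname(fw$fused[i, ]), as.numeric(attentionFuse(tok, blk)),
                 tolerance = 1e-12)
  }
})
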