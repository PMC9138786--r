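makeCorpus <- function(nSent = 100, seed = 1) {
  set.seed(seed)
  alph <- LETTERS[1:12]
  lapply(seq_len(nSent), function(i)
    sample(alph, sample(5:15, 1), replace = TRUE))
}

test_that("predicted center-token distribution sums to one", {
  corp <- list(rep(c("A", "B"), 10))
  tb <- trainCbow(corp, dim = 16, window = 2, epochs = 5, seed = 1)
  p <- cbowProbability(tb, c("A", "B", "A"))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  tb2 <- trainCbow(makeCorpus(20), dim = 16, window = 3, epochs = 3, seed = 2)
  for (ctx in list("A", c("B", "C"), c("D", "D", "E")))
    expect_equal(sum(cbowProbability(tb2, ctx)), 1, tolerance = 1e-6)
})

test_that("training reduces the objective on a fixed corpus", {
  corp <- makeCorpus(100, seed = 3)
  tb1 <- trainCbow(corp, dim = 32, window = 4, epochs = 1, seed = 5)
  tbE <- trainCbow(corp, dim = 32, window = 4, epochs = 12, seed = 5)
  expect_lte(cbowObjective(tbE, corp), cbowObjective(tb1, corp))
})

test_that("tokens that only ever co-occur are closer than random pairs in a shuffled control", {
  # the planted pair appears only as an interleaved block, so A and B share
  # their prediction contexts; that co-occurrence signal lives in the
  # softmax (output) vectors, which score center-token probability
  outVec <- function(tb, tok) tb@outputWeights[match(tok, tb@vocab), ]
  for (r in 1:20) {
    set.seed(100 + r)
    filler <- LETTERS[3:10]
    corp <- lapply(1:30, function(i) {
      s <- sample(filler, sample(4:8, 1), replace = TRUE)
      at <- sample(length(s), 1)
      append(s, c("A", "B", "A", "B"), after = at)
    })
    tb <- trainCbow(corp, dim = 16, window = 2, epochs = 25, lr = 0.3,
                    seed = r)
    planted <- cosSim(outVec(tb, "A"), outVec(tb, "B"))
    # control: same pipeline, same seed policy, token-shuffled corpus
    flat <- unlist(corp)
    set.seed(100 + r)
    flat <- sample(flat)
    shuf <- split(flat, rep(seq_along(corp), lengths(corp)))
    tbS <- trainCbow(shuf, dim = 16, window = 2, epochs = 25, lr = 0.3,
                     seed = r)
    pairs <- combn(tbS@vocab, 2)
    ctrl <- mean(vapply(seq_len(ncol(pairs)), function(k)
      cosSim(outVec(tbS, pairs[1, k]), outVec(tbS, pairs[2, k])),
      numeric(1)))
    expect_gt(planted, ctrl)
  }
})

test_that("training is reproducible for a fixed seed", {
  corp <- makeCorpus(30, seed = 9)
  a <- trainCbow(corp, dim = 16, window = 3, epochs = 4, seed = 77)
  b <- trainCbow(corp, dim = 16, window = 3, epochs = 4, seed = 77)
  expect_identical(a@inputWeights, b@inputWeights)
  expect_identical(a@outputWeights, b@outputWeights)
})

test_that("minCount filters rare tokens and empty vocabularies error", {
  corp <- list(c("A", "A", "A", "B"), c("A", "A"))
  tb <- trainCbow(corp, dim = 8, window = 2, epochs = 1, minCount = 2)
  expect_identical(tb@vocab, "A")
  expect_error(trainCbow(corp, dim = 8, minCount = 10), "no tokens retained")
})

test_that("drug matrix obeys padding, truncation and unknown-token rules", {
  corp <- makeCorpus(20, seed = 4)
  tb <- trainCbow(corp, dim = 16, window = 3, epochs = 2, seed = 1)

  m <- buildDrugMatrix(c("A", "B", "C"), tb, lMax = 64)
  expect_identical(dim(m), c(64L, 16L))
  expect_equal(m[1, ], unname(tokenVector(tb, "A")))
  expect_equal(m[3, ], unname(tokenVector(tb, "C")))
  expect_true(all(m[4:64, ] == 0))

  long <- sample(tb@vocab, 100, replace = TRUE)
  mLong <- buildDrugMatrix(long, tb, lMax = 64)
  expect_identical(dim(mLong), c(64L, 16L))
  for (i in c(1, 40, 64))
    expect_equal(mLong[i, ], unname(tokenVector(tb, long[i])))

  mUnk <- buildDrugMatrix(c("zz", "qq"), tb, lMax = 64)
  expect_true(all(mUnk == 0))

  # padding adds nothing to the Frobenius norm
  placed <- rbind(tokenVector(tb, "A"), tokenVector(tb, "B"),
                  tokenVector(tb, "C"))
  expect_equal(sqrt(sum(m^2)), sqrt(sum(placed^2)))
})
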