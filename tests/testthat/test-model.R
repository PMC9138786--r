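smallWorldSetup <- function(seed = 81, nDrugs = 60) {
  w <- genWorld(nDrugs = nDrugs, nCommunities = 3, seed = seed,
                receptorsPerType = 30)
  s <- balancedSamples(DDIfuse:::.canonicalPairs(w@edges), drugIds(w),
                       seed = seed)
  cfg <- cheapConfig()
  assignment <- splitAssign(nrow(s), seed = seed + 1)
  trainPos <- s[assignment == "train" & s$label == 1,
                c("drug_id_a", "drug_id_b")]
  feat <- buildFeatureSet(w@drugs, trainPos, w@associations,
                          config = cfg, seed = seed + 2)
  list(world = w, samples = s, assignment = assignment, features = feat,
       config = cfg)
}

test_that("training reduces the loss and records a history", {
  su <- smallWorldSetup()
  model <- trainDdiModel(su$features,
                         su$samples[su$assignment == "train", ],
                         su$samples[su$assignment == "val", ],
                         config = su$config, seed = 1)
  h <- model@history
  expect_gte(nrow(h), 2L)
  expect_lte(h$train[nrow(h)], h$train[1])
})

test_that("predictions are probabilities, symmetric and deterministic", {
  su <- smallWorldSetup()
  model <- trainDdiModel(su$features,
                         su$samples[su$assignment == "train", ],
                         su$samples[su$assignment == "val", ],
                         config = su$config, seed = 2)
  test <- su$samples[su$assignment == "test", ][1:20, ]
  p1 <- as.numeric(predictScores(model, test[, 1:2]))
  expect_true(all(p1 > 0 & p1 < 1))
  # reversed pairs score identically
  rev <- test[, c("drug_id_b", "drug_id_a")]
  expect_equal(as.numeric(predictScores(model, rev)), p1, tolerance = 1e-12)
  # duplicates and repeat calls are stable
  expect_equal(as.numeric(predictScores(model, test[, 1:2])), p1)
})

test_that("training is reproducible for a fixed seed", {
  su <- smallWorldSetup()
  m1 <- trainDdiModel(su$features,
                      su$samples[su$assignment == "train", ],
                      su$samples[su$assignment == "val", ],
                      config = su$config, seed = 3)
  m2 <- trainDdiModel(su$features,
                      su$samples[su$assignment == "train", ],
                      su$samples[su$assignment == "val", ],
                      config = su$config, seed = 3)
  expect_identical(m1@weights, m2@weights)
})

test_that("drugs absent from every channel are scored with zero bundles and flagged", {
  su <- smallWorldSetup()
  model <- trainDdiModel(su$features,
                         su$samples[su$assignment == "train", ],
                         su$samples[su$assignment == "val", ],
                         config = su$config, seed = 4)
  ids <- drugIds(su$features)
  pairs <- data.frame(a = c(ids[1], "GHOST1", "GHOST1"),
                      b = c("GHOST2", ids[2], "GHOST2"))
  expect_warning(p <- predictScores(model, pairs), "zero feature bundles")
  expect_identical(attr(p, "ghost"), c(TRUE, TRUE, TRUE))
  expect_true(all(as.numeric(p) > 0 & as.numeric(p) < 1))
  # a fully ghosted pair scores like the all-zero representation, both orders
  pairsSwap <- data.frame(a = pairs$b, b = pairs$a)
  expect_warning(p2 <- predictScores(model, pairsSwap), "zero")
  expect_equal(as.numeric(p2), as.numeric(p), tolerance = 1e-12)
})

test_that("single-class training sets are rejected", {
  su <- smallWorldSetup()
  bad <- su$samples[su$samples$label == 1, ][1:20, ]
  expect_error(trainDdiModel(su$features, bad, config = su$config),
               "both classes")
})

test_that("channel ablation flags zero the corresponding token", {
  su <- smallWorldSetup()
  cfg <- su$config
  cfg$useChem <- FALSE
  cfg$useBio <- FALSE
  w <- DDIfuse:::.initFusionWeights(cfg, ncol(su$features@bio), seed = 5)
  fw <- DDIfuse:::.fusionForward(w, su$features, 1:4, cfg)
  expect_identical(fw$tokens[[1]], matrix(0, 4, 64))
  expect_identical(fw$tokens[[3]], matrix(0, 4, 64))
  expect_false(all(fw$tokens[[2]] == 0))
})

test_that("disabling attention concatenates the raw channel tokens", {
  su <- smallWorldSetup()
  cfg <- su$config
  cfg$useAttention <- FALSE
  w <- DDIfuse:::.initFusionWeights(cfg, ncol(su$features@bio), seed = 6)
  fw <- DDIfuse:::.fusionForward(w, su$features, 1:3, cfg)
  expect_identical(fw$fused,
                   cbind(fw$tokens[[1]], fw$tokens[[2]], fw$tokens[[3]]))
})
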