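test_that("metrics match brute-force confusion arithmetic on random instances", {
  set.seed(31)
  for (r in 1:1000) {
    n <- sample(10:40, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    # mix continuous and heavily tied score sets
    scores <- if (r %% 3 == 0) sample(seq(0, 1, 0.25), n, replace = TRUE)
              else runif(n)
    m <- computeMetrics(labels, scores)
    cc <- refConfusion(labels, scores)
    ref <- confusionMetrics(cc["tp"], cc["fp"], cc["tn"], cc["fn"])
    expect_identical(unname(m[c("TP", "FP", "TN", "FN")]),
                     as.numeric(cc[c("tp", "fp", "tn", "fn")]))
    expect_equal(unname(m[c("Acc", "Prec", "Sen", "F1", "MCC")]),
                 unname(ref))
    expect_equal(m[["AUC"]], refPairwiseAuc(labels, scores),
                 tolerance = 1e-9)
  }
})

test_that("frozen confusion example gives the textbook values", {
  m <- confusionMetrics(tp = 3, fp = 1, tn = 4, fn = 2)
  expect_equal(m[["Prec"]], 0.75)
  expect_equal(m[["Sen"]], 0.6)
  expect_equal(m[["F1"]], 2 / 3, tolerance = 1e-12)
  expect_equal(m[["MCC"]], (3 * 4 - 1 * 2) / sqrt(4 * 6 * 5 * 5),
               tolerance = 1e-12)
  expect_equal(m[["MCC"]], 0.4082483, tolerance = 1e-7)
})

test_that("perfect predictions hit the metric ceilings", {
  labels <- c(1, 1, 1, 0, 0)
  m <- computeMetrics(labels, labels)
  expect_equal(unname(m[c("Acc", "Prec", "Sen", "F1", "MCC", "AUC", "AUPR")]),
               rep(1, 7))
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  for (r in 1:20) {
    labels <- rbinom(50, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    scores <- runif(50)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(aucScore(labels, scores), ref, tolerance = 1e-12)
  }
})

test_that("MCC negates when all predictions flip", {
  set.seed(33)
  labels <- rbinom(40, 1, 0.5); labels[1:2] <- c(0L, 1L)
  scores <- runif(40)
  m1 <- computeMetrics(labels, scores)
  m2 <- computeMetrics(labels, 1 - scores)   # flips thresholded predictions
  expect_equal(m1[["MCC"]], -m2[["MCC"]], tolerance = 1e-12)
  expect_true(abs(m1[["MCC"]]) <= 1)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(34)
  labels <- rbinom(60, 1, 0.4); labels[1:2] <- c(0L, 1L)
  scores <- rnorm(60)
  a <- aucScore(labels, scores)
  expect_equal(aucScore(labels, exp(scores)), a, tolerance = 1e-12)
  expect_equal(aucScore(labels, 5 * scores - 3), a, tolerance = 1e-12)
  expect_equal(auprScore(labels, plogis(scores)),
               auprScore(labels, scores), tolerance = 1e-12)
})

test_that("single-class inputs yield NA for rank and correlation metrics", {
  m <- computeMetrics(c(1, 1, 1), c(0.9, 0.8, 0.2))
  expect_true(is.na(m[["AUC"]]))
  expect_true(is.na(m[["AUPR"]]))
  expect_true(is.na(m[["MCC"]]))
  expect_equal(m[["Acc"]], 2 / 3, tolerance = 1e-12)
  expect_equal(m[["Sen"]], 2 / 3, tolerance = 1e-12)
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  set.seed(35)
  for (r in 1:50) {
    labels <- rbinom(30, 1, 0.5); labels[1:2] <- c(0L, 1L)
    m <- computeMetrics(labels, runif(30))
    if (!is.na(m[["F1"]]))
      expect_equal(m[["F1"]],
                   2 * m[["Prec"]] * m[["Sen"]] / (m[["Prec"]] + m[["Sen"]]),
                   tolerance = 1e-12)
  }
})

test_that("fold reports summarize mean and sd over exactly k folds", {
  pf <- data.frame(fold = 1:5, Acc = seq(0.8, 0.9, length.out = 5),
                   AUC = seq(0.9, 0.95, length.out = 5))
  rep <- metricsReport(pf)
  expect_identical(nrow(rep@perFold), 5L)
  expect_equal(rep@summary["mean", "Acc"], mean(pf$Acc))
  expect_equal(rep@summary["sd", "AUC"], sd(pf$AUC))
})
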