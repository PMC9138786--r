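test_that("profile matrices are direct incidence with idempotent duplicates", {
  assoc <- data.frame(
    drug_id = c("A", "B", "B", "B"),
    receptor_id = c("t1", "t1", "t2", "t2"),   # duplicate (B, t2)
    function_type = "target")
  ps <- buildProfiles(assoc, c("A", "B", "C"))
  m <- profileMatrix(ps, "target")
  expect_equal(unname(m), rbind(c(1, 0), c(1, 1), c(0, 0)))
  expect_identical(rownames(m), c("A", "B", "C"))
})

test_that("unknown drugs in associations are rejected, empty views are skipped", {
  assoc <- data.frame(drug_id = "Z", receptor_id = "t1",
                      function_type = "target")
  expect_error(buildProfiles(assoc, c("A", "B")), "Z")
  good <- data.frame(drug_id = "A", receptor_id = "t1",
                     function_type = "target")
  expect_warning(ps <- buildProfiles(good, c("A", "B"),
                                     types = c("target", "enzyme")),
                 "enzyme")
  expect_identical(names(ps@profiles), "target")
})

test_that("profile distances follow the Euclidean identities", {
  m <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(euclidDistance(m)["a", "b"], 5)
  m2 <- rbind(a = c(1, 0, 1), b = c(1, 0, 1))
  expect_equal(euclidDistance(m2)["a", "b"], 0)
  # binary rows differing in k positions -> sqrt(k)
  m3 <- rbind(a = c(1, 0, 1, 0, 1), b = c(0, 1, 1, 0, 0))
  expect_equal(euclidDistance(m3)["a", "b"], sqrt(3))
})

test_that("profile distance is a metric on random binary profiles", {
  set.seed(21)
  for (r in 1:5) {
    m <- matrix(rbinom(80, 1, 0.4), 10, 8)
    rownames(m) <- letters[1:10]
    D <- euclidDistance(m)
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0))
    for (i in 1:10) for (j in 1:10) for (k in 1:10)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("fusion matches an independent cross-diffusion reference on 6x6 views", {
  set.seed(5)
  x1 <- matrix(rnorm(18), 6, 3)
  x2 <- matrix(rnorm(24), 6, 4)
  d1 <- as.matrix(dist(x1)); d2 <- as.matrix(dist(x2))
  dimnames(d1) <- dimnames(d2) <- list(letters[1:6], letters[1:6])
  got <- fusedMatrix(snfFuse(list(d1, d2), K = 3, T = 5, mu = 0.5))
  ref <- refSnf(list(d1, d2), K = 3, T = 5, mu = 0.5)
  expect_equal(unname(got), ref, tolerance = 1e-12)
})

test_that("fusing M identical views equals the single-view result", {
  set.seed(6)
  x <- matrix(rnorm(24), 6, 4)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(letters[1:6], letters[1:6])
  one <- fusedMatrix(snfFuse(list(D), K = 3, T = 10, mu = 0.5))
  three <- fusedMatrix(snfFuse(list(D, D, D), K = 3, T = 10, mu = 0.5))
  expect_lt(max(abs(one - three)), 1e-8)
})

test_that("block-structured views fuse into block-contrasted similarity", {
  set.seed(7)
  blocks <- rep(1:2, each = 5)
  mkview <- function() {
    centers <- rbind(c(5, 0, 0), c(0, 5, 0))
    as.matrix(dist(centers[blocks, ] + matrix(rnorm(30, sd = 0.5), 10, 3)))
  }
  f <- fusedMatrix(snfFuse(list(mkview(), mkview()), K = 3, T = 10, mu = 0.5))
  sameBlock <- outer(blocks, blocks, "==") & !diag(10)
  diffBlock <- outer(blocks, blocks, "!=")
  expect_gt(mean(f[sameBlock]), mean(f[diffBlock]))
})

test_that("normalized kernels are row-stochastic and fusion preserves symmetry", {
  set.seed(8)
  D <- as.matrix(dist(matrix(rnorm(40), 8, 5)))
  W <- affinityKernel(D, K = 3, mu = 0.5)
  expect_equal(W, t(W))
  expect_true(all(W >= 0))
  P <- DDIfuse:::.snfNormalize(W)
  expect_equal(unname(rowSums(P)), rep(1, 8), tolerance = 1e-8)
  f <- snfFuse(list(D), K = 3, T = 7, mu = 0.5)
  expect_equal(fusedMatrix(f), t(fusedMatrix(f)))
  expect_true(all(fusedMatrix(f) >= 0))
})

test_that("fusion is equivariant under drug reordering", {
  set.seed(9)
  ids <- letters[1:7]
  d1 <- as.matrix(dist(matrix(rnorm(21), 7, 3)))
  d2 <- as.matrix(dist(matrix(rnorm(28), 7, 4)))
  dimnames(d1) <- dimnames(d2) <- list(ids, ids)
  f <- fusedMatrix(snfFuse(list(d1, d2), K = 3, T = 5, mu = 0.5))
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  fp <- fusedMatrix(snfFuse(list(d1[perm, perm], d2[perm, perm]),
                            K = 3, T = 5, mu = 0.5))
  expect_equal(fp[ids, ids], f[ids, ids], tolerance = 1e-12)
})

test_that("K is clamped and empty view lists are rejected", {
  D <- as.matrix(dist(matrix(rnorm(12), 4, 3)))
  expect_warning(snfFuse(list(D), K = 10, T = 2), "clamped")
  expect_error(snfFuse(list(), K = 2, T = 2), "no similarity views")
})

test_that("bio features are fused rows with symmetric cross-entries", {
  set.seed(10)
  D <- as.matrix(dist(matrix(rnorm(20), 5, 4)))
  dimnames(D) <- list(letters[1:5], letters[1:5])
  f <- snfFuse(list(D), K = 2, T = 3)
  expect_identical(unname(bioFeature(f, "b")), unname(fusedMatrix(f)["b", ]))
  expect_equal(bioFeature(f, "a")[["c"]], bioFeature(f, "c")[["a"]])
  expect_warning(z <- bioFeature(f, "zz"), "zero vector")
  expect_identical(unname(z), numeric(5))
})
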