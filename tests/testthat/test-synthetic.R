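test_that("null-world edge counts follow the binomial expectation", {
  w <- genWorld(nDrugs = 200, nCommunities = 4, pIn = 0.05, pOut = 0.05,
                seed = 61)
  expected <- choose(200, 2) * 0.05
  expect_gt(nrow(w@edges) / expected, 0.9)
  expect_lt(nrow(w@edges) / expected, 1.1)
})

test_that("generation is reproducible and files are byte-identical per seed", {
  w1 <- genWorld(nDrugs = 30, seed = 62)
  w2 <- genWorld(nDrugs = 30, seed = 62)
  expect_identical(w1@drugs, w2@drugs)
  expect_identical(w1@edges, w2@edges)
  expect_identical(w1@associations, w2@associations)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeWorld(w1, d1)
  writeWorld(w2, d2)
  for (f in c("drugs.tsv", "edges.tsv", "associations.tsv", "world.json"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})

test_that("written worlds round-trip through the readers", {
  w <- genWorld(nDrugs = 25, seed = 63)
  dir <- withr::local_tempdir()
  writeWorld(w, dir)
  expect_identical(readDrugTable(file.path(dir, "drugs.tsv")), w@drugs)
  expect_identical(readEdgeList(file.path(dir, "edges.tsv")), w@edges)
  expect_identical(readAssociations(file.path(dir, "associations.tsv")),
                   w@associations)
})

test_that("invalid probabilities are rejected", {
  expect_error(genWorld(pIn = 0.1, pOut = 0.5), "pOut <= pIn")
  expect_error(genWorld(pIn = 1.2, pOut = 0.1), "pOut <= pIn")
})

test_that("signal worlds fuse into community-contrasted similarity", {
  # within-community fused similarity must exceed between-community
  # similarity in every seeded replicate
  for (s in 1:10) {
    w <- genWorld(nDrugs = 60, nCommunities = 3, seed = 70 + s,
                  receptorsPerType = 30)
    ps <- buildProfiles(w@associations, drugIds(w))
    f <- fusedMatrix(snfFuse(ps, K = 10, T = 10, mu = 0.5))
    comm <- w@community[rownames(f)]
    same <- outer(comm, comm, "==") & !diag(length(comm))
    expect_gt(mean(f[same]), mean(f[outer(comm, comm, "!=")]))
  }
})

test_that("single-community worlds show no block contrast", {
  w <- genWorld(nDrugs = 40, nCommunities = 1, seed = 64,
                receptorsPerType = 30)
  ps <- buildProfiles(w@associations, drugIds(w))
  f <- fusedMatrix(snfFuse(ps, K = 10, T = 10, mu = 0.5))
  # no planted split: an arbitrary halving should show ~zero contrast
  fake <- rep(1:2, each = 20)
  same <- outer(fake, fake, "==") & !diag(40)
  ratio <- mean(f[same]) / mean(f[outer(fake, fake, "!=")])
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("permuted labels decorrelate community structure from the labels", {
  w <- genWorld(nDrugs = 200, seed = 65)
  s <- balancedSamples(DDIfuse:::.canonicalPairs(w@edges), drugIds(w),
                       seed = 65)
  sp <- permuteLabels(s, seed = 66)
  same <- as.integer(w@community[sp$drug_id_a] == w@community[sp$drug_id_b])
  r <- suppressWarnings(cor(sp$label, same))
  expect_lt(abs(r), 0.05)
  # while the unpermuted labels are strongly aligned with the communities
  sameOrig <- as.integer(w@community[s$drug_id_a] == w@community[s$drug_id_b])
  expect_gt(cor(s$label, sameOrig), 0.3)
})
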