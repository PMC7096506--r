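mkModel <- function(id, d = NA_real_, score = NA_real_, ss = "",
                    structure = NULL) {
  if (is.null(structure))
    structure <- newStructure(serial = 1:2, atomName = "CA",
                              residueNumber = 1:2, x = c(0, 3.8),
                              y = 0, z = 0)
  new("CandidateModel", structure = structure, d = d,
      externalScore = score, ss = ss, id = id)
}

test_that("distance filter keeps the inclusive 9.9 +/- 1.0 window", {
  ms <- list(mkModel("a", d = 9.9), mkModel("b", d = 10.9),
             mkModel("c", d = 8.9), mkModel("d", d = 10.9001),
             mkModel("e", d = 8.8999))
  kept <- distanceFilter(ms)
  expect_identical(vapply(kept, function(m) m@id, ""), c("a", "b", "c"))
})

test_that("filter output equals a brute-force recount on a random ensemble", {
  ens <- generateCandidateEnsemble(list(nModels = 200L), seed = 77L)
  models <- computeEnsembleDistances(ens$models, ens$scheme)
  kept <- distanceFilter(models)
  truth <- which(abs(ens$groundTruth$d - 9.9) <= 1.0)
  expect_identical(vapply(kept, function(m) m@id, ""),
                   sprintf("model_%03d", truth))
  # measured distances equal the planted ones
  expect_equal(vapply(models, function(m) m@d, 0), ens$groundTruth$d,
               tolerance = 1e-9)
})

test_that("score ranking returns the k lowest-energy models", {
  ms <- list(mkModel("m1", score = 3), mkModel("m2", score = 1),
             mkModel("m3", score = 2))
  top2 <- rankByScore(ms, 2L)
  expect_identical(vapply(top2, function(m) m@id, ""), c("m2", "m3"))
  expect_length(rankByScore(ms, 3L), 3L)
  expect_error(rankByScore(ms, 4L), "exceeds")
  msNA <- c(ms, list(mkModel("m4")))
  expect_error(rankByScore(msNA, 2L), "m4")

  set.seed(40)
  ms70 <- lapply(1:70, function(i) mkModel(sprintf("m%02d", i),
                                           score = rnorm(1)))
  top <- rankByScore(ms70, 26L)
  oracle <- vapply(ms70, function(m) m@id, "")[
    order(vapply(ms70, function(m) m@externalScore, 0))][1:26]
  expect_identical(vapply(top, function(m) m@id, ""), oracle)
})

test_that("farthest-point clustering reproduces complete linkage exactly", {
  # identical items merge first
  D <- matrix(c(0, 0, 0.5, 0, 0, 0.5, 0.5, 0.5, 0), 3, 3)
  res <- clusterFarthestPoint(D, 2L)
  expect_equal(res$tree@height[1], 0)
  expect_equal(unname(res$assignment[1]), unname(res$assignment[2]))

  # planted 2+2 blocks are recovered
  D4 <- matrix(0.9, 4, 4)
  D4[1, 2] <- D4[2, 1] <- D4[3, 4] <- D4[4, 3] <- 0.1
  diag(D4) <- 0
  a4 <- clusterFarthestPoint(D4, 2L)$assignment
  expect_equal(unname(a4[1]), unname(a4[2]))
  expect_equal(unname(a4[3]), unname(a4[4]))
  expect_false(a4[1] == a4[3])

  # merge sequence identical to the exhaustive oracle and to hclust
  for (s in 1:5) {
    set.seed(200 + s)
    n <- 6L
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- runif(n * (n - 1) / 2)
    D <- D + t(D)
    res <- clusterFarthestPoint(D)
    bf <- bruteForceCompleteLinkage(D)
    expect_equal(res$tree@height, bf$heights, tolerance = 1e-12)
    hc <- hclust(as.dist(D), method = "complete")
    expect_equal(res$tree@height, hc$height, tolerance = 1e-12)
    for (k in 2:4)
      expect_equal(adjustedRand(cutLinkageTree(res$tree, k),
                                cutree(hc, k)), 1)
  }
  expect_error(clusterFarthestPoint(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
})

test_that("complete-linkage merge heights never decrease", {
  for (s in 1:5) {
    set.seed(300 + s)
    n <- 9L
    D <- as.matrix(dist(matrix(rnorm(n * 2), n, 2)))
    res <- clusterFarthestPoint(D)
    expect_true(all(diff(res$tree@height) >= -1e-12))
  }
})

test_that("medoid selection equals the brute-force row-sum argmin", {
  expect_equal(unname(selectRepresentatives(c(1L, 1L, 1L),
    matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))[1]), 1L)
  # a singleton cluster returns its only member
  D2 <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_equal(unname(selectRepresentatives(c(1L, 2L), D2)), c(1L, 2L))
  # one central item
  Dc <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3, 3)
  expect_equal(unname(selectRepresentatives(rep(1L, 3), Dc)[1]), 1L)
  set.seed(41)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(X))
  med <- selectRepresentatives(rep(1L, 10), D)
  expect_equal(unname(med[1]), unname(which.min(rowSums(D))))
})

test_that("steric-clash screen flags overlapping non-bonded atoms", {
  bp <- generateBeadProtein(c(6L, 6L), seed = 9L)
  expect_false(hasClash(bp$structure))
  xyz <- coords(bp$structure)
  xyz[10, ] <- xyz[1, ] + c(0.5, 0, 0)   # plant a clash
  expect_true(hasClash(setStructureCoords(bp$structure, xyz)))
})

test_that("the screening pipeline recovers planted SS groups", {
  ens <- generateCandidateEnsemble(
    list(nModels = 48L, dDistribution = list(type = "constant", value = 9.9),
         nGroups = 4L, flipNoise = 0.05), seed = 55L)
  out <- screenPipeline(ens$models, ens$scheme, kTop = 48L, nClusters = 4L)
  expect_equal(unname(out$report$counts["representatives"]), 4L)
  expect_true(all(diff(out$report$counts) <= 0))
  asg <- out$report$clusterAssignment
  truth <- ens$groundTruth$groups[match(names(asg),
                                        sprintf("model_%03d",
                                                seq_along(ens$models)))]
  expect_gte(adjustedRand(asg, truth), 0.95)
  # one representative drawn from each planted group
  repGroups <- ens$groundTruth$groups[match(out$report$representativeIds,
                                            sprintf("model_%03d",
                                                    seq_along(ens$models)))]
  expect_length(unique(repGroups), 4L)
})

test_that("the pipeline errors cleanly when no model passes the filter", {
  ens <- generateCandidateEnsemble(
    list(nModels = 10L, dDistribution = list(type = "constant", value = 30)),
    seed = 56L)
  expect_error(screenPipeline(ens$models, ens$scheme), "distance filter")
})

test_that("the pipeline is deterministic and permutation-stable", {
  ens <- generateCandidateEnsemble(list(nModels = 40L), seed = 57L)
  r1 <- screenPipeline(ens$models, ens$scheme, kTop = 20L)
  r2 <- screenPipeline(ens$models, ens$scheme, kTop = 20L)
  expect_identical(serialize(r1$report, NULL), serialize(r2$report, NULL))
})
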