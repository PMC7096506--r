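blobs <- function(k, nPer, sep = 12, dim = 2, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * dim, sd = sep), k, dim)
  X <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(nPer * dim), nPer, dim), 2, centers[i, ], `+`)))
  list(X = X, labels = rep(seq_len(k), each = nPer))
}

test_that("k-means recovers two well-separated blobs perfectly", {
  b <- blobs(2, 60, seed = 50)
  sol <- kmeansClusters(b$X, 2L, seed = 1L)
  expect_equal(adjustedRand(sol@assignment, b$labels), 1)
})

test_that("duplicating every point leaves the centroids unchanged", {
  b <- blobs(3, 30, seed = 51)
  s1 <- kmeansClusters(b$X, 3L, seed = 2L)
  s2 <- kmeansClusters(rbind(b$X, b$X), 3L, seed = 2L)
  o1 <- s1@centroids[order(s1@centroids[, 1]), ]
  o2 <- s2@centroids[order(s2@centroids[, 1]), ]
  expect_equal(o1, o2, tolerance = 1e-8)
})

test_that("k-means at k = 2 attains the exhaustive-partition optimum", {
  for (s in 1:3) {
    set.seed(400 + s)
    X <- matrix(rnorm(24), 12, 2)
    sol <- kmeansClusters(X, 2L, seed = s, nRestarts = 25L)
    expect_equal(sol@inertia, bruteForceBestTwoPartition(X),
                 tolerance = 1e-9)
  }
})

test_that("k >= n and k < 2 are rejected; fixed seeds reproduce", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(kmeansClusters(X, 10L, seed = 1L), "smaller")
  expect_error(kmeansClusters(X, 1L, seed = 1L), "at least 2")
  b <- blobs(3, 20, seed = 52)
  s1 <- kmeansClusters(b$X, 3L, seed = 7L)
  s2 <- kmeansClusters(b$X, 3L, seed = 7L)
  expect_identical(s1@assignment, s2@assignment)
  expect_identical(s1@inertia, s2@inertia)
})

test_that("validity indices behave at their limits and under rigid maps", {
  b <- blobs(2, 40, sep = 40, seed = 53)
  sol <- kmeansClusters(b$X, 2L, seed = 3L)
  expect_lt(sol@daviesBouldin, 0.2)   # tight, far-apart blobs
  # CH peaks at the true k
  b6 <- blobs(6, 30, sep = 25, seed = 54)
  ch <- vapply(5:7, function(k)
    kmeansClusters(b6$X, k, seed = 4L)@calinskiHarabasz, 0)
  expect_gt(ch[2], ch[1])
  expect_gt(ch[2], ch[3])
  # invariance under rotation + translation of the feature space
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  Xr <- sweep(b$X %*% R, 2, c(100, -50), `+`)
  expect_equal(daviesBouldin(Xr, sol@assignment),
               daviesBouldin(b$X, sol@assignment), tolerance = 1e-9)
  expect_equal(calinskiHarabasz(Xr, sol@assignment),
               calinskiHarabasz(b$X, sol@assignment), tolerance = 1e-9)
})

test_that("degenerate duplicate-point clusterings flag CH as infinite", {
  X <- rbind(matrix(1, 3, 2), matrix(5, 3, 2))
  lab <- rep(1:2, each = 3)
  expect_equal(calinskiHarabasz(X, lab), Inf)
  expect_equal(daviesBouldin(X, lab), 0)
})

test_that("chooseK finds six planted conformational clusters", {
  b6 <- blobs(6, 40, sep = 25, seed = 55)
  ck <- chooseK(b6$X, kRange = 2:10, seed = 60L, nRestarts = 10L)
  expect_equal(ck$chosenK, 6L)
  expect_gte(adjustedRand(ck$solution@assignment, b6$labels), 0.95)
  ck2 <- chooseK(b6$X, kRange = 2:10, seed = 60L, nRestarts = 10L)
  expect_identical(ck$solution@assignment, ck2$solution@assignment)
})

test_that("a single Gaussian blob still yields a recorded solution", {
  set.seed(56)
  X <- matrix(rnorm(160), 80, 2)
  ck <- chooseK(X, kRange = 2:5, seed = 61L, nRestarts = 5L)
  expect_true(ck$chosenK %in% 2:5)
  expect_length(ck$chCurve, 4L)
  expect_length(ck$dbCurve, 4L)
  expect_type(ck$conflict, "logical")
})

test_that("RMSD histograms are area-normalized and find planted modes", {
  fx <- beadTrajectoryFixture(nFrames = 60L, seed = 63L)
  # constant trajectory: everything in the first bin
  base <- coords(fx$bp$structure)
  const <- newTrajectory(array(base, c(nrow(base), 3L, 30L)),
                         fx$bp$structure)
  rd <- rmsdDistribution(const, fx$bp$scheme, bins = 100L)
  dens <- rd$all$density
  w <- diff(rd$all$breaks[1:2])
  expect_equal(sum(dens * w), 1, tolerance = 1e-9)
  expect_equal(sum(dens > 0), 1L)

  # two-state trajectory: bimodal at 0 and ~5 A
  tr <- generateTransitionTrajectory(
    fx$bp$structure,
    stateB = coords(fx$bp$structure) +
      kitdyn:::.unflattenCoords(5 * sqrt(nrow(base)) *
        covarianceSpec(nrow(base), 1, seed = 64L,
                       meanCoords = base)$directions[, 1]),
    switchStart = 500L, switchLen = 2L, noiseSigma = 0.05,
    nFrames = 1000L, seed = 65L)
  rd2 <- rmsdDistribution(tr$trajectory, fx$bp$scheme, bins = 1000L)
  expect_equal(sum(rd2$all$density * diff(rd2$all$breaks[1:2])), 1,
               tolerance = 1e-9)
  expect_gte(rd2$all$modes, 2L)
})

test_that("internal-vs-displacement decomposition isolates rigid moves", {
  bp <- generateBeadProtein(c(10L, 10L, 10L), seed = 66L)
  base <- coords(bp$structure)
  kidIdx <- applySelection(caSelection(bp$scheme, "KID"), bp$structure)
  nFr <- 12L
  arr <- array(base, c(30L, 3L, nFr))
  for (f in seq_len(nFr))          # KID translates rigidly, rest fixed
    arr[kidIdx, 1, f] <- base[kidIdx, 1] + 0.3 * (f - 1)
  traj <- newTrajectory(arr, bp$structure)
  dec <- internalVsDisplacement(traj, bp$scheme, "KID")
  expect_lt(max(values(dec$internal)), 1e-8)
  expect_gt(values(dec$all)[nFr], 0.5)
  expect_equal(values(dec$difference), values(dec$all), tolerance = 1e-8)
})

test_that("an internally deforming, non-displacing domain gives A == B", {
  bp <- generateBeadProtein(c(10L, 10L, 10L), seed = 67L)
  base <- coords(bp$structure)
  kidIdx <- applySelection(caSelection(bp$scheme, "KID"), bp$structure)
  nFr <- 10L
  arr <- array(base, c(30L, 3L, nFr))
  set.seed(68)
  for (f in 2:nFr) {
    d <- matrix(rnorm(length(kidIdx) * 3, sd = 0.3), length(kidIdx), 3L)
    d <- sweep(d, 2L, colMeans(d))   # no net displacement
    arr[kidIdx, , f] <- base[kidIdx, ] + d
  }
  traj <- newTrajectory(arr, bp$structure)
  dec <- internalVsDisplacement(traj, bp$scheme, "KID")
  expect_equal(values(dec$all), values(dec$internal), tolerance = 0.15)
  expect_lt(mean(abs(values(dec$difference))), 0.1)
})

test_that("change-point detection matches closed cases and the DP oracle", {
  expect_length(detectTransitions(rep(2.5, 50))@changePoints, 0L)

  set.seed(70)
  y <- c(rnorm(500, 0, 0.3), rnorm(500, 5, 0.3))
  rep1 <- detectTransitions(y)
  expect_length(rep1@changePoints, 1L)
  expect_lt(abs(rep1@changePoints[1] - 500L), 10L)
  expect_equal(rep1@segmentMeans, c(0, 5), tolerance = 0.1)

  for (s in 1:4) {
    set.seed(500 + s)
    y <- c(rnorm(15, 0), rnorm(20, 3), rnorm(15, -2))
    rp <- detectTransitions(y, maxChanges = 2L)
    m <- length(rp@changePoints)
    expect_equal(sseOfSegmentation(y, rp@changePoints),
                 bruteForceSegmentationSSE(y, m), tolerance = 1e-9)
  }
  expect_error(detectTransitions(rnorm(5)), "short")
})

test_that("cluster solutions export medoid frames and indices", {
  b <- blobs(2, 20, seed = 71)
  sol <- kmeansClusters(b$X, 2L, seed = 8L)
  prefix <- tempfile()
  med <- writeClusterSolution(sol, b$X, prefix)
  expect_true(file.exists(paste0(prefix, ".csv")))
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$k, 2L)
  expect_length(med, 2L)
  expect_equal(sol@assignment[med], 1:2)
  unlink(paste0(prefix, c(".csv", ".json")))
})
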