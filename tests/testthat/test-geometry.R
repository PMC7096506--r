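randomRotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

test_that("kabschFit recovers exact superpositions and stays proper", {
  set.seed(11)
  X <- matrix(rnorm(30), 10, 3)
  sp0 <- kabschFit(X, X)
  expect_lt(sp0@rmsd, 1e-12)
  expect_equal(sp0@rotation, diag(3), tolerance = 1e-10)
  for (s in 1:5) {
    R <- randomRotation(s)
    tr <- runif(3, -10, 10)
    sp <- kabschFit(X %*% R + rep(tr, each = 10), X)
    expect_lt(sp@rmsd, 1e-10)
    expect_equal(det(sp@rotation), 1, tolerance = 1e-8)
    expect_lt(max(abs(crossprod(sp@rotation) - diag(3))), 1e-8)
  }
})

test_that("kabschFit is symmetric in RMSD and rejects degenerate input", {
  set.seed(12)
  A <- matrix(rnorm(18), 6, 3)
  B <- A + matrix(rnorm(18, sd = 0.5), 6, 3)
  expect_equal(kabschFit(A, B)@rmsd, kabschFit(B, A)@rmsd,
               tolerance = 1e-10)
  expect_error(kabschFit(A[1:2, ], B[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabschFit(line + 0.0, line), "collinear")
})

test_that("kabschFit matches a rotation-space brute-force search", {
  for (s in 1:3) {
    set.seed(100 + s)
    X <- matrix(rnorm(12), 4, 3)
    Y <- X %*% randomRotation(s) + matrix(rnorm(12, sd = 0.4), 4, 3)
    mine <- kabschFit(Y, X)@rmsd
    oracle <- bruteForceMinRmsd(Y, X, seed = s)
    expect_lt(abs(mine - oracle), 1e-6)
  }
})

test_that("rmsdSeries is zero for constant and rigid-only trajectories", {
  bp <- generateBeadProtein(c(6L, 8L, 6L), seed = 2L)
  base <- coords(bp$structure)
  const <- newTrajectory(array(base, c(nrow(base), 3L, 5L)), bp$structure)
  expect_equal(values(rmsdSeries(const, caSelection())), rep(0, 5),
               tolerance = 1e-10)
  rig <- newTrajectory(rigidTrajectory(base), bp$structure)
  expect_lt(max(values(rmsdSeries(rig, caSelection()))), 1e-8)
})

test_that("rmsdSeries equals the hand-computed value on a toy", {
  # 5 atoms far apart; fit on the 4 that never move, so the fit is the
  # identity and the displaced atom contributes sqrt(delta^2 / N)
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10),
                c(5, 5, 5))
  moved <- base
  moved[5, ] <- moved[5, ] + c(2, 0, 0)
  st <- newStructure(serial = 1:5, atomName = "CA", residueNumber = 1:5,
                     x = base[, 1], y = base[, 2], z = base[, 3])
  arr <- array(c(base, moved), c(5L, 3L, 2L))
  traj <- newTrajectory(arr, st)
  s <- rmsdSeries(traj, fitSelection = atomSelection("CA", 1:4),
                  computeSelection = caSelection())
  expect_equal(values(s)[2], sqrt(4 / 5), tolerance = 1e-10)
})

test_that("rmsf matches closed forms and rejects oversized burn-in", {
  bp <- generateBeadProtein(c(5L, 5L), seed = 3L)
  base <- coords(bp$structure)
  const <- newTrajectory(array(base, c(10L, 3L, 6L)), bp$structure)
  expect_equal(unname(rmsf(const)), rep(0, 10), tolerance = 1e-10)
  expect_error(rmsf(const, burnIn = 6L), "burnIn")

  # one atom oscillating +/- a along x, fit on the static atoms
  a <- 0.8
  arr <- array(base, c(10L, 3L, 40L))
  arr[1, 1, ] <- base[1, 1] + a * rep(c(1, -1), 20)
  osc <- newTrajectory(arr, bp$structure)
  rf <- rmsf(osc, selection = caSelection(),
             fitSelection = atomSelection("CA", 2:10))
  expect_equal(unname(rf[1]), a, tolerance = 1e-10)
  expect_lt(max(rf[-1]), 1e-10)
})

test_that("rmsf recovers planted per-atom fluctuations within 5%", {
  bp <- generateBeadProtein(c(20L, 20L, 20L), seed = 7L)
  cs <- covarianceSpec(60L, c(4, 2, 1), seed = 3L,
                       meanCoords = coords(bp$structure))
  g <- generateGaussianTrajectory(bp$structure, cs, nFrames = 5000L,
                                  seed = 11L)
  rf <- rmsf(g$trajectory)
  truth <- g$groundTruth$perAtomRmsf
  keep <- truth > 0.1  # relative error on near-static atoms is noise
  expect_lt(max(abs(rf[keep] - truth[keep]) / truth[keep]), 0.05)
})

test_that("radius of gyration closed forms, homogeneity and invariance", {
  expect_equal(radiusOfGyration(rbind(c(-1, 0, 0), c(1, 0, 0))), 1)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(radiusOfGyration(sq), sqrt(0.5), tolerance = 1e-12)
  set.seed(8)
  X <- matrix(rnorm(60), 20, 3)
  rg <- radiusOfGyration(X)
  expect_equal(radiusOfGyration(3.7 * X), 3.7 * rg, tolerance = 1e-12)
  expect_equal(radiusOfGyration(sweep(X, 2, c(5, -3, 2), `+`)), rg,
               tolerance = 1e-12)
  expect_error(radiusOfGyration(X, masses = rep(-1, 20)), "mass")
})

test_that("rmsd100 normalization follows the size-independent formula", {
  for (x in c(0.5, 2, 7)) expect_equal(rmsd100(x, 100), x)
  expect_equal(rmsd100(2, 400), 2 / (1 + log(2)), tolerance = 1e-12)
  ns <- seq(100, 1000, by = 50)
  expect_true(all(diff(rmsd100(2, ns)) < 0))
  expect_error(rmsd100(1, 15), ">= 20")
  expect_error(rmsd100(-1, 100), "non-negative")
})

test_that("end-to-end distance d is a rigid invariant Calpha metric", {
  st <- newStructure(serial = 1:2, atomName = "CA", residueNumber = c(689L, 768L),
                     x = c(0, 0), y = c(0, 0), z = c(0, 9.9))
  sc <- newDomainScheme("KID", 700L, 750L, c(689L, 768L))
  expect_equal(endToEndDistance(st, sc), 9.9)
  R <- randomRotation(4)
  st2 <- setStructureCoords(st, coords(st) %*% R + rep(c(3, -2, 7), each = 2))
  expect_equal(endToEndDistance(st2, sc), 9.9, tolerance = 1e-10)
  expect_error(endToEndDistance(st, newDomainScheme("KID", 700L, 750L,
                                                    c(689L, 999L))),
               "999")
})

test_that("endToEndSeries tracks per-frame distances", {
  bp <- generateBeadProtein(c(5L, 10L, 5L), seed = 6L)
  base <- coords(bp$structure)
  arr <- array(base, c(20L, 3L, 3L))
  traj <- newTrajectory(arr, bp$structure)
  d0 <- endToEndDistance(bp$structure, bp$scheme)
  expect_equal(values(endToEndSeries(traj, bp$scheme)), rep(d0, 3),
               tolerance = 1e-10)
})

test_that("metric series export and mean-sd formatting", {
  s <- new("MetricSeries", values = c(12.4, 12.6, 12.8),
           timeNs = c(0, 1, 2), label = "Rg")
  f <- withr::local_tempfile(fileext = ".csv")
  writeMetricSeries(s, f)
  tab <- read.csv(f)
  expect_equal(tab$value, values(s))
  expect_equal(formatMeanSd(s), "12.6 (2)")
})
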