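test_that("a constant trajectory has a zero covariance matrix", {
  bp <- generateBeadProtein(c(8L, 8L), seed = 13L)
  base <- coords(bp$structure)
  const <- newTrajectory(array(base, c(16L, 3L, 10L)), bp$structure)
  ed <- covarianceED(const, fitTarget = "initial")
  expect_lt(max(abs(ed@covariance)), 1e-20)
})

test_that("fitting removes pure rigid-body motion from the covariance", {
  bp <- generateBeadProtein(c(8L, 8L), seed = 14L)
  rig <- newTrajectory(rigidTrajectory(coords(bp$structure), 12L),
                       bp$structure)
  ed <- covarianceED(rig, fitTarget = "average")
  expect_lt(max(abs(ed@covariance)), 1e-10)
})

test_that("planted anisotropic covariance is recovered within 10%", {
  fx <- beadTrajectoryFixture(lambda = c(4, 2, 1), nFrames = 5000L,
                              seed = 7L)
  ed <- covarianceED(fx$traj, fitTarget = "average")
  Ctrue <- fx$spec$directions %*% diag(fx$spec$eigenvalues) %*%
    t(fx$spec$directions)
  relErr <- norm(ed@covariance - Ctrue, "F") / norm(Ctrue, "F")
  expect_lt(relErr, 0.10)
  ed <- pcaED(ed)
  expect_equal(ed@eigenvalues[1:3], fx$spec$eigenvalues, tolerance = 0.10)
  expect_gt(abs(sum(ed@eigenvectors[, 1] * fx$spec$directions[, 1])), 0.99)
})

test_that("eigen-decomposition conserves trace and stays orthonormal", {
  fx <- beadTrajectoryFixture(nFrames = 400L, seed = 23L)
  ed <- pcaED(covarianceED(fx$traj))
  expect_equal(sum(ed@eigenvalues), sum(diag(ed@covariance)),
               tolerance = 1e-6)
  V <- ed@eigenvectors
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  expect_true(all(ed@eigenvalues >= 0))
  expect_true(all(diff(ed@eigenvalues) <= 1e-12))
})

test_that("a hand-computable 2x2 covariance yields closed-form eigenpairs", {
  C <- matrix(c(3, 1, 1, 3), 2, 2)
  ed <- new("EssentialDynamics", covariance = C, eigenvalues = numeric(0),
            eigenvectors = matrix(0, 0, 0),
            meanCoords = matrix(0, 1, 3), atomIndices = 1L)
  ed <- pcaED(ed)
  expect_equal(ed@eigenvalues, c(4, 2))
  expect_equal(abs(ed@eigenvectors[, 1]), rep(1 / sqrt(2), 2),
               tolerance = 1e-12)
})

test_that("cumulative variance is monotone and matches planted spectra", {
  # isotropic: 10 of 30 equal modes carry exactly 1/3
  edIso <- new("EssentialDynamics", covariance = diag(30),
               eigenvalues = numeric(0), eigenvectors = matrix(0, 0, 0),
               meanCoords = matrix(0, 10, 3), atomIndices = 1:10)
  edIso <- pcaED(edIso)
  expect_equal(cumulativeVariance(edIso, 10L), 10 / 30)
  expect_equal(cumulativeVariance(edIso, 30L), 1)

  # planted 1/i^2 spectrum on 20 atoms (3N = 60), sampled at 5000 frames
  lam <- 1 / (1:20)^2
  bp <- generateBeadProtein(c(10L, 10L), seed = 15L)
  cs <- covarianceSpec(20L, lam, seed = 16L,
                       meanCoords = coords(bp$structure))
  g <- generateGaussianTrajectory(bp$structure, cs, nFrames = 5000L,
                                  seed = 17L)
  ed <- pcaED(covarianceED(g$trajectory, fitTarget = "average"))
  cv <- vapply(1:10, function(k) cumulativeVariance(ed, k), 0)
  expect_true(all(diff(cv) >= 0))
  analytic <- cumsum(lam)[1:10] / sum(lam)
  expect_equal(cv, analytic, tolerance = 0.05)
})

test_that("mode displacements honour the amplitude cutoff", {
  # plant a single mode moving only the first 5 atoms
  bp <- generateBeadProtein(c(10L, 10L), seed = 18L)
  v <- numeric(60)
  v[1:15] <- rep(c(1, 0, 0), 5)
  v <- v / sqrt(sum(v^2))
  cs <- covarianceSpec(20L, 4, directions = matrix(v, ncol = 1))
  g <- generateGaussianTrajectory(bp$structure, cs, nFrames = 2000L,
                                  seed = 19L)
  ed <- pcaED(covarianceED(g$trajectory, fitTarget = "average"))
  all0 <- modeDisplacements(ed, 1L, cutoff = 0)
  expect_equal(nrow(all0), 20L)
  none <- modeDisplacements(ed, 1L,
                            cutoff = max(all0$amplitude) + 1)
  expect_equal(nrow(none), 0L)
  # planted amplitude: sqrt(lambda)*|v_atom| ~ 2/sqrt(5) on moving atoms
  moving <- modeDisplacements(ed, 1L, cutoff = 0.5)
  expect_setequal(moving$atom, 1:5)
  expect_error(modeDisplacements(ed, 1L, cutoff = -1), "non-negative")
})

test_that("mode export writes a two-frame PDB around the mean", {
  fx <- beadTrajectoryFixture(nFrames = 200L, seed = 25L)
  ed <- pcaED(covarianceED(fx$traj))
  f <- withr::local_tempfile(fileext = ".pdb")
  exportModePDB(ed, topology(fx$traj), 1L, f)
  t2 <- readMultiModel(f)
  expect_equal(nFrames(t2), 2L)
  mid <- (coords(t2, frame = 1L) + coords(t2, frame = 2L)) / 2
  expect_equal(mid, ed@meanCoords, tolerance = 1e-2)
})

test_that("DCCM has unit diagonal, symmetry and [-1, 1] bounds", {
  fx <- beadTrajectoryFixture(nFrames = 300L, seed = 26L)
  cm <- dccm(fx$traj)
  M <- cm@map
  expect_equal(diag(M), rep(1, nrow(M)))
  expect_equal(M, t(M))
  expect_true(all(M >= -1 & M <= 1))
})

test_that("identical and anti-phase motions hit the correlation limits", {
  # anchors plus two tracked atoms; tiny amplitudes keep the per-frame
  # fit at the identity to first order
  set.seed(27)
  base <- rbind(matrix(rnorm(60, sd = 6), 20, 3),
                c(0, 5, 0), c(0, -5, 0))
  st <- newStructure(serial = 1:22, atomName = "CA", residueNumber = 1:22,
                     x = base[, 1], y = base[, 2], z = base[, 3])
  nFr <- 50L
  amp <- 1e-3 * sin(seq_len(nFr))
  # same-direction pair: both tracked atoms share the displacement
  arrS <- array(base, c(22L, 3L, nFr))
  for (f in seq_len(nFr)) arrS[21:22, 1, f] <- base[21:22, 1] + amp[f]
  cmS <- dccm(newTrajectory(arrS, st), fitTarget = "initial")
  expect_equal(cmS@map[21, 22], 1, tolerance = 1e-4)
  # anti-phase pair
  arrA <- array(base, c(22L, 3L, nFr))
  for (f in seq_len(nFr)) {
    arrA[21, 1, f] <- base[21, 1] + amp[f]
    arrA[22, 1, f] <- base[22, 1] - amp[f]
  }
  cmA <- dccm(newTrajectory(arrA, st), fitTarget = "initial")
  expect_equal(cmA@map[21, 22], -1, tolerance = 1e-4)
})

test_that("zero-fluctuation atoms are flagged and zeroed", {
  # 3 atoms: the first two fluctuate (coupled), the third is frozen
  C <- matrix(0, 9, 9)
  C[1:3, 1:3] <- C[4:6, 4:6] <- diag(3)
  C[1:3, 4:6] <- C[4:6, 1:3] <- 0.5 * diag(3)
  ed <- new("EssentialDynamics", covariance = C, eigenvalues = numeric(0),
            eigenvectors = matrix(0, 0, 0), meanCoords = matrix(0, 3, 3),
            atomIndices = 1:3)
  cm <- dccmFromED(ed)
  expect_identical(cm@flagged, 3L)
  expect_equal(cm@map[3, 1:2], c(0, 0))
  expect_equal(diag(cm@map), rep(1, 3))
  expect_equal(cm@map[1, 2], 0.5)
})

test_that("DCCM matches bio3d's correlation map on fitted frames", {
  fx <- beadTrajectoryFixture(nFrames = 250L, seed = 29L)
  cm <- dccm(fx$traj, fitTarget = "initial")
  ft <- kitdyn:::.fittedFlat(fx$traj, caSelection(), "initial")
  ref <- bio3d::dccm(ft$flat, method = "pearson")
  expect_equal(unname(cm@map), unname(ref[, ]), tolerance = 1e-6)
})

test_that("spectrum export carries eigenvalues and cumulative fractions", {
  fx <- beadTrajectoryFixture(nFrames = 200L, seed = 31L)
  ed <- pcaED(covarianceED(fx$traj))
  f <- withr::local_tempfile(fileext = ".csv")
  writeEigenSpectrum(ed, f, nModes = 5L)
  tab <- read.csv(f)
  expect_equal(tab$eigenvalue, ed@eigenvalues[1:5])
  expect_equal(tab$cumulativeFraction[5],
               cumulativeVariance(ed, 5L), tolerance = 1e-12)
})
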