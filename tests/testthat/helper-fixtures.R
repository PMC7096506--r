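# shared fixtures and independent oracles used across the suite

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

# a rigid-body-motion-only trajectory around a base conformation
rigidTrajectory <- function(base, nFrames = 8L, seed = 99L) {
  set.seed(seed)
  n <- nrow(base)
  arr <- array(NA_real_, c(n, 3L, nFrames))
  arr[, , 1L] <- base
  for (f in 2:nFrames) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 0, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * outer(ax, ax)
    arr[, , f] <- base %*% R + rep(runif(3, -5, 5), each = n)
  }
  arr
}

beadTrajectoryFixture <- function(domainSizes = c(10L, 20L, 10L),
                                  lambda = c(2, 1, 0.5), nFrames = 300L,
                                  seed = 17L) {
  bp <- generateBeadProtein(domainSizes, seed = seed)
  cs <- covarianceSpec(sum(domainSizes), lambda, seed = seed + 1L,
                       meanCoords = coords(bp$structure))
  g <- generateGaussianTrajectory(bp$structure, cs, nFrames, seed = seed + 2L)
  list(bp = bp, spec = cs, traj = g$trajectory, truth = g$groundTruth)
}

# independent brute-force minimum RMSD over rotation space:
# random-quaternion scan followed by Nelder-Mead refinement over Euler
# angles; never calls the Kabsch solver
bruteForceMinRmsd <- function(mobile, reference, nSamples = 20000L,
                              seed = 5L) {
  set.seed(seed)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  quat2rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  objQ <- function(q) sqrt(mean(rowSums((X %*% t(quat2rot(q)) - Y)^2)))
  best <- Inf; bestQ <- c(1, 0, 0, 0)
  for (i in seq_len(nSamples)) {
    q <- rnorm(4)
    v <- objQ(q)
    if (v < best) { best <- v; bestQ <- q }
  }
  opt <- optim(bestQ, objQ, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# exhaustive complete-linkage agglomeration for tiny matrices: at each
# step enumerates every active pair and merges the closest (same
# tie-break as the implementation) while tracking member sets directly
bruteForceCompleteLinkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  sets <- list()
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best - 1e-15) { best <- d; bi <- i; bj <- j }
    }
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    heights <- c(heights, best)
    sets <- c(sets, list(merged))
    clusters[[bi]] <- merged
    clusters[[bj]] <- NULL
  }
  list(heights = heights, sets = sets)
}

# exhaustive best 2-partition by total within-cluster sum of squares
bruteForceBestTwoPartition <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1L) - 1L)) {
    lab <- as.integer(intToBits(code))[1:n]
    if (all(lab == lab[1])) next
    w <- 0
    for (g in 0:1) {
      M <- X[lab == g, , drop = FALSE]
      w <- w + sum(sweep(M, 2, colMeans(M))^2)
    }
    if (w < best) best <- w
  }
  best
}

# exhaustive least-squares segmentation cost for exactly m change points
bruteForceSegmentationSSE <- function(y, m) {
  n <- length(y)
  sse <- function(seg) sum((seg - mean(seg))^2)
  if (m == 0L) return(sse(y))
  best <- Inf
  if (m == 1L) {
    for (c1 in 1:(n - 1L))
      best <- min(best, sse(y[1:c1]) + sse(y[(c1 + 1):n]))
  } else if (m == 2L) {
    for (c1 in 1:(n - 2L)) for (c2 in (c1 + 1L):(n - 1L))
      best <- min(best, sse(y[1:c1]) + sse(y[(c1 + 1):c2]) +
                    sse(y[(c2 + 1):n]))
  } else stop("oracle supports up to 2 changes")
  best
}

sseOfSegmentation <- function(y, changePoints) {
  bounds <- c(0L, changePoints, length(y))
  sum(vapply(seq_len(length(bounds) - 1L), function(s) {
    seg <- y[(bounds[s] + 1L):bounds[s + 1L]]
    sum((seg - mean(seg))^2)
  }, 0))
}
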