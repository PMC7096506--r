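# k-means++ seeding: spread initial centers with probability proportional
# to squared distance from the chosen set
.kmeansppCenters <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in seq_len(k)[-1L]) {
    i <- if (sum(d2) <= 0) sample.int(n, 1L)
         else sample.int(n, 1L, prob = d2)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

#' k-means clustering of trajectory features
#'
#' Lloyd's algorithm (via `stats::kmeans`) with k-means++ seeding, run
#' `nRestarts` times; the solution with the lowest inertia (total
#' within-cluster sum of squares) is kept. Deterministic for a fixed
#' seed. Davies-Bouldin and Calinski-Harabasz validity indices are
#' attached.
#'
#' @param features numeric matrix, observations (frames) x dimensions.
#' @param k number of clusters (>= 2, < number of observations).
#' @param seed RNG seed.
#' @param nRestarts independent restarts (default 10).
#' @return a [ClusterSolution-class].
#' @export
kmeansClusters <- function(features, k, seed, nRestarts = 10L) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (k < 2L) stop("k must be at least 2")
  if (k >= n) stop("k (", k, ") must be smaller than the number of ",
                   "observations (", n, ")")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    km <- tryCatch(
      stats::kmeans(X, centers = .kmeansppCenters(X, k),
                    algorithm = "Lloyd", iter.max = 200L),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(stats::kmeans(X, centers = .kmeansppCenters(X, k),
                                       algorithm = "Lloyd",
                                       iter.max = 500L))
      })
    if (is.null(km) || any(km$size == 0L)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed in all restarts")
  asg <- as.integer(best$cluster)
  new("ClusterSolution", k = as.integer(k), assignment = asg,
      centroids = best$centers, inertia = best$tot.withinss,
      daviesBouldin = daviesBouldin(X, asg),
      calinskiHarabasz = calinskiHarabasz(X, asg),
      seed = as.integer(seed))
}

.clusterStats <- function(X, assignment) {
  ks <- sort(unique(assignment))
  cent <- t(vapply(ks, function(kk)
    colMeans(X[assignment == kk, , drop = FALSE]), numeric(ncol(X))))
  sizes <- vapply(ks, function(kk) sum(assignment == kk), 0L)
  sigma <- vapply(seq_along(ks), function(i) {
    M <- X[assignment == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(M, 2L, cent[i, ])^2)))
  }, 0)
  list(ks = ks, centroids = cent, sizes = sizes, sigma = sigma)
}

#' Davies-Bouldin index (lower is better)
#'
#' Mean over clusters of the worst-case ratio `(sigma_i + sigma_j) /
#' d(c_i, c_j)`, with sigma the mean member-to-centroid distance.
#'
#' @param features observations x dimensions matrix.
#' @param assignment integer cluster labels (>= 2 non-empty clusters).
#' @return a non-negative score.
#' @export
daviesBouldin <- function(features, assignment) {
  X <- as.matrix(features)
  st <- .clusterStats(X, assignment)
  k <- length(st$ks)
  if (k < 2L) stop("need at least 2 clusters")
  dc <- as.matrix(stats::dist(st$centroids))
  r <- vapply(seq_len(k), function(i)
    max(vapply(seq_len(k)[-i], function(j)
      (st$sigma[i] + st$sigma[j]) / dc[i, j], 0)), 0)
  mean(r)
}

#' Calinski-Harabasz index (higher is better)
#'
#' Between- to within-cluster dispersion ratio scaled by
#' `(n - k) / (k - 1)`. Returns `Inf` for a zero-within-dispersion
#' (singletons/duplicates) clustering.
#'
#' @inheritParams daviesBouldin
#' @return a positive score, possibly `Inf`.
#' @export
calinskiHarabasz <- function(features, assignment) {
  X <- as.matrix(features)
  st <- .clusterStats(X, assignment)
  k <- length(st$ks)
  if (k < 2L) stop("need at least 2 clusters")
  n <- nrow(X)
  g <- colMeans(X)
  B <- sum(st$sizes * rowSums(sweep(st$centroids, 2L, g)^2))
  W <- sum(vapply(seq_len(k), function(i) {
    M <- X[assignment == st$ks[i], , drop = FALSE]
    sum(sweep(M, 2L, st$centroids[i, ])^2)
  }, 0))
  if (W <= 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of conformational clusters
#'
#' Runs [kmeansClusters()] for every k in `kRange` and picks the k
#' maximizing the Calinski-Harabasz index. When the Davies-Bouldin
#' minimum points to a different k, the smaller of the two is chosen and
#' the conflict is recorded.
#'
#' @param features observations x dimensions matrix.
#' @param kRange candidate cluster counts (default 2:10).
#' @param seed RNG seed.
#' @param nRestarts restarts per k.
#' @return list with `solution` (the chosen [ClusterSolution-class]),
#'   `chosenK`, `chCurve`, `dbCurve` (named by k), and `conflict`
#'   (logical).
#' @export
chooseK <- function(features, kRange = 2:10, seed, nRestarts = 10L) {
  kRange <- sort(unique(as.integer(kRange)))
  sols <- lapply(kRange, function(k)
    kmeansClusters(features, k, seed = seed + k, nRestarts = nRestarts))
  ch <- vapply(sols, function(s) s@calinskiHarabasz, 0)
  db <- vapply(sols, function(s) s@daviesBouldin, 0)
  names(ch) <- names(db) <- kRange
  kCH <- kRange[which.max(ch)]
  kDB <- kRange[which.min(db)]
  conflict <- kCH != kDB
  chosen <- min(kCH, kDB)
  list(solution = sols[[match(chosen, kRange)]], chosenK = chosen,
       chCurve = ch, dbCurve = db, conflict = conflict)
}

#' Flattened fitted-Calpha feature matrix for conformational clustering
#'
#' Fits every frame onto the first frame over the region's Calpha atoms
#' and returns the flattened coordinates, the Euclidean feature space
#' used for conformational k-means.
#'
#' @param traj a [Trajectory-class].
#' @param selection an [AtomSelection-class] (default all Calpha).
#' @return frames x 3N numeric matrix.
#' @export
conformationFeatures <- function(traj, selection = caSelection()) {
  idx <- applySelection(selection, traj)
  ref <- traj@coords[idx, , 1L]
  X <- matrix(NA_real_, nFrames(traj), 3L * length(idx))
  for (f in seq_len(nFrames(traj))) {
    sp <- kabschFit(traj@coords[idx, , f], ref)
    X[f, ] <- .flattenCoords(applySuperposition(traj@coords[idx, , f], sp))
  }
  X
}

#' Normalized RMSD histograms per region
#'
#' For each region, the Calpha RMSD series with respect to the first
#' conformation is binned into `bins` equal-width bins over
#' `[0, 1.05 * max]` and area-normalized; a simple prominence rule
#' reports the number of modes (conformational sub-states) per region.
#'
#' @param traj a [Trajectory-class].
#' @param scheme a [DomainScheme-class].
#' @param regions character vector of domain/range names (NULL = whole
#'   chain).
#' @param referenceFrame reference conformation (default 1).
#' @param bins histogram bin count (default 1000).
#' @param prominence fraction of the maximum density a local maximum
#'   must rise above its surrounding minima to count as a mode.
#' @return named list per region: `series`, `breaks`, `density`,
#'   `modes`.
#' @export
rmsdDistribution <- function(traj, scheme, regions = NULL,
                             referenceFrame = 1L, bins = 1000L,
                             prominence = 0.1) {
  if (is.null(regions)) regions <- list(all = NULL)
  else regions <- stats::setNames(as.list(regions), regions)
  lapply(regions, function(rg) {
    sel <- if (is.null(rg)) caSelection() else caSelection(scheme, rg)
    s <- rmsdSeries(traj, sel, referenceFrame = referenceFrame,
                    label = if (is.null(rg)) "all" else rg)
    v <- s@values
    upper <- max(v) * 1.05
    if (upper <= 0) upper <- 1e-6
    breaks <- seq(0, upper, length.out = bins + 1L)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    list(series = s, breaks = breaks, density = h$density,
         modes = .countModes(h$density, prominence))
  })
}

# local maxima of a (lightly smoothed) density with a prominence floor
.countModes <- function(dens, prominence = 0.1) {
  w <- max(3L, 2L * (length(dens) %/% 100L) + 1L)
  sm <- stats::filter(dens, rep(1 / w, w), sides = 2L)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  n <- length(sm)
  thr <- prominence * max(sm)
  peaks <- 0L
  for (i in 2:(n - 1L)) {
    if (sm[i] > sm[i - 1L] && sm[i] >= sm[i + 1L]) {
      leftMin <- min(sm[1:i])
      rightMin <- min(sm[i:n])
      if (sm[i] - max(leftMin, rightMin) >= thr &&
          sm[i] - min(leftMin, rightMin) >= thr)
        peaks <- peaks + 1L
    }
  }
  max(peaks, if (max(sm) > 0) 1L else 0L)
}

#' Internal versus displacement RMSD decomposition for a domain
#'
#' Series A ("all displacements") is the domain RMSD after fitting the
#' whole protein; series B ("internal components") the domain RMSD after
#' fitting the domain itself; series C = A - B per frame, the part of
#' the domain's RMSD due to its displacement relative to the rest. C can
#' be negative on individual frames.
#'
#' @param traj a [Trajectory-class].
#' @param scheme a [DomainScheme-class].
#' @param domain domain/range name.
#' @return list of three [MetricSeries-class]: `all`, `internal`,
#'   `difference`.
#' @export
internalVsDisplacement <- function(traj, scheme, domain) {
  domSel <- caSelection(scheme, domain)
  A <- rmsdSeries(traj, caSelection(), domSel, label = "all displacements")
  B <- rmsdSeries(traj, domSel, domSel, label = "internal components")
  C <- new("MetricSeries", values = A@values - B@values, timeNs = A@timeNs,
           label = "difference")
  list(all = A, internal = B, difference = C)
}

.segmentCost <- function(S1, S2, i, j) {
  len <- j - i + 1L
  (S2[j + 1L] - S2[i]) - (S1[j + 1L] - S1[i])^2 / len
}

#' Change-point detection on a metric series
#'
#' Least-squares piecewise-constant segmentation: for every number of
#' changes m up to `maxChanges` the optimal partition is found by
#' dynamic programming, and m is chosen by a BIC-style penalized cost
#' `n log(SSE/n) + penalty * m * log(n)`.
#'
#' @param series a [MetricSeries-class] or numeric vector (length >= 10).
#' @param maxChanges maximum number of change points (default 5).
#' @param penalty per-change penalty multiplier on `log(n)` (default 3).
#' @return a [TransitionReport-class]; change point i means a new
#'   segment starts at frame i + 1.
#' @export
detectTransitions <- function(series, maxChanges = 5L, penalty = 3) {
  y <- if (is(series, "MetricSeries")) series@values else as.numeric(series)
  n <- length(y)
  if (n < 10L) stop("series too short (need >= 10 points)")
  maxChanges <- min(maxChanges, n - 1L)
  S1 <- c(0, cumsum(y))
  S2 <- c(0, cumsum(y^2))
  nSeg <- maxChanges + 1L
  E <- matrix(Inf, nSeg, n)     # E[m, j]: best cost, m segments over 1..j
  P <- matrix(0L, nSeg, n)      # backpointer: end of previous segment
  E[1L, ] <- vapply(seq_len(n), function(j) .segmentCost(S1, S2, 1L, j), 0)
  for (m in seq_len(nSeg)[-1L]) {
    for (j in seq.int(m, n)) {
      t <- seq.int(m - 1L, j - 1L)
      cost <- (S2[j + 1L] - S2[t + 1L]) -
        (S1[j + 1L] - S1[t + 1L])^2 / (j - t)
      tot <- E[m - 1L, t] + cost
      b <- which.min(tot)
      E[m, j] <- tot[b]
      P[m, j] <- t[b]
    }
  }
  sse <- E[, n]
  eps <- 1e-12 * max(1, S2[n + 1L])
  crit <- n * log(pmax(sse, eps) / n) +
    penalty * (seq_len(nSeg) - 1L) * log(n)
  mBest <- which.min(crit)
  cp <- integer(0)
  j <- n
  if (mBest >= 2L) for (m in seq.int(mBest, 2L)) {
    j <- P[m, j]
    cp <- c(j, cp)
  }
  bounds <- c(0L, cp, n)
  sm <- ss <- numeric(length(bounds) - 1L)
  for (s in seq_along(sm)) {
    seg <- y[(bounds[s] + 1L):bounds[s + 1L]]
    sm[s] <- mean(seg)
    ss[s] <- if (length(seg) > 1L) stats::sd(seg) else 0
  }
  new("TransitionReport", changePoints = as.integer(cp),
      segmentMeans = sm, segmentSds = ss)
}

#' Export a clustering solution (CSV + JSON summary)
#'
#' Writes per-frame assignments as CSV and a JSON summary with k, the
#' validity indices and each cluster's medoid frame.
#'
#' @param solution a [ClusterSolution-class].
#' @param features the feature matrix the solution was computed on.
#' @param prefix output path prefix (writes `<prefix>.csv` and
#'   `<prefix>.json`).
#' @return invisibly, the medoid frame indices per cluster.
#' @export
writeClusterSolution <- function(solution, features, prefix) {
  utils::write.csv(data.frame(frame = seq_along(solution@assignment),
                              cluster = solution@assignment),
                   paste0(prefix, ".csv"), row.names = FALSE)
  X <- as.matrix(features)
  med <- vapply(seq_len(solution@k), function(kk) {
    members <- which(solution@assignment == kk)
    D <- as.matrix(stats::dist(X[members, , drop = FALSE]))
    members[which.min(rowSums(D))]
  }, 0L)
  jsonlite::write_json(list(k = solution@k, inertia = solution@inertia,
                            daviesBouldin = solution@daviesBouldin,
                            calinskiHarabasz = solution@calinskiHarabasz,
                            seed = solution@seed,
                            medoidFrames = med),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(med)
}
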