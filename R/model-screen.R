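#' Compute end-to-end distances for a candidate ensemble
#'
#' Fills the `d` slot of every model from its coordinates and the
#' scheme's reference pair.
#'
#' @param models list of [CandidateModel-class].
#' @param scheme a [DomainScheme-class].
#' @return the list with `d` populated.
#' @export
computeEnsembleDistances <- function(models, scheme) {
  lapply(models, function(m) {
    m@d <- endToEndDistance(m@structure, scheme)
    m
  })
}

#' Filter candidate models on the end-to-end distance d
#'
#' Keeps models whose d lies within `target +/- tol` (bounds inclusive),
#' preserving input order. Defaults reproduce the screening condition
#' 9.9 +/- 1.0 A observed in the autoinhibited KIT template.
#'
#' @param models list of [CandidateModel-class] with `d` computed.
#' @param target target distance, Angstrom.
#' @param tol tolerance, Angstrom (>= 0).
#' @return the kept sub-list.
#' @export
distanceFilter <- function(models, target = 9.9, tol = 1.0) {
  stopifnot(tol >= 0)
  d <- vapply(models, function(m) m@d, 0)
  if (any(is.na(d)))
    stop("models without computed d: ",
         paste(vapply(models[is.na(d)], function(m) m@id, ""),
               collapse = ", "))
  models[abs(d - target) <= tol]
}

#' Keep the k best-scoring models
#'
#' "Best" means lowest external score (energy-like, e.g. DOPE). Ties are
#' broken deterministically by model id.
#'
#' @param models list of [CandidateModel-class] carrying `externalScore`.
#' @param k number of models to keep (k <= length(models)).
#' @return the k best models, best first.
#' @export
rankByScore <- function(models, k) {
  sc <- vapply(models, function(m) m@externalScore, 0)
  if (any(is.na(sc)))
    stop("models without external score: ",
         paste(vapply(models[is.na(sc)], function(m) m@id, ""),
               collapse = ", "))
  if (k > length(models)) stop("k exceeds the number of models")
  ids <- vapply(models, function(m) m@id, "")
  models[order(sc, ids)][seq_len(k)]
}

#' Steric-clash screen
#'
#' Flags a structure when any pair of non-bonded atoms (non-consecutive
#' in chain order) sits closer than `cutoff` — an automatic,
#' reproducible proxy for the visual elimination of models with
#' intramolecular "nodes".
#'
#' @param structure a [ProteinStructure-class].
#' @param cutoff minimum allowed non-bonded distance, Angstrom.
#' @return TRUE when a clash is present.
#' @export
hasClash <- function(structure, cutoff = 1.5) {
  xyz <- coords(structure)
  n <- nrow(xyz)
  if (n < 3L) return(FALSE)
  D <- as.matrix(stats::dist(xyz))
  D[abs(row(D) - col(D)) <= 1L] <- Inf
  min(D) < cutoff
}

#' Farthest-point (complete-linkage) hierarchical clustering
#'
#' Agglomerative clustering under the farthest-point rule: the distance
#' between two clusters u, v is `max(dist(u[i], v[j]))` over all member
#' pairs. Returns the merge tree and, when `nClusters` is given, the flat
#' assignment from cutting it. Ties in the minimum inter-cluster distance
#' are broken by the smallest involved indices, making the merge order
#' deterministic.
#'
#' @param distanceMatrix symmetric matrix with zero diagonal.
#' @param nClusters optional number of flat clusters to cut.
#' @return list with `tree` ([LinkageTree-class]) and `assignment`
#'   (integer vector, or NULL when `nClusters` is missing).
#' @export
clusterFarthestPoint <- function(distanceMatrix, nClusters = NULL) {
  D <- as.matrix(distanceMatrix)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (max(abs(diag(D))) > 1e-12) stop("distance matrix diagonal must be 0")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  id <- -seq_len(n)          # hclust convention: leaves negative
  active <- seq_len(n)
  cd <- D
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_); bd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      d <- cd[active[ii], active[jj]]
      if (d < bd - 1e-15) { bd <- d; best <- c(active[ii], active[jj]) }
    }
    i <- best[1]; j <- best[2]
    pair <- sort(c(id[i], id[j]))
    merge[step, ] <- pair
    height[step] <- bd
    # complete linkage update on row i; retire j
    for (k in active) if (k != i && k != j)
      cd[i, k] <- cd[k, i] <- max(cd[i, k], cd[j, k])
    id[i] <- step
    active <- setdiff(active, j)
  }
  tree <- new("LinkageTree", merge = merge, height = height,
              labels = labels)
  assignment <- if (!is.null(nClusters)) cutLinkageTree(tree, nClusters)
  list(tree = tree, assignment = assignment)
}

#' Cut a linkage tree into k flat clusters
#'
#' @param tree a [LinkageTree-class].
#' @param k number of clusters.
#' @return integer assignment named by the tree labels.
#' @export
cutLinkageTree <- function(tree, k) {
  h <- list(merge = tree@merge, height = tree@height,
            order = seq_along(tree@labels), labels = tree@labels,
            method = "complete")
  class(h) <- "hclust"
  stats::cutree(h, k = k)
}

#' Medoid representative of each cluster
#'
#' For every cluster, returns the member with minimal summed distance to
#' all other members; ties are broken by label order.
#'
#' @param assignment integer cluster labels.
#' @param distanceMatrix the full pairwise distance matrix.
#' @return integer vector of medoid indices, one per cluster (named by
#'   cluster).
#' @export
selectRepresentatives <- function(assignment, distanceMatrix) {
  D <- as.matrix(distanceMatrix)
  ks <- sort(unique(assignment))
  out <- vapply(ks, function(k) {
    members <- which(assignment == k)
    sums <- rowSums(D[members, members, drop = FALSE])
    members[which.min(sums)]   # which.min takes the first = smallest index
  }, 0L)
  names(out) <- ks
  out
}

#' The full model-screening pipeline
#'
#' Composes the screening stages that reduce a large generated ensemble
#' to a handful of distinct candidates: end-to-end distance computation,
#' distance filtering around the crystallographic value, a steric-clash
#' screen, ranking on the external model-quality score, clustering of the
#' survivors by secondary-structure similarity under farthest-point
#' linkage, and medoid representative selection.
#'
#' @param models list of [CandidateModel-class] (with `ss` strings).
#' @param scheme a [DomainScheme-class].
#' @param targetD,tol distance-filter window (default 9.9 +/- 1.0 A).
#' @param kTop number of best-scoring models kept (default 26).
#' @param nClusters number of representative clusters (default 4).
#' @param clashCutoff steric-clash distance, Angstrom.
#' @return list with `representatives` (list of models), `report` (stage
#'   counts, kept ids, cluster membership, parameters).
#' @export
screenPipeline <- function(models, scheme, targetD = 9.9, tol = 1.0,
                           kTop = 26L, nClusters = 4L, clashCutoff = 1.5) {
  nIn <- length(models)
  if (nIn == 0L) stop("empty model set at stage: input")
  models <- computeEnsembleDistances(models, scheme)
  kept <- distanceFilter(models, targetD, tol)
  if (length(kept) == 0L)
    stop("empty model set at stage: distance filter (no model within ",
         targetD, " +/- ", tol, " A)")
  nDist <- length(kept)
  kept <- kept[!vapply(kept, function(m) hasClash(m@structure, clashCutoff),
                       TRUE)]
  if (length(kept) == 0L) stop("empty model set at stage: clash screen")
  nClash <- length(kept)
  kept <- rankByScore(kept, min(kTop, length(kept)))
  nScore <- length(kept)
  ss <- vapply(kept, function(m) m@ss, "")
  if (any(!nzchar(ss))) stop("models without SS strings at stage: clustering")
  Dss <- ssSimilarityMatrix(ss)
  rownames(Dss) <- colnames(Dss) <- vapply(kept, function(m) m@id, "")
  nCl <- min(nClusters, length(kept))
  cl <- clusterFarthestPoint(Dss, nCl)
  reps <- selectRepresentatives(cl$assignment, Dss)
  report <- list(
    counts = c(input = nIn, distance = nDist, clash = nClash,
               score = nScore, representatives = length(reps)),
    parameters = list(targetD = targetD, tol = tol, kTop = kTop,
                      nClusters = nClusters, clashCutoff = clashCutoff),
    keptIds = vapply(kept, function(m) m@id, ""),
    clusterAssignment = stats::setNames(cl$assignment,
                                        vapply(kept, function(m) m@id, "")),
    representativeIds = vapply(kept[reps], function(m) m@id, ""))
  list(representatives = kept[reps], report = report, tree = cl$tree)
}

#' Write a screening report as JSON
#'
#' @param report the `report` element of a [screenPipeline()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeScreenReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
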