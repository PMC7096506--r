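#' @import methods
NULL

SS_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "C")

#' Protein structure container
#'
#' An atom-level representation of a protein structure parsed from a PDB
#' file or built synthetically. The `atoms` slot is a data.frame with one
#' row per atom and columns `serial`, `atomName`, `residueName`, `chainId`,
#' `residueNumber`, `insert`, `x`, `y`, `z`, `occupancy`, `bFactor`
#' (coordinates in Angstrom).
#'
#' @slot atoms data.frame of per-atom records.
#' @export
setClass("ProteinStructure", representation(atoms = "data.frame"))

.validProteinStructure <- function(object) {
  a <- object@atoms
  need <- c("serial", "atomName", "residueName", "chainId", "residueNumber",
            "insert", "x", "y", "z", "occupancy", "bFactor")
  if (!all(need %in% names(a)))
    return(paste("atoms is missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) > 0L && !all(is.finite(c(a$x, a$y, a$z))))
    return("non-finite coordinates")
  TRUE
}
setValidity("ProteinStructure", .validProteinStructure)

#' Trajectory container
#'
#' An ordered set of conformations over a fixed atom set. Coordinates are
#' stored as an `nAtoms x 3 x nFrames` array; `topology` carries atom
#' metadata shared by all frames; `timeStep` is the time between recorded
#' frames in nanoseconds.
#'
#' @slot coords numeric array, `nAtoms x 3 x nFrames`.
#' @slot topology a [ProteinStructure-class].
#' @slot timeStep numeric, ns per frame (> 0).
#' @export
setClass("Trajectory",
         representation(coords = "array", topology = "ProteinStructure",
                        timeStep = "numeric"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an nAtoms x 3 x nFrames array")
  if (d[1] != nrow(object@topology@atoms))
    return("frame atom count differs from topology atom count")
  if (length(object@timeStep) != 1L || !is.finite(object@timeStep) ||
      object@timeStep <= 0)
    return("timeStep must be a single positive number")
  if (!all(is.finite(object@coords))) return("non-finite frame coordinates")
  TRUE
})

#' Named residue-range scheme for a multi-domain protein
#'
#' Domains are contiguous residue ranges that must not overlap; additional
#' `analysisRanges` (for example an elongated KID, or the kinase domain as
#' N-lobe + C-lobe) may overlap the domains and each other. `referencePair`
#' holds the two residue numbers whose Calpha-Calpha separation defines the
#' end-to-end distance d.
#'
#' @slot domains data.frame with columns `name`, `first`, `last`.
#' @slot analysisRanges data.frame with the same columns; may overlap.
#' @slot referencePair integer vector of length 2.
#' @slot notes character, free-text flags (e.g. boundary inconsistencies).
#' @export
setClass("DomainScheme",
         representation(domains = "data.frame", analysisRanges = "data.frame",
                        referencePair = "integer", notes = "character"))

setValidity("DomainScheme", function(object) {
  d <- object@domains
  if (!all(c("name", "first", "last") %in% names(d)))
    return("domains needs columns name, first, last")
  if (nrow(d) > 0L) {
    if (any(d$first > d$last)) return("domain with first > last")
    o <- order(d$first)
    if (nrow(d) > 1L && any(d$first[o][-1] <= d$last[o][-nrow(d)]))
      return("overlapping domain ranges")
  }
  if (length(object@referencePair) != 2L)
    return("referencePair must have length 2")
  TRUE
})

#' Atom selection predicate
#'
#' Selects atoms by name and/or residue-number restriction. Empty
#' `atomNames` or `residues` means no restriction on that attribute.
#' Apply with [applySelection()], which returns stable integer indices.
#'
#' @slot atomNames character vector of PDB atom names (e.g. `"CA"`).
#' @slot residues integer vector of residue numbers.
#' @export
setClass("AtomSelection",
         representation(atomNames = "character", residues = "integer"))

#' Per-frame scalar metric series
#'
#' @slot values numeric, one scalar per frame.
#' @slot timeNs numeric, frame times in ns (same length as `values`).
#' @slot label character.
#' @export
setClass("MetricSeries",
         representation(values = "numeric", timeNs = "numeric",
                        label = "character"))

setValidity("MetricSeries", function(object) {
  if (length(object@values) != length(object@timeNs))
    return("values and timeNs lengths differ")
  TRUE
})

#' Rigid-body superposition result
#'
#' Least-squares optimal proper rotation and translation mapping a mobile
#' coordinate set onto a reference: `fitted = mobile %*% rotation +
#' translation` (row-vector convention).
#'
#' @slot rotation 3x3 proper orthogonal matrix.
#' @slot translation numeric length 3, Angstrom.
#' @slot rmsd numeric, post-fit RMSD in Angstrom.
#' @export
setClass("Superposition",
         representation(rotation = "matrix", translation = "numeric",
                        rmsd = "numeric"))

setValidity("Superposition", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation columns not orthonormal")
  if (abs(det(R) - 1) > 1e-8) return("rotation is not proper (det != +1)")
  if (object@rmsd < 0) return("negative rmsd")
  TRUE
})

#' Secondary-structure timeline
#'
#' A residues x sampled-frames character matrix over the 8-letter
#' alphabet H/G/I/E/B/T/S/C, with the sampling stride in picoseconds.
#'
#' @slot symbols character matrix, rows = residues, columns = frames.
#' @slot stridePs numeric, sampling stride in ps (> 0).
#' @slot residueNumbers integer, residue number per row.
#' @export
setClass("SSTimeline",
         representation(symbols = "matrix", stridePs = "numeric",
                        residueNumbers = "integer"))

setValidity("SSTimeline", function(object) {
  if (!all(object@symbols %in% SS_ALPHABET))
    return("symbols outside the H/G/I/E/B/T/S/C alphabet")
  if (object@stridePs <= 0) return("stridePs must be positive")
  if (length(object@residueNumbers) != nrow(object@symbols))
    return("residueNumbers length differs from row count")
  TRUE
})

#' Essential dynamics (covariance/PCA) result
#'
#' Holds the 3N x 3N positional covariance matrix of the selected atoms
#' (Angstrom^2), its eigen-decomposition C = V Lambda V^T (eigenvalues
#' descending, eigenvectors orthonormal columns) and the mean (fit
#' reference) coordinates.
#'
#' @slot covariance 3N x 3N numeric matrix.
#' @slot eigenvalues numeric, descending; empty until [pcaED()] is run.
#' @slot eigenvectors numeric matrix of orthonormal columns.
#' @slot meanCoords N x 3 matrix of reference coordinates.
#' @slot atomIndices integer, topology indices of the selected atoms.
#' @export
setClass("EssentialDynamics",
         representation(covariance = "matrix", eigenvalues = "numeric",
                        eigenvectors = "matrix", meanCoords = "matrix",
                        atomIndices = "integer"))

setValidity("EssentialDynamics", function(object) {
  C <- object@covariance
  if (nrow(C) != ncol(C)) return("covariance not square")
  if (nrow(C) > 0L && max(abs(C - t(C))) > 1e-6 * (1 + max(abs(C))))
    return("covariance not symmetric")
  if (length(object@eigenvalues) > 1L &&
      any(diff(object@eigenvalues) > 1e-8))
    return("eigenvalues not in descending order")
  TRUE
})

#' Dynamic cross-correlation map
#'
#' @slot map N x N numeric matrix in [-1, 1] with unit diagonal.
#' @slot flagged integer indices of zero-fluctuation atoms whose rows were
#'   zeroed off-diagonal.
#' @export
setClass("CrossCorrelationMap",
         representation(map = "matrix", flagged = "integer"))

setValidity("CrossCorrelationMap", function(object) {
  m <- object@map
  if (nrow(m) != ncol(m)) return("map not square")
  if (max(abs(m - t(m))) > 1e-8) return("map not symmetric")
  if (any(m > 1 + 1e-8) || any(m < -1 - 1e-8)) return("entries outside [-1,1]")
  if (max(abs(diag(m) - 1)) > 1e-8) return("diagonal not 1")
  TRUE
})

#' Agglomerative linkage tree (farthest-point / complete linkage)
#'
#' Merge list in the `stats::hclust` convention: row i of `merge` gives the
#' two clusters joined at step i (negative = leaf index, positive = earlier
#' merge), `height` the merge distance.
#'
#' @slot merge integer matrix, (n-1) x 2.
#' @slot height numeric, non-decreasing merge distances.
#' @slot labels character leaf labels.
#' @export
setClass("LinkageTree",
         representation(merge = "matrix", height = "numeric",
                        labels = "character"))

setValidity("LinkageTree", function(object) {
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1L) return("merge must have n-1 rows")
  if (length(object@height) != n - 1L) return("height must have n-1 entries")
  if (n > 2L && any(diff(object@height) < -1e-8))
    return("complete-linkage merge heights must be non-decreasing")
  TRUE
})

#' k-means clustering solution with validity indices
#'
#' @slot k integer number of clusters.
#' @slot assignment integer per-observation cluster labels in 1..k.
#' @slot centroids k x p numeric matrix.
#' @slot inertia numeric total within-cluster sum of squares.
#' @slot daviesBouldin numeric (lower is better).
#' @slot calinskiHarabasz numeric (higher is better).
#' @slot seed integer RNG seed used.
#' @export
setClass("ClusterSolution",
         representation(k = "integer", assignment = "integer",
                        centroids = "matrix", inertia = "numeric",
                        daviesBouldin = "numeric",
                        calinskiHarabasz = "numeric", seed = "integer"))

setValidity("ClusterSolution", function(object) {
  if (any(object@assignment < 1L | object@assignment > object@k))
    return("assignment outside 1..k")
  if (length(unique(object@assignment)) != object@k)
    return("empty cluster in assignment")
  TRUE
})

#' Change-point segmentation report
#'
#' @slot changePoints integer indices i such that a new segment starts at
#'   i + 1; strictly increasing, interior to the series.
#' @slot segmentMeans numeric, one per segment.
#' @slot segmentSds numeric, one per segment.
#' @export
setClass("TransitionReport",
         representation(changePoints = "integer", segmentMeans = "numeric",
                        segmentSds = "numeric"))

setValidity("TransitionReport", function(object) {
  cp <- object@changePoints
  if (length(cp) > 1L && any(diff(cp) <= 0L))
    return("change points must be strictly increasing")
  if (length(object@segmentMeans) != length(cp) + 1L)
    return("need one segment mean per segment")
  TRUE
})

#' Candidate structural model
#'
#' A model entering the screening pipeline: coordinates, the end-to-end
#' distance d between the scheme's reference residues, an optional external
#' model-quality score (lower = better energy, e.g. a DOPE-like statistical
#' potential supplied from outside), and its secondary-structure string.
#'
#' @slot structure a [ProteinStructure-class].
#' @slot d numeric end-to-end distance, Angstrom (NA until computed).
#' @slot externalScore numeric (NA when absent).
#' @slot ss character secondary-structure string (may be empty).
#' @slot id character model identifier.
#' @export
setClass("CandidateModel",
         representation(structure = "ProteinStructure", d = "numeric",
                        externalScore = "numeric", ss = "character",
                        id = "character"))

#' Per-candidate trajectory metric report
#'
#' @slot id character candidate identifier.
#' @slot domainRmsdMean named numeric, per-domain production-window RMSD
#'   mean (Angstrom).
#' @slot domainRmsdSd named numeric.
#' @slot domainRmsfMean named numeric, per-domain mean RMSF (Angstrom).
#' @slot dMean,dSd,dDev numeric: mean/sd of the end-to-end distance and
#'   |dMean - dRef|.
#' @slot rgMean,rgSd numeric: KID radius-of-gyration mean/sd.
#' @slot ssConservation numeric in [0,1] (NA when no reference SS).
#' @slot plateau named logical, RMSD plateau flag per domain.
#' @export
setClass("CandidateReport",
         representation(id = "character",
                        domainRmsdMean = "numeric", domainRmsdSd = "numeric",
                        domainRmsfMean = "numeric",
                        dMean = "numeric", dSd = "numeric", dDev = "numeric",
                        rgMean = "numeric", rgSd = "numeric",
                        ssConservation = "numeric", plateau = "logical"))

#' Consensus ranking of candidate models
#'
#' @slot ranking character, candidate ids best-first.
#' @slot rankTable data.frame of per-metric ranks (rows = candidates).
#' @slot scores named numeric rank sums (lower = better).
#' @slot notes character conflict/tie annotations.
#' @export
setClass("ConsensusRanking",
         representation(ranking = "character", rankTable = "data.frame",
                        scores = "numeric", notes = "character"))
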