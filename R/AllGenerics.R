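#' @include AllClasses.R
NULL

#' Accessors for kitdyn S4 containers
#'
#' Small generic accessors used throughout the package instead of direct
#' slot access: `atoms()` (per-atom data.frame), `coords()` (N x 3 matrix,
#' or a frame of a trajectory), `nAtoms()`, `nFrames()`, `timeStep()`,
#' `domains()`, `referencePair()`, `values()`, `timesNs()`.
#'
#' @param x a kitdyn object.
#' @param ... further arguments for methods (e.g. `frame` for
#'   `coords()` on a [Trajectory-class]).
#' @return The slot contents (data.frame, matrix or vector) as documented
#'   per method.
#' @name accessors
#' @examples
#' s <- generateBeadProtein(c(5, 5), seed = 1)$structure
#' nAtoms(s)
#' head(atoms(s))
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setMethod("atoms", "ProteinStructure", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))
#' @rdname accessors
#' @export
setMethod("coords", "ProteinStructure", function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
})
#' @rdname accessors
#' @param frame integer frame index (Trajectory method).
#' @export
setMethod("coords", "Trajectory", function(x, frame = 1L) {
  x@coords[, , frame, drop = TRUE]
})

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setMethod("nAtoms", "ProteinStructure", function(x) nrow(x@atoms))
#' @rdname accessors
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @rdname accessors
#' @export
setGeneric("timeStep", function(x) standardGeneric("timeStep"))
#' @rdname accessors
#' @export
setMethod("timeStep", "Trajectory", function(x) x@timeStep)

#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname accessors
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' @rdname accessors
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))
#' @rdname accessors
#' @export
setMethod("domains", "DomainScheme", function(x) x@domains)

#' @rdname accessors
#' @export
setGeneric("analysisRanges", function(x) standardGeneric("analysisRanges"))
#' @rdname accessors
#' @export
setMethod("analysisRanges", "DomainScheme", function(x) x@analysisRanges)

#' @rdname accessors
#' @export
setGeneric("referencePair", function(x) standardGeneric("referencePair"))
#' @rdname accessors
#' @export
setMethod("referencePair", "DomainScheme", function(x) x@referencePair)

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setMethod("values", "MetricSeries", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("timesNs", function(x) standardGeneric("timesNs"))
#' @rdname accessors
#' @export
setMethod("timesNs", "MetricSeries", function(x) x@timeNs)

#' Mean and standard deviation of a metric series
#'
#' @param x a [MetricSeries-class].
#' @return a single number.
#' @export
seriesMean <- function(x) mean(x@values)

#' @rdname seriesMean
#' @export
seriesSd <- function(x) stats::sd(x@values)

#' Format a series as "mean (sd-digit)" in the style of MD reports
#'
#' Rounds the mean to one decimal and prints the standard deviation as a
#' single parenthetical digit, e.g. `"12.6 (2)"` for mean 12.64, sd 0.21.
#'
#' @param x a [MetricSeries-class].
#' @return character scalar.
#' @export
formatMeanSd <- function(x) {
  m <- seriesMean(x)
  s <- seriesSd(x)
  sprintf("%.1f (%d)", m, as.integer(round(s * 10)))
}

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  cat("ProteinStructure:", nrow(a), "atoms,",
      length(unique(paste(a$chainId, a$residueNumber, a$insert))),
      "residues,", length(unique(a$chainId)), "chain(s)\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nFrames(object), "frames x", nAtoms(object),
      "atoms, timeStep", object@timeStep, "ns\n")
})

setMethod("show", "DomainScheme", function(object) {
  cat("DomainScheme with", nrow(object@domains), "domains\n")
  if (nrow(object@domains)) {
    apply(object@domains, 1L, function(r)
      cat(sprintf("  %-12s %s-%s\n", r[["name"]], r[["first"]], r[["last"]])))
  }
  cat("  reference pair:", paste(object@referencePair, collapse = "-"), "\n")
  if (length(object@notes) && nzchar(object@notes[1]))
    cat("  notes:", object@notes, "\n")
})

setMethod("show", "MetricSeries", function(object) {
  cat(sprintf("MetricSeries '%s': %d frames, mean %.3f, sd %.3f\n",
              object@label, length(object@values),
              mean(object@values), stats::sd(object@values)))
})

setMethod("show", "EssentialDynamics", function(object) {
  n <- nrow(object@covariance)
  cat("EssentialDynamics:", n, "coordinates (", n / 3L, "atoms )\n")
  if (length(object@eigenvalues)) {
    cv <- cumsum(object@eigenvalues) / sum(object@eigenvalues)
    k <- min(10L, length(object@eigenvalues))
    cat(sprintf("  top eigenvalue %.4g A^2; %d modes cover %.1f%% variance\n",
                object@eigenvalues[1], k, 100 * cv[k]))
  } else cat("  eigen-decomposition not yet computed (run pcaED)\n")
})

setMethod("show", "ClusterSolution", function(object) {
  cat(sprintf("ClusterSolution: k = %d, inertia %.4g, DB %.3f, CH %.4g\n",
              object@k, object@inertia, object@daviesBouldin,
              object@calinskiHarabasz))
})

setMethod("show", "TransitionReport", function(object) {
  cat("TransitionReport:", length(object@changePoints), "change point(s)",
      if (length(object@changePoints))
        paste("at", paste(object@changePoints, collapse = ", ")) else "",
      "\n")
})

setMethod("show", "ConsensusRanking", function(object) {
  cat("ConsensusRanking:", paste(object@ranking, collapse = " > "), "\n")
})

setMethod("show", "CandidateModel", function(object) {
  cat(sprintf("CandidateModel '%s': d = %.2f A, score = %s\n", object@id,
              object@d, format(object@externalScore)))
})
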