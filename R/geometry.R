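#' Optimal rigid-body superposition (Kabsch)
#'
#' Computes the weighted least-squares optimal proper rotation and
#' translation mapping `mobile` onto `reference` (row-vector convention:
#' `fitted = mobile %*% rotation + translation`). The reflection branch of
#' the SVD solution is corrected so the rotation determinant is always +1.
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3.
#' @param weights optional non-negative per-point weights (default
#'   uniform).
#' @return a [Superposition-class] with the post-fit weighted RMSD.
#' @export
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' kabschFit(x, x)@rmsd  # 0
kabschFit <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("point counts differ")
  if (n < 3L) stop("need at least 3 points for a superposition")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  w <- weights / sum(weights)
  cmM <- colSums(mobile * w); cmR <- colSums(reference * w)
  X <- sweep(mobile, 2L, cmM); Y <- sweep(reference, 2L, cmR)
  svR <- svd(Y)$d
  if (svR[2] < 1e-9 * max(svR[1], 1))
    stop("degenerate (collinear) reference configuration")
  A <- crossprod(X * w, Y)
  s <- svd(A)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tr <- cmR - drop(cmM %*% R)
  fitted <- mobile %*% R + rep(tr, each = n)
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  new("Superposition", rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a superposition to coordinates
#'
#' @param coords N x 3 matrix.
#' @param sp a [Superposition-class].
#' @return transformed N x 3 matrix.
#' @export
applySuperposition <- function(coords, sp) {
  coords %*% sp@rotation + rep(sp@translation, each = nrow(coords))
}

# Fit every frame of `arr` (N x 3 x F) onto refCoords using the atoms in
# fitIdx; all atoms are transformed.
.fitFrames <- function(arr, fitIdx, refCoords) {
  out <- arr
  for (f in seq_len(dim(arr)[3])) {
    sp <- kabschFit(arr[fitIdx, , f], refCoords)
    out[, , f] <- applySuperposition(arr[, , f], sp)
  }
  out
}

.plainRmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD series against a reference frame
#'
#' For every frame, the trajectory is least-squares fitted on `fitSelection`
#' to the reference frame, and the RMSD is then computed over
#' `computeSelection`. The two selections may differ — fitting on the whole
#' protein while measuring one domain isolates that domain's displacement
#' contribution ("all displacements"), fitting on the domain itself its
#' internal deformation.
#'
#' @param traj a [Trajectory-class].
#' @param fitSelection,computeSelection [AtomSelection-class] objects
#'   (`computeSelection` defaults to `fitSelection`).
#' @param referenceFrame index of the reference conformation (default 1,
#'   the initial model).
#' @param label series label.
#' @return a [MetricSeries-class] in Angstrom.
#' @export
rmsdSeries <- function(traj, fitSelection, computeSelection = fitSelection,
                       referenceFrame = 1L, label = "RMSD") {
  fitIdx <- applySelection(fitSelection, traj)
  compIdx <- applySelection(computeSelection, traj)
  if (referenceFrame < 1L || referenceFrame > nFrames(traj))
    stop("reference frame out of range")
  refFit <- traj@coords[fitIdx, , referenceFrame]
  refComp <- traj@coords[compIdx, , referenceFrame]
  vals <- vapply(seq_len(nFrames(traj)), function(f) {
    sp <- kabschFit(traj@coords[fitIdx, , f], refFit)
    .plainRmsd(applySuperposition(traj@coords[compIdx, , f], sp), refComp)
  }, 0)
  new("MetricSeries", values = vals,
      timeNs = (seq_len(nFrames(traj)) - 1L) * traj@timeStep, label = label)
}

#' Per-atom root-mean-square fluctuation
#'
#' Discards the first `burnIn` frames (non-equilibrated part), fits each
#' retained frame onto the first retained frame over `fitSelection`, and
#' returns each selected atom's RMS deviation from its time-average
#' position.
#'
#' @param traj a [Trajectory-class].
#' @param selection atoms to report (default all Calpha).
#' @param fitSelection atoms used for the fit (default = `selection`).
#' @param burnIn number of leading frames to discard.
#' @return named numeric vector of per-atom RMSFs (Angstrom), named by
#'   residue number.
#' @export
rmsf <- function(traj, selection = caSelection(), fitSelection = selection,
                 burnIn = 0L) {
  if (burnIn >= nFrames(traj))
    stop("burnIn (", burnIn, ") must be smaller than the frame count (",
         nFrames(traj), ")")
  keep <- seq.int(burnIn + 1L, nFrames(traj))
  if (length(keep) < 2L) stop("need at least 2 retained frames")
  fitIdx <- applySelection(fitSelection, traj)
  selIdx <- applySelection(selection, traj)
  arr <- .fitFrames(traj@coords[, , keep, drop = FALSE], fitIdx,
                    traj@coords[fitIdx, , keep[1]])
  sub <- arr[selIdx, , , drop = FALSE]
  avg <- apply(sub, c(1L, 2L), mean)
  dev2 <- sweep(sub, c(1L, 2L), avg)^2
  out <- sqrt(apply(dev2, 1L, mean) * 3)  # mean over frames of |dr|^2
  names(out) <- traj@topology@atoms$residueNumber[selIdx]
  out
}

.ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974)

.atomMasses <- function(atomNames) {
  el <- substr(gsub("[0-9]", "", atomNames), 1L, 1L)
  m <- .ELEMENT_MASSES[el]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Radius of gyration
#'
#' Mass-weighted spread of coordinates about the centre of mass,
#' `sqrt(sum(m |r - rcm|^2) / sum(m))`. When `x` is a
#' [ProteinStructure-class] and `masses` is `NULL`, standard atomic masses
#' inferred from the atom names are used; for a bare coordinate matrix the
#' default is uniform weights (appropriate for Calpha bead models).
#'
#' @param x N x 3 coordinate matrix or [ProteinStructure-class].
#' @param masses optional positive per-atom masses.
#' @return Rg in Angstrom.
#' @export
#' @examples
#' radiusOfGyration(rbind(c(-1, 0, 0), c(1, 0, 0)))  # 1
radiusOfGyration <- function(x, masses = NULL) {
  if (is(x, "ProteinStructure")) {
    if (is.null(masses)) masses <- .atomMasses(x@atoms$atomName)
    x <- coords(x)
  }
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("need at least one point")
  if (is.null(masses)) masses <- rep(1, nrow(x))
  if (any(masses <= 0)) stop("non-positive mass")
  w <- masses / sum(masses)
  cm <- colSums(x * w)
  sqrt(sum(w * rowSums(sweep(x, 2L, cm)^2)))
}

#' Radius-of-gyration series over a trajectory
#'
#' @param traj a [Trajectory-class].
#' @param selection an [AtomSelection-class] (default Calpha).
#' @param masses optional per-selected-atom masses; default standard
#'   atomic masses from the topology atom names.
#' @return a [MetricSeries-class] (Angstrom).
#' @export
rgSeries <- function(traj, selection = caSelection(), masses = NULL) {
  idx <- applySelection(selection, traj)
  if (is.null(masses)) masses <- .atomMasses(traj@topology@atoms$atomName[idx])
  vals <- vapply(seq_len(nFrames(traj)), function(f)
    radiusOfGyration(traj@coords[idx, , f], masses), 0)
  new("MetricSeries", values = vals,
      timeNs = (seq_len(nFrames(traj)) - 1L) * traj@timeStep, label = "Rg")
}

#' Size-normalized RMSD (RMSD100)
#'
#' Rescales an RMSD measured on an n-residue region to the value expected
#' for a 100-residue protein: `rmsd / (1 + ln(sqrt(n / 100)))`. The
#' denominator vanishes near n = 13, so n is required to be at least 20.
#'
#' @param rmsd RMSD in Angstrom (>= 0).
#' @param nResidues number of residues (>= 20).
#' @return normalized RMSD in Angstrom.
#' @export
#' @examples
#' rmsd100(2.0, 100)  # unchanged
#' rmsd100(2.0, 400)  # 2 / (1 + ln 2)
rmsd100 <- function(rmsd, nResidues) {
  if (any(rmsd < 0)) stop("rmsd must be non-negative")
  if (any(nResidues < 20))
    stop("nResidues must be >= 20 (normalization diverges near n = 13)")
  rmsd / (1 + log(sqrt(nResidues / 100)))
}

.caCoordOfResidue <- function(structure, resno) {
  a <- structure@atoms
  i <- which(a$residueNumber == resno & a$atomName == "CA")
  if (length(i) == 0L)
    stop("no CA atom for residue ", resno, " in structure")
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

#' End-to-end distance d between the scheme's reference residues
#'
#' The Euclidean Calpha-Calpha distance between the two residues of
#' `referencePair(scheme)` — for KIT, F689 and D768, the residues flanking
#' the KID. This distance is conserved across crystallographic KIT
#' structures (9.9 A in the autoinhibited template) and serves as a
#' structure-correctness criterion for candidate models.
#'
#' @param structure a [ProteinStructure-class].
#' @param scheme a [DomainScheme-class].
#' @return distance in Angstrom.
#' @export
endToEndDistance <- function(structure, scheme) {
  rp <- scheme@referencePair
  p1 <- .caCoordOfResidue(structure, rp[1])
  p2 <- .caCoordOfResidue(structure, rp[2])
  sqrt(sum((p1 - p2)^2))
}

#' @rdname endToEndDistance
#' @param traj a [Trajectory-class].
#' @return `endToEndSeries`: a [MetricSeries-class] of per-frame d values.
#' @export
endToEndSeries <- function(traj, scheme) {
  rp <- scheme@referencePair
  a <- traj@topology@atoms
  i1 <- which(a$residueNumber == rp[1] & a$atomName == "CA")[1]
  i2 <- which(a$residueNumber == rp[2] & a$atomName == "CA")[1]
  if (is.na(i1) || is.na(i2))
    stop("reference-pair residue missing a CA atom: ",
         rp[if (is.na(i1)) 1 else 2])
  d <- sqrt(colSums((traj@coords[i1, , ] - traj@coords[i2, , ])^2))
  new("MetricSeries", values = d,
      timeNs = (seq_len(nFrames(traj)) - 1L) * traj@timeStep, label = "d")
}

#' Export a metric series as a two-column text table
#'
#' @param series a [MetricSeries-class].
#' @param path output file (CSV: `time_ns,value`).
#' @return `path`, invisibly.
#' @export
writeMetricSeries <- function(series, path) {
  utils::write.csv(data.frame(time_ns = series@timeNs,
                              value = series@values),
                   path, row.names = FALSE)
  invisible(path)
}
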