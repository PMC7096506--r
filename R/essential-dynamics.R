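# shared fitting for covariance/DCCM: returns F x 3N matrix of fitted,
# flattened coordinates plus the reference used
.fittedFlat <- function(traj, selection, fitTarget = c("average", "initial"),
                        burnIn = 0L, tol = 1e-6, maxIter = 50L) {
  fitTarget <- match.arg(fitTarget)
  if (burnIn >= nFrames(traj))
    stop("burnIn must be smaller than the frame count")
  keep <- seq.int(burnIn + 1L, nFrames(traj))
  if (length(keep) < 2L) stop("need at least 2 retained frames")
  idx <- applySelection(selection, traj)
  sub <- traj@coords[idx, , keep, drop = FALSE]
  nf <- length(keep)
  ref <- sub[, , 1L]
  fitOnto <- function(ref) {
    out <- sub
    for (f in seq_len(nf)) {
      sp <- kabschFit(sub[, , f], ref)
      out[, , f] <- applySuperposition(sub[, , f], sp)
    }
    out
  }
  if (fitTarget == "initial") {
    fitted <- fitOnto(ref)
  } else {
    # iterate fit -> mean -> refit until the mean structure settles
    for (it in seq_len(maxIter)) {
      fitted <- fitOnto(ref)
      newRef <- apply(fitted, c(1L, 2L), mean)
      if (max(abs(newRef - ref)) < tol) { ref <- newRef; break }
      ref <- newRef
    }
    fitted <- fitOnto(ref)
  }
  flat <- matrix(NA_real_, nf, 3L * length(idx))
  for (f in seq_len(nf)) flat[f, ] <- .flattenCoords(fitted[, , f])
  list(flat = flat, idx = idx, reference = ref)
}

#' Positional covariance matrix of selected atoms
#'
#' Builds the 3N x 3N covariance matrix of atomic positions after
#' removing rigid-body motion by least-squares fitting every frame either
#' to the initial conformation or, iteratively, to the average
#' conformation (fit, recompute mean, refit until the mean moves by less
#' than `tol` Angstrom).
#'
#' @param traj a [Trajectory-class].
#' @param selection atoms entering the analysis (default all Calpha).
#' @param fitTarget `"average"` (default) or `"initial"`.
#' @param burnIn leading frames discarded as non-equilibrated.
#' @param tol convergence threshold for the iterative average fit.
#' @return an [EssentialDynamics-class] with the covariance and mean
#'   filled in (run [pcaED()] for the modes).
#' @export
covarianceED <- function(traj, selection = caSelection(),
                         fitTarget = c("average", "initial"), burnIn = 0L,
                         tol = 1e-6) {
  ft <- .fittedFlat(traj, selection, fitTarget, burnIn, tol)
  mu <- colMeans(ft$flat)
  Xc <- sweep(ft$flat, 2L, mu)
  C <- crossprod(Xc) / nrow(Xc)
  C <- (C + t(C)) / 2
  new("EssentialDynamics", covariance = C, eigenvalues = numeric(0),
      eigenvectors = matrix(0, 0L, 0L),
      meanCoords = .unflattenCoords(mu), atomIndices = ft$idx)
}

#' Essential-dynamics eigen-decomposition (C = V Lambda V^T)
#'
#' Diagonalizes the positional covariance matrix. Eigenvalues are
#' returned in descending order with tiny negative values (numerical
#' noise below 1e-8) clamped to zero; each eigenvector is normalized and
#' signed so its largest-magnitude component is positive.
#'
#' @param ed an [EssentialDynamics-class] from [covarianceED()].
#' @return the object with `eigenvalues` and `eigenvectors` filled in.
#' @export
pcaED <- function(ed) {
  C <- ed@covariance
  if (max(abs(C - t(C))) > 1e-6 * (1 + max(abs(C))))
    stop("covariance matrix is not symmetric")
  e <- eigen(C, symmetric = TRUE)
  lam <- e$values
  if (any(lam < -1e-8 * max(abs(lam), 1)))
    warning("covariance has a significantly negative eigenvalue")
  lam[lam < 0] <- 0
  V <- e$vectors
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  ed@eigenvalues <- lam
  ed@eigenvectors <- V
  ed
}

#' Cumulative variance fraction of the leading modes
#'
#' @param ed an [EssentialDynamics-class] after [pcaED()].
#' @param nModes number of leading modes.
#' @return fraction of the total positional variance in [0, 1].
#' @export
cumulativeVariance <- function(ed, nModes) {
  lam <- ed@eigenvalues
  if (length(lam) == 0L) stop("run pcaED() first")
  nModes <- min(nModes, length(lam))
  sum(lam[seq_len(nModes)]) / sum(lam)
}

#' Per-atom displacement amplitudes of a PCA mode
#'
#' The amplitude of atom a in mode k is `sqrt(lambda_k) * |v_k,a|`
#' (Angstrom). Atoms with amplitude below `cutoff` are suppressed,
#' mirroring the cutoff used when drawing porcupine arrows.
#'
#' @param ed an [EssentialDynamics-class] after [pcaED()].
#' @param modeIndex mode number (1 = largest variance).
#' @param cutoff suppression threshold in Angstrom (>= 0).
#' @return data.frame with `atom` (index into the selection),
#'   `amplitude`, and the scaled displacement vector `dx`, `dy`, `dz`;
#'   only atoms at or above the cutoff.
#' @export
modeDisplacements <- function(ed, modeIndex, cutoff = 0) {
  if (cutoff < 0) stop("cutoff must be non-negative")
  lam <- ed@eigenvalues
  if (modeIndex < 1L || modeIndex > length(lam)) stop("no such mode")
  v <- .unflattenCoords(ed@eigenvectors[, modeIndex]) * sqrt(lam[modeIndex])
  amp <- sqrt(rowSums(v^2))
  keep <- which(amp >= cutoff & amp > 0)
  data.frame(atom = keep, amplitude = amp[keep],
             dx = v[keep, 1], dy = v[keep, 2], dz = v[keep, 3])
}

#' Export a PCA mode as a two-frame PDB for porcupine-style viewing
#'
#' Writes `mean - scale*sqrt(lambda)*v` and `mean + scale*sqrt(lambda)*v`
#' as two MODEL blocks over the selected atoms.
#'
#' @param ed an [EssentialDynamics-class] after [pcaED()].
#' @param topology the trajectory topology the ED was computed from.
#' @param modeIndex mode number.
#' @param path output PDB path.
#' @param scale displacement scale in units of sqrt(lambda) (default 2).
#' @return `path`, invisibly.
#' @export
exportModePDB <- function(ed, topology, modeIndex, path, scale = 2) {
  v <- .unflattenCoords(ed@eigenvectors[, modeIndex]) *
    sqrt(ed@eigenvalues[modeIndex]) * scale
  sub <- topology@atoms[ed@atomIndices, , drop = FALSE]
  st <- new("ProteinStructure", atoms = sub)
  arr <- array(NA_real_, dim = c(nrow(sub), 3L, 2L))
  arr[, , 1L] <- ed@meanCoords - v
  arr[, , 2L] <- ed@meanCoords + v
  writeMultiModel(newTrajectory(arr, st, 1), path)
}

#' Dynamic cross-correlation map of atomic fluctuations
#'
#' Normalized correlation of the fluctuation vectors of every atom pair,
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, computed after
#' least-squares fitting (rigid-body removal). +1 marks fully correlated,
#' -1 fully anti-correlated motion. An atom with zero fluctuation gets a
#' zero row/column (unit diagonal) and is listed in `flagged`.
#'
#' @inheritParams covarianceED
#' @return a [CrossCorrelationMap-class].
#' @export
dccm <- function(traj, selection = caSelection(),
                 fitTarget = c("average", "initial"), burnIn = 0L) {
  dccmFromED(covarianceED(traj, selection, fitTarget, burnIn))
}

#' @rdname dccm
#' @param ed an [EssentialDynamics-class] whose covariance normalizes to
#'   the map.
#' @export
dccmFromED <- function(ed) {
  C3 <- ed@covariance
  n <- nrow(C3) %/% 3L
  # trace of each 3x3 block
  tr <- matrix(0, n, n)
  for (a in 1:3) {
    ia <- seq(a, 3L * n, by = 3L)
    tr <- tr + C3[ia, ia]
  }
  v <- diag(tr)
  flagged <- which(v < 1e-12)
  s <- sqrt(pmax(v, 1e-300))
  M <- tr / outer(s, s)
  if (length(flagged)) {
    M[flagged, ] <- 0
    M[, flagged] <- 0
  }
  diag(M) <- 1
  M <- (M + t(M)) / 2
  M[M > 1] <- 1
  M[M < -1] <- -1
  new("CrossCorrelationMap", map = M, flagged = as.integer(flagged))
}

#' Export the eigen-spectrum as a CSV table
#'
#' Columns `mode`, `eigenvalue` (Angstrom^2) and `cumulativeFraction`.
#'
#' @param ed an [EssentialDynamics-class] after [pcaED()].
#' @param path output file.
#' @param nModes number of modes to write (default 10).
#' @return `path`, invisibly.
#' @export
writeEigenSpectrum <- function(ed, path, nModes = 10L) {
  lam <- ed@eigenvalues
  nModes <- min(nModes, length(lam))
  utils::write.csv(data.frame(
    mode = seq_len(nModes), eigenvalue = lam[seq_len(nModes)],
    cumulativeFraction = cumsum(lam)[seq_len(nModes)] / sum(lam)),
    path, row.names = FALSE)
  invisible(path)
}

#' Export a dense matrix (covariance or DCCM) as whitespace-separated text
#'
#' @param m a matrix or [CrossCorrelationMap-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDenseMatrix <- function(m, path) {
  if (is(m, "CrossCorrelationMap")) m <- m@map
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
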