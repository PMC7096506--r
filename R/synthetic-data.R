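#' Generate a self-avoiding Calpha bead protein with a domain scheme
#'
#' Builds a persistent self-avoiding random walk with ~3.8 A consecutive
#' bead spacing (the Calpha-Calpha virtual bond length) and a minimum
#' non-consecutive bead separation of 3.0 A, split into contiguous named
#' domains. The middle domain plays the role of the KID; the scheme's
#' reference pair is set to the two beads flanking it, mirroring how F689
#' and D768 flank the KIT KID.
#'
#' @param domainSizes integer vector of beads per domain.
#' @param seed RNG seed.
#' @param spacing consecutive bead distance in Angstrom.
#' @param minSeparation minimum allowed non-consecutive distance.
#' @return list with `structure` ([ProteinStructure-class]) and `scheme`
#'   ([DomainScheme-class]).
#' @export
#' @examples
#' bp <- generateBeadProtein(c(10, 20, 10), seed = 42)
#' bp$scheme
generateBeadProtein <- function(domainSizes, seed, spacing = 3.8,
                                minSeparation = 3.0) {
  stopifnot(all(domainSizes >= 1))
  set.seed(seed)
  n <- sum(domainSizes)
  pos <- matrix(NA_real_, n, 3L)
  pos[1L, ] <- 0
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  for (i in seq_len(n - 1L)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      # persistent walk: small angular kicks keep the chain extended and
      # collisions rare; after repeated failures fall back to fully random
      kick <- if (try <= 50L) 0.5 else 2.0
      cand <- dir + kick * stats::rnorm(3)
      cand <- cand / sqrt(sum(cand^2))
      p <- pos[i, ] + spacing * cand
      if (i < 2L ||
          min(sqrt(colSums((t(pos[seq_len(i - 1L), , drop = FALSE]) - p)^2))) >=
          minSeparation + 0.05) {
        pos[i + 1L, ] <- p
        dir <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("self-avoiding walk failed to place bead ", i + 1L)
  }
  structure <- newStructure(serial = seq_len(n), atomName = "CA",
                            residueName = "ALA", residueNumber = seq_len(n),
                            x = pos[, 1], y = pos[, 2], z = pos[, 3])
  k <- length(domainSizes)
  nm <- if (k == 5L) c("JMR", "N-lobe", "KID", "C-lobe", "C-term")
        else if (k == 3L) c("N-lobe", "KID", "C-lobe")
        else {
          v <- paste0("D", seq_len(k))
          if (k >= 2L) v[ceiling(k / 2)] <- "KID"
          v
        }
  last <- cumsum(domainSizes)
  first <- c(1L, last[-k] + 1L)
  kid <- match("KID", nm)
  rp <- if (is.na(kid)) c(1L, n)
        else c(max(1L, first[kid] - 1L), min(n, last[kid] + 1L))
  list(structure = structure,
       scheme = newDomainScheme(nm, first, last, rp))
}

#' Build a covariance specification with planted eigen-structure
#'
#' Draws `length(eigenvalues)` random orthonormal directions in the 3N
#' coordinate space (QR of a Gaussian matrix) to act as the planted
#' principal modes.
#'
#' @param nAtoms number of atoms N.
#' @param eigenvalues planted variances (Angstrom^2), non-negative.
#' @param seed RNG seed.
#' @param directions optional 3N x r orthonormal matrix overriding the
#'   random draw.
#' @param meanCoords optional N x 3 mean conformation; when given, the
#'   planted directions are made orthogonal to the six rigid-body modes
#'   about it, so they represent purely internal motion (what survives
#'   least-squares fitting).
#' @return list with `eigenvalues` and `directions`.
#' @export
covarianceSpec <- function(nAtoms, eigenvalues, seed = 1L,
                           directions = NULL, meanCoords = NULL) {
  if (any(eigenvalues < 0)) stop("negative planted eigenvalue")
  r <- length(eigenvalues)
  if (is.null(directions)) {
    set.seed(seed)
    directions <- matrix(stats::rnorm(3 * nAtoms * r), 3 * nAtoms, r)
    if (!is.null(meanCoords)) {
      B <- .rigidBodyBasis(meanCoords)
      directions <- directions - B %*% crossprod(B, directions)
    }
    directions <- qr.Q(qr(directions))
  }
  list(eigenvalues = as.numeric(eigenvalues), directions = directions)
}

# orthonormal basis of the 6 rigid-body modes (3 translations + 3
# infinitesimal rotations) about the centred conformation
.rigidBodyBasis <- function(meanCoords) {
  n <- nrow(meanCoords)
  rc <- sweep(meanCoords, 2L, colMeans(meanCoords))
  B <- matrix(0, 3L * n, 6L)
  for (a in 1:3) B[seq(a, 3L * n, by = 3L), a] <- 1
  for (i in seq_len(n)) {
    r <- rc[i, ]
    B[3L * (i - 1L) + 1:3, 4L] <- c(0, -r[3], r[2])
    B[3L * (i - 1L) + 1:3, 5L] <- c(r[3], 0, -r[1])
    B[3L * (i - 1L) + 1:3, 6L] <- c(-r[2], r[1], 0)
  }
  qr.Q(qr(B))
}

# flattening convention used throughout: (x1, y1, z1, x2, y2, z2, ...)
.flattenCoords <- function(m) as.vector(t(m))
.unflattenCoords <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Generate a Gaussian-fluctuation trajectory with planted modes
#'
#' Frames are `mean + sum_i sqrt(lambda_i) z_i v_i` with standard-normal
#' `z`: an equilibrium-fluctuation stand-in whose positional covariance is
#' exactly the planted spectrum, used for PCA/RMSF/DCCM recovery tests.
#'
#' @param structure mean conformation ([ProteinStructure-class]).
#' @param covSpec a [covarianceSpec()] list.
#' @param nFrames number of frames.
#' @param seed RNG seed.
#' @param timeStep ns per frame.
#' @return list with `trajectory` ([Trajectory-class]) and `groundTruth`
#'   (planted `eigenvalues`, `directions`, `perAtomRmsf`).
#' @export
generateGaussianTrajectory <- function(structure, covSpec, nFrames, seed,
                                       timeStep = 0.001) {
  lam <- covSpec$eigenvalues
  V <- covSpec$directions
  if (any(lam < 0)) stop("negative eigenvalue in covariance spec")
  n3 <- 3L * nAtoms(structure)
  if (!is.null(V) && nrow(V) != n3)
    stop("direction dimension does not match 3N")
  mu <- .flattenCoords(coords(structure))
  set.seed(seed)
  Z <- matrix(stats::rnorm(nFrames * length(lam)), nFrames)
  frames <- tcrossprod(sweep(Z, 2L, sqrt(lam), `*`), V)  # F x 3N
  frames <- sweep(frames, 2L, mu, `+`)
  arr <- array(NA_real_, dim = c(nAtoms(structure), 3L, nFrames))
  for (f in seq_len(nFrames)) arr[, , f] <- .unflattenCoords(frames[f, ])
  # per-atom variance = sum_modes lambda * |v_atom|^2
  pav <- rep(0, nAtoms(structure))
  for (i in seq_along(lam)) {
    vi <- .unflattenCoords(V[, i])
    pav <- pav + lam[i] * rowSums(vi^2)
  }
  list(trajectory = newTrajectory(arr, structure, timeStep),
       groundTruth = list(eigenvalues = lam, directions = V,
                          perAtomRmsf = sqrt(pav)))
}

#' Generate a two-state transition trajectory
#'
#' Interpolates linearly from `stateA` to `stateB` across a switch window
#' and adds isotropic Gaussian coordinate noise — a stand-in for a
#' conformational transition such as the KID rearrangement. Ground truth
#' carries the window bounds and two-state frame labels (NA inside the
#' window).
#'
#' @param structure topology ([ProteinStructure-class]).
#' @param stateA,stateB N x 3 coordinate matrices (`stateA` defaults to
#'   the structure's own coordinates).
#' @param switchStart first frame of the switch window.
#' @param switchLen window length in frames.
#' @param noiseSigma isotropic coordinate noise sd (Angstrom).
#' @param nFrames total frames.
#' @param seed RNG seed.
#' @param timeStep ns per frame.
#' @return list with `trajectory` and `groundTruth` (`switchStart`,
#'   `switchEnd`, `labels`).
#' @export
generateTransitionTrajectory <- function(structure, stateA = NULL, stateB,
                                         switchStart, switchLen,
                                         noiseSigma, nFrames, seed,
                                         timeStep = 0.001) {
  if (is.null(stateA)) stateA <- coords(structure)
  stopifnot(all(dim(stateA) == dim(stateB)),
            switchStart >= 1L, switchStart + switchLen <= nFrames)
  set.seed(seed)
  n <- nAtoms(structure)
  arr <- array(NA_real_, dim = c(n, 3L, nFrames))
  for (f in seq_len(nFrames)) {
    w <- if (f < switchStart) 0
         else if (f >= switchStart + switchLen) 1
         else (f - switchStart + 1) / (switchLen + 1)
    arr[, , f] <- (1 - w) * stateA + w * stateB +
      if (noiseSigma > 0) matrix(stats::rnorm(3L * n, sd = noiseSigma),
                                 n, 3L) else 0
  }
  labels <- ifelse(seq_len(nFrames) < switchStart, 1L,
                   ifelse(seq_len(nFrames) >= switchStart + switchLen,
                          2L, NA_integer_))
  list(trajectory = newTrajectory(arr, structure, timeStep),
       groundTruth = list(switchStart = switchStart,
                          switchEnd = switchStart + switchLen,
                          labels = labels))
}

#' Generate a candidate-model ensemble with ground truth
#'
#' Emulates a fragment-assembly model set entering the screening stage:
#' bead models whose end-to-end distance d is drawn from a prescribed
#' distribution (imposed exactly by radially repositioning the second
#' reference bead), secondary-structure strings drawn from a small number
#' of group templates with per-position flip noise, and external
#' model-quality scores from a normal distribution (lower = better).
#'
#' @param spec list with elements `nModels` (default 200), `domainSizes`
#'   (default `c(10, 30, 10)`), `dDistribution` (either
#'   `list(type = "uniform", min, max)` or `list(type = "constant",
#'   value)`; default Uniform(7, 13) A), `nGroups` (default 4),
#'   `flipNoise` (default 0.05), `scoreMean`/`scoreSd` (default -30000 /
#'   1000, a DOPE-like scale).
#' @param seed RNG seed.
#' @return list with `models` (list of [CandidateModel-class]), `scheme`,
#'   and `groundTruth` (`d`, `groups`, `scores`, `templates`).
#' @export
generateCandidateEnsemble <- function(spec = list(), seed) {
  def <- list(nModels = 200L, domainSizes = c(10L, 30L, 10L),
              dDistribution = list(type = "uniform", min = 7, max = 13),
              nGroups = 4L, flipNoise = 0.05,
              scoreMean = -30000, scoreSd = 1000)
  spec <- utils::modifyList(def, spec)
  set.seed(seed)
  nRes <- sum(spec$domainSizes)
  alphabet <- c("H", "G", "E", "C", "T")
  templates <- replicate(spec$nGroups,
                         paste(sample(alphabet, nRes, replace = TRUE),
                               collapse = ""))
  nm <- spec$nModels
  dTrue <- switch(spec$dDistribution$type,
                  uniform = stats::runif(nm, spec$dDistribution$min,
                                         spec$dDistribution$max),
                  constant = rep(spec$dDistribution$value, nm),
                  stop("unknown d distribution type"))
  groups <- rep_len(seq_len(spec$nGroups), nm)
  scores <- stats::rnorm(nm, spec$scoreMean, spec$scoreSd)
  subSeeds <- sample.int(1e6, nm)
  scheme <- NULL
  models <- vector("list", nm)
  for (m in seq_len(nm)) {
    bp <- generateBeadProtein(spec$domainSizes, seed = subSeeds[m])
    if (is.null(scheme)) scheme <- bp$scheme
    xyz <- coords(bp$structure)
    rp <- referencePair(bp$scheme)
    # impose d exactly: move the second reference bead radially
    v <- xyz[rp[2], ] - xyz[rp[1], ]
    xyz[rp[2], ] <- xyz[rp[1], ] + dTrue[m] * v / sqrt(sum(v^2))
    st <- setStructureCoords(bp$structure, xyz)
    tmpl <- strsplit(templates[groups[m]], "")[[1]]
    flip <- stats::runif(nRes) < spec$flipNoise
    ss <- tmpl
    if (any(flip))
      ss[flip] <- vapply(tmpl[flip], function(s)
        sample(setdiff(alphabet, s), 1L), "")
    models[[m]] <- new("CandidateModel", structure = st, d = NA_real_,
                       externalScore = scores[m],
                       ss = paste(ss, collapse = ""),
                       id = sprintf("model_%03d", m))
  }
  list(models = models, scheme = scheme,
       groundTruth = list(d = dTrue, groups = groups, scores = scores,
                          templates = templates))
}

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

# natural-extension-reference-frame placement of atom D from A-B-C
.nerfPlace <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180; ch <- -chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(B - A, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  C + r * (-cos(th) * bc + sin(th) * cos(ch) * m + sin(th) * sin(ch) * n)
}

#' Build an ideal two-stranded antiparallel beta sheet
#'
#' Constructs one extended strand (phi = -139, psi = 135) and places a
#' second, antiparallel copy alongside it (180-degree rotation about the
#' strand axis plus a calibrated inter-strand offset) so that ladder
#' hydrogen bonds form between the strands.
#'
#' @param nRes residues per strand (default 6).
#' @param sep inter-strand separation in Angstrom.
#' @param shift registry shift along the strand axis in Angstrom.
#' @return a [ProteinStructure-class] with `2 * nRes` residues.
#' @export
generateIdealSheet <- function(nRes = 6L, sep = 4.4, shift = 0.75) {
  sA <- generateIdealBackbone(nRes, -139, 135)
  a <- atoms(sA)
  xyzA <- coords(sA)
  pc <- stats::prcomp(xyzA)$rotation
  ax <- pc[, 1]; perp <- pc[, 2]
  cen <- colMeans(xyzA)
  rotAbout <- function(axis, theta) {
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3L, 3L, byrow = TRUE)
    diag(3) * cos(theta) + sin(theta) * K +
      (1 - cos(theta)) * outer(axis, axis)
  }
  R <- rotAbout(ax, pi) %*% rotAbout(perp, pi)
  xyzB <- sweep(sweep(xyzA, 2L, cen) %*% t(R), 2L,
                cen + sep * perp + shift * ax, `+`)
  b <- a
  b$residueNumber <- b$residueNumber + nRes
  b$serial <- b$serial + nrow(a)
  b$x <- xyzB[, 1]; b$y <- xyzB[, 2]; b$z <- xyzB[, 3]
  new("ProteinStructure", atoms = rbind(a, b))
}

#' Build an ideal polypeptide backbone from phi/psi angles
#'
#' Constructs N, CA, C, O coordinates with standard bond lengths and
#' angles and the requested backbone dihedrals (trans peptide bonds).
#' Used to build the ideal alpha-helix and beta-strand fixtures for the
#' secondary-structure assigner.
#'
#' @param n number of residues.
#' @param phi,psi backbone dihedrals in degrees (recycled to length n).
#' @param residueName three-letter residue name for all residues.
#' @return a [ProteinStructure-class] with 4 backbone atoms per residue.
#' @export
#' @examples
#' helix <- generateIdealBackbone(12, phi = -57, psi = -47)
#' assignSS(helix)
generateIdealBackbone <- function(n, phi = -57, psi = -47,
                                  residueName = "ALA") {
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  bNCa <- 1.458; bCaC <- 1.525; bCN <- 1.329; bCO <- 1.231
  aNCaC <- 111.2; aCaCN <- 116.2; aCNCa <- 121.7; aCaCO <- 120.8
  N <- CA <- C <- O <- matrix(NA_real_, n, 3L)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bNCa, 0, 0)
  C[1, ] <- CA[1, ] + bCaC * c(cos(pi * (180 - aNCaC) / 180),
                               sin(pi * (180 - aNCaC) / 180), 0)
  for (i in seq_len(n)) {
    O[i, ] <- .nerfPlace(N[i, ], CA[i, ], C[i, ], bCO, aCaCO, psi[i] + 180)
    if (i < n) {
      N[i + 1, ] <- .nerfPlace(N[i, ], CA[i, ], C[i, ], bCN, aCaCN, psi[i])
      CA[i + 1, ] <- .nerfPlace(CA[i, ], C[i, ], N[i + 1, ], bNCa, aCNCa, 180)
      C[i + 1, ] <- .nerfPlace(C[i, ], N[i + 1, ], CA[i + 1, ], bCaC, aNCaC,
                               phi[i + 1])
    }
  }
  xyz <- matrix(NA_real_, 4L * n, 3L)
  nm <- character(4L * n); resno <- integer(4L * n)
  for (i in seq_len(n)) {
    j <- 4L * (i - 1L)
    xyz[j + 1L, ] <- N[i, ]; xyz[j + 2L, ] <- CA[i, ]
    xyz[j + 3L, ] <- C[i, ]; xyz[j + 4L, ] <- O[i, ]
    nm[j + 1:4] <- c("N", "CA", "C", "O")
    resno[j + 1:4] <- i
  }
  newStructure(serial = seq_len(4L * n), atomName = nm,
               residueName = residueName, residueNumber = resno,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}
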