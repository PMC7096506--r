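#' Torsion angle of four points
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees in (-180, 180].
#' @export
torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# backbone atom coordinate lookup table for one chain, ordered by residue
.backboneTable <- function(structure) {
  a <- structure@atoms
  a <- a[a$chainId == a$chainId[1], , drop = FALSE]
  res <- unique(a$residueNumber)
  get <- function(resno, name) {
    i <- which(a$residueNumber == resno & a$atomName == name)
    if (length(i) == 0L) return(rep(NA_real_, 3))
    c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
  }
  list(res = res,
       resName = vapply(res, function(r)
         a$residueName[which(a$residueNumber == r)[1]], ""),
       N = t(vapply(res, get, numeric(3), name = "N")),
       CA = t(vapply(res, get, numeric(3), name = "CA")),
       C = t(vapply(res, get, numeric(3), name = "C")),
       O = t(vapply(res, get, numeric(3), name = "O")))
}

#' Backbone dihedral angles (phi/psi)
#'
#' Computes per-residue phi (C(i-1)-N-CA-C) and psi (N-CA-C-N(i+1)) for
#' the first chain. Terminal residues and residues with incomplete
#' backbones get NA.
#'
#' @param structure a [ProteinStructure-class].
#' @return data.frame with `residueNumber`, `residueName`, `phi`, `psi`
#'   (degrees).
#' @export
backboneDihedrals <- function(structure) {
  bt <- .backboneTable(structure)
  n <- length(bt$res)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L && all(is.finite(c(bt$C[i - 1, ], bt$N[i, ], bt$CA[i, ],
                                  bt$C[i, ]))))
      phi[i] <- torsionAngle(bt$C[i - 1, ], bt$N[i, ], bt$CA[i, ], bt$C[i, ])
    if (i < n && all(is.finite(c(bt$N[i, ], bt$CA[i, ], bt$C[i, ],
                                 bt$N[i + 1, ]))))
      psi[i] <- torsionAngle(bt$N[i, ], bt$CA[i, ], bt$C[i, ], bt$N[i + 1, ])
  }
  data.frame(residueNumber = bt$res, residueName = bt$resName,
             phi = phi, psi = psi, stringsAsFactors = FALSE)
}

#' Favored + allowed Ramachandran regions
#'
#' A coarse published-style region map (in the spirit of classical
#' stereochemical-quality checkers) given as a union of phi/psi
#' rectangles: right-handed alpha, beta/extended (including its psi
#' wrap-around), and left-handed alpha. Values in degrees.
#'
#' @return data.frame with `region`, `phiMin`, `phiMax`, `psiMin`,
#'   `psiMax`.
#' @export
ramachandranRegions <- function() {
  data.frame(
    region = c("alphaR", "beta", "betaWrap", "alphaL"),
    phiMin = c(-180, -180, -180, 30),
    phiMax = c(-30, -30, -30, 100),
    psiMin = c(-120, 45, -180, -25),
    psiMax = c(45, 180, -140, 90),
    stringsAsFactors = FALSE)
}

.inAllowedRegion <- function(phi, psi, regions = ramachandranRegions()) {
  ok <- rep(FALSE, length(phi))
  for (r in seq_len(nrow(regions)))
    ok <- ok | (phi >= regions$phiMin[r] & phi <= regions$phiMax[r] &
                psi >= regions$psiMin[r] & psi <= regions$psiMax[r])
  ok
}

#' Fraction of residues in allowed Ramachandran regions
#'
#' Computes phi/psi for every evaluable residue (complete backbone,
#' interior of the chain), excludes glycine and proline as is customary,
#' and returns the fraction falling inside the favored+allowed region map
#' of [ramachandranRegions()]. For a trajectory the fraction is averaged
#' over frames.
#'
#' @param x a [ProteinStructure-class] or [Trajectory-class].
#' @param residues optional residue-number restriction.
#' @return fraction in [0, 1].
#' @export
ramachandranFraction <- function(x, residues = NULL) {
  if (is(x, "Trajectory")) {
    fr <- vapply(seq_len(nFrames(x)), function(f)
      ramachandranFraction(frameStructure(x, f), residues), 0)
    return(mean(fr))
  }
  bd <- backboneDihedrals(x)
  if (!is.null(residues)) bd <- bd[bd$residueNumber %in% residues, ]
  bd <- bd[!(bd$residueName %in% c("GLY", "PRO")), ]
  bd <- bd[is.finite(bd$phi) & is.finite(bd$psi), ]
  if (nrow(bd) == 0L)
    stop("no evaluable (non-Gly/Pro, complete-backbone) residues")
  mean(.inAllowedRegion(bd$phi, bd$psi))
}
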