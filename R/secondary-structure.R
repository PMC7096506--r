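#' Backbone hydrogen-bond matrix (Kabsch-Sander energy criterion)
#'
#' Detects backbone N-H...O=C hydrogen bonds with the Kabsch-Sander
#' electrostatic model: `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH -
#' 1/r_CN)` kcal/mol, a bond being assigned when `E < -0.5` kcal/mol.
#' Amide hydrogens are reconstructed geometrically (1.01 A from N along
#' the bisector of the C'(i-1)->N and CA->N directions) when not present
#' in the file; the chain's first residue and prolines have no donor.
#'
#' @param structure a [ProteinStructure-class] with backbone N/CA/C/O.
#' @param cutoff H-bond energy cutoff in kcal/mol (default -0.5).
#' @return logical matrix `HB`, `HB[i, j]` = TRUE when the NH of residue
#'   i donates to the CO of residue j.
#' @export
hbondMatrix <- function(structure, cutoff = -0.5) {
  bt <- .backboneTable(structure)
  n <- length(bt$res)
  H <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    if (i == 1L || bt$resName[i] == "PRO") next
    if (!all(is.finite(c(bt$C[i - 1L, ], bt$N[i, ], bt$CA[i, ])))) next
    d1 <- bt$N[i, ] - bt$C[i - 1L, ]
    d2 <- bt$N[i, ] - bt$CA[i, ]
    b <- d1 / sqrt(sum(d1^2)) + d2 / sqrt(sum(d2^2))
    H[i, ] <- bt$N[i, ] + 1.01 * b / sqrt(sum(b^2))
  }
  q <- 27.888  # 0.084 * 332 (kcal/mol * A)
  HB <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {        # donor
    if (!all(is.finite(H[i, ]))) next
    for (j in seq_len(n)) {      # acceptor
      if (abs(i - j) < 1L || i == j) next
      if (!all(is.finite(c(bt$C[j, ], bt$O[j, ])))) next
      rON <- sqrt(sum((bt$O[j, ] - bt$N[i, ])^2))
      if (rON > 7) next  # distance pre-screen, energy is ~0 beyond this
      rCH <- sqrt(sum((bt$C[j, ] - H[i, ])^2))
      rOH <- sqrt(sum((bt$O[j, ] - H[i, ])^2))
      rCN <- sqrt(sum((bt$C[j, ] - bt$N[i, ])^2))
      E <- if (min(rON, rCH, rOH, rCN) < 0.5) -9.9
           else q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      HB[i, j] <- E < cutoff
    }
  }
  dimnames(HB) <- list(bt$res, bt$res)
  HB
}

#' Assign per-residue secondary structure from coordinates
#'
#' A Kabsch-Sander-style assignment over the 8-letter alphabet: backbone
#' H-bonds by the electrostatic energy criterion ([hbondMatrix()]), then
#' the classical pattern rules — two consecutive n-turns make a helix
#' (n = 4: 'H', n = 3: 'G', n = 5: 'I'), bridge patterns make strand
#' residues ('E' in ladders, isolated bridges 'B'), remaining turn
#' residues 'T', Calpha-curvature bends 'S' (angle over i-2/i/i+2 above
#' 70 degrees), else coil 'C'. Assignment priority H > E > B > G > I >
#' T > S. Residues with incomplete backbones are assigned 'C' and listed
#' in the `flagged` attribute.
#'
#' @param structure a [ProteinStructure-class].
#' @return named character vector (names = residue numbers) over
#'   H/G/I/E/B/T/S/C, with attribute `flagged`.
#' @export
#' @examples
#' assignSS(generateIdealBackbone(12, -57, -47))
assignSS <- function(structure) {
  bt <- .backboneTable(structure)
  n <- length(bt$res)
  complete <- vapply(seq_len(n), function(i)
    all(is.finite(c(bt$N[i, ], bt$CA[i, ], bt$C[i, ], bt$O[i, ]))), TRUE)
  HB <- hbondMatrix(structure)
  turn <- function(nt) vapply(seq_len(n), function(i)
    i + nt <= n && HB[i + nt, i], TRUE)
  t3 <- turn(3L); t4 <- turn(4L); t5 <- turn(5L)
  isH <- isG <- isI <- isT <- bridge <- adjBridge <- rep(FALSE, n)
  markHelix <- function(tn, len) {
    out <- rep(FALSE, n)
    for (i in 2L:n) if (tn[i - 1L] && tn[i])
      out[i:min(n, i + len - 1L)] <- TRUE
    out
  }
  if (n >= 2L) {
    isH <- markHelix(t4, 4L)
    isG <- markHelix(t3, 3L)
    isI <- markHelix(t5, 5L)
  }
  for (nt in c(3L, 4L, 5L)) {
    tt <- switch(as.character(nt), "3" = t3, "4" = t4, "5" = t5)
    for (i in seq_len(n)) if (tt[i] && i + nt <= n)
      isT[(i + 1L):(i + nt - 1L)] <- TRUE
  }
  if (n >= 5L) for (i in 2L:(n - 1L)) {
    for (j in seq_len(n)) {
      if (j < i + 3L) next  # bridges need |i-j| >= 3
      par <- (i > 1L && HB[j, i - 1L] && i + 1L <= n && HB[i + 1L, j]) ||
             (j > 1L && HB[i, j - 1L] && j + 1L <= n && HB[j + 1L, i])
      anti <- (HB[j, i] && HB[i, j]) ||
              (i > 1L && j + 1L <= n && HB[j + 1L, i - 1L] &&
               i + 1L <= n && j > 1L && HB[i + 1L, j - 1L])
      if (par || anti) bridge[i] <- bridge[j] <- TRUE
    }
  }
  adjBridge <- bridge &
    (c(FALSE, bridge[-n]) | c(bridge[-1L], FALSE))
  bend <- rep(FALSE, n)
  if (n >= 5L) for (i in 3L:(n - 2L)) {
    u <- bt$CA[i, ] - bt$CA[i - 2L, ]
    v <- bt$CA[i + 2L, ] - bt$CA[i, ]
    if (!all(is.finite(c(u, v)))) next
    ca <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    if (acos(pmin(1, pmax(-1, ca))) * 180 / pi > 70) bend[i] <- TRUE
  }
  ss <- rep("C", n)
  ss[bend] <- "S"
  ss[isT] <- "T"
  ss[isI] <- "I"
  ss[isG] <- "G"
  ss[bridge & !adjBridge] <- "B"
  ss[adjBridge] <- "E"
  ss[isH] <- "H"
  ss[!complete] <- "C"
  names(ss) <- bt$res
  attr(ss, "flagged") <- bt$res[!complete]
  ss
}

#' Secondary-structure timeline over a trajectory
#'
#' Runs [assignSS()] on frames sampled every `stridePs` picoseconds.
#'
#' @param traj a [Trajectory-class] whose topology has backbone atoms.
#' @param stridePs sampling stride in ps; must be at least the frame
#'   spacing.
#' @return an [SSTimeline-class].
#' @export
ssTimeline <- function(traj, stridePs = 10) {
  dtPs <- traj@timeStep * 1000
  if (stridePs < dtPs)
    stop("stride (", stridePs, " ps) smaller than the frame spacing (",
         dtPs, " ps)")
  step <- max(1L, round(stridePs / dtPs))
  frames <- seq.int(1L, nFrames(traj), by = step)
  first <- assignSS(frameStructure(traj, frames[1L]))
  m <- matrix("", nrow = length(first), ncol = length(frames))
  m[, 1L] <- unname(first)
  for (k in seq_along(frames)[-1L])
    m[, k] <- unname(assignSS(frameStructure(traj, frames[k])))
  newSSTimeline(m, stridePs, as.integer(names(first)))
}

#' Construct an SSTimeline from a symbol matrix
#'
#' @param symbols residues x frames character matrix over H/G/I/E/B/T/S/C.
#' @param stridePs sampling stride in ps.
#' @param residueNumbers residue number per row (default `1:nrow`).
#' @return an [SSTimeline-class].
#' @export
newSSTimeline <- function(symbols, stridePs = 10,
                          residueNumbers = seq_len(nrow(symbols))) {
  new("SSTimeline", symbols = symbols, stridePs = stridePs * 1.0,
      residueNumbers = as.integer(residueNumbers))
}

#' Per-residue secondary-structure percentages over a timeline
#'
#' @param timeline an [SSTimeline-class].
#' @return residues x 8 matrix of percentages of simulation time (rows
#'   sum to 100).
#' @export
ssPercentages <- function(timeline) {
  m <- t(apply(timeline@symbols, 1L, function(r)
    100 * tabulate(factor(r, levels = SS_ALPHABET), 8L) / length(r)))
  colnames(m) <- SS_ALPHABET
  rownames(m) <- timeline@residueNumbers
  m
}

#' Per-frame secondary-structure content fractions
#'
#' For each sampled frame, the fraction of residues in each SS type plus
#' the "sum of folded structures" (1 minus the coil+turn+bend fraction).
#'
#' @param timeline an [SSTimeline-class].
#' @return data.frame with one row per frame: columns H, G, I, E, B, T,
#'   S, C and `folded`.
#' @export
ssContentSeries <- function(timeline) {
  if (length(timeline@symbols) == 0L) stop("empty timeline")
  fr <- t(apply(timeline@symbols, 2L, function(col)
    tabulate(factor(col, levels = SS_ALPHABET), 8L) / length(col)))
  colnames(fr) <- SS_ALPHABET
  out <- as.data.frame(fr)
  out$folded <- 1 - (out$C + out$T + out$S)
  out
}

#' Pairwise secondary-structure distance matrix
#'
#' `dist(i, j) = 1 - (fraction of positions with identical symbols)`: the
#' positional-identity semimetric used to cluster candidate models by
#' secondary-structure similarity.
#'
#' @param ssStrings character vector (or list) of equal-length SS strings.
#' @return symmetric numeric matrix with zero diagonal, values in [0, 1].
#' @export
ssSimilarityMatrix <- function(ssStrings) {
  ssStrings <- as.character(ssStrings)
  n <- length(ssStrings)
  L <- nchar(ssStrings)
  if (length(unique(L)) != 1L)
    stop("SS strings have unequal lengths: ",
         paste(unique(L), collapse = ", "))
  ch <- do.call(rbind, strsplit(ssStrings, ""))
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    d <- 1 - mean(ch[i, ] == ch[j, ])
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Secondary-structure conservation versus a reference assignment
#'
#' Mean over frames of the per-frame fraction of positions whose symbol
#' matches the reference, within the given region. Helix subtypes H/G/I
#' are merged before comparison (conservation here means helix
#' persistence, not subtype identity); E and B stay distinct.
#'
#' @param timeline an [SSTimeline-class].
#' @param referenceSS reference SS string (or character vector) covering
#'   the timeline's residues.
#' @param region optional residue numbers restricting the comparison.
#' @return fraction in [0, 1].
#' @export
ssConservation <- function(timeline, referenceSS, region = NULL) {
  ref <- if (length(referenceSS) == 1L) strsplit(referenceSS, "")[[1]]
         else as.character(referenceSS)
  if (length(ref) != nrow(timeline@symbols))
    stop("reference length (", length(ref),
         ") differs from timeline residue count (",
         nrow(timeline@symbols), ")")
  rows <- seq_len(nrow(timeline@symbols))
  if (!is.null(region)) {
    rows <- which(timeline@residueNumbers %in% region)
    if (length(rows) == 0L) stop("region outside the timeline residues")
  }
  merge <- function(x) ifelse(x %in% c("H", "G", "I"), "H", x)
  refM <- merge(ref[rows])
  mean(apply(timeline@symbols[rows, , drop = FALSE], 2L,
             function(col) mean(merge(col) == refM)))
}
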