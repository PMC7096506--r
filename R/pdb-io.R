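#' Read a PDB file into a ProteinStructure
#'
#' Parses the ATOM records of the first model of a PDB file (via bio3d's
#' parser). Alternate locations are resolved by keeping the
#' highest-occupancy copy of each atom; on ties the alphabetically first
#' altloc identifier is kept.
#'
#' @param path path to a PDB file.
#' @return a [ProteinStructure-class].
#' @export
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writePDB(generateBeadProtein(c(4, 4), seed = 1)$structure, f)
#' readPDB(f)
readPDB <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("PDB parse error in '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records in ", path)
  .structureFromBio3d(a)
}

.structureFromBio3d <- function(a) {
  alt <- ifelse(is.na(a$alt) | a$alt == "", "", a$alt)
  occ <- ifelse(is.na(a$o), 1, a$o)
  ins <- ifelse(is.na(a$insert) | a$insert == "", "", a$insert)
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  key <- paste(chain, a$resno, ins, a$elety, sep = "|")
  # altloc policy: highest occupancy wins, ties broken alphabetically
  keep <- order(key, -occ, alt)
  keep <- keep[!duplicated(key[keep])]
  keep <- sort(keep)  # restore file order
  a <- a[keep, , drop = FALSE]
  newStructure(serial = a$eleno, atomName = a$elety,
               residueName = a$resid, chainId = chain[keep],
               residueNumber = a$resno, insert = ins[keep],
               x = a$x, y = a$y, z = a$z,
               occupancy = occ[keep],
               bFactor = ifelse(is.na(a$b), 0, a$b))
}

#' Construct a ProteinStructure from atom vectors
#'
#' @param serial,atomName,residueName,chainId,residueNumber,insert,x,y,z,occupancy,bFactor
#'   per-atom vectors; scalars are recycled.
#' @return a [ProteinStructure-class].
#' @export
newStructure <- function(serial, atomName, residueName = "ALA",
                         chainId = "A", residueNumber, insert = "",
                         x, y, z, occupancy = 1, bFactor = 0) {
  n <- length(x)
  atoms <- data.frame(serial = as.integer(rep_len(serial, n)),
                      atomName = rep_len(atomName, n),
                      residueName = rep_len(residueName, n),
                      chainId = rep_len(chainId, n),
                      residueNumber = as.integer(rep_len(residueNumber, n)),
                      insert = rep_len(insert, n),
                      x = as.numeric(x), y = as.numeric(y),
                      z = as.numeric(z),
                      occupancy = rep_len(as.numeric(occupancy), n),
                      bFactor = rep_len(as.numeric(bFactor), n),
                      stringsAsFactors = FALSE)
  new("ProteinStructure", atoms = atoms)
}

#' Replace the coordinates of a structure
#'
#' @param structure a [ProteinStructure-class].
#' @param xyz N x 3 coordinate matrix.
#' @return the structure with new coordinates.
#' @export
setStructureCoords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nAtoms(structure), ncol(xyz) == 3L)
  structure@atoms$x <- xyz[, 1]
  structure@atoms$y <- xyz[, 2]
  structure@atoms$z <- xyz[, 3]
  validObject(structure)
  structure
}

.pdbAtomLine <- function(serial, name, resName, chain, resno, insert,
                         x, y, z, occ, b) {
  name4 <- ifelse(nchar(name) >= 4L, substr(name, 1L, 4L),
                  sprintf(" %-3s", name))
  sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial %% 100000L, name4, substr(resName, 1L, 3L),
          substr(paste0(chain, " "), 1L, 1L), resno,
          substr(paste0(insert, " "), 1L, 1L), x, y, z, occ, b)
}

.structureLines <- function(structure) {
  a <- structure@atoms
  .pdbAtomLine(a$serial, a$atomName, a$residueName, a$chainId,
               a$residueNumber, a$insert, a$x, a$y, a$z, a$occupancy,
               a$bFactor)
}

#' Write a structure as a single-model PDB file
#'
#' @param structure a [ProteinStructure-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePDB <- function(structure, path) {
  writeLines(c(.structureLines(structure), "END"), path)
  invisible(path)
}

#' Read a multi-model PDB file as a Trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; the topology (atom
#' names, residues) is taken from the first model. A file without MODEL
#' records is read as a single-frame trajectory. Models must share an
#' identical atom set; a model with a deviating atom count aborts the read
#' with an error naming it.
#'
#' @param path path to a (multi-model) PDB file.
#' @param timeStep time between frames in ns (default 0.001, i.e. one
#'   frame per ps).
#' @return a [Trajectory-class].
#' @export
readMultiModel <- function(path, timeStep = 0.001) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  isModel <- startsWith(lines, "MODEL")
  if (any(isModel)) {
    # pre-scan atom counts per MODEL block so the offending model can be named
    blockId <- cumsum(isModel)
    isAtom <- startsWith(lines, "ATOM")
    counts <- tapply(isAtom[blockId > 0L], blockId[blockId > 0L], sum)
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1])[1]
      stop("inconsistent atom count in MODEL ", names(counts)[bad],
           " (", counts[bad], " atoms vs ", counts[1], " in MODEL 1)")
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE, rm.alt = FALSE)
  idx <- which(pdb$atom$type == "ATOM")
  topo <- .structureFromBio3d(pdb$atom[idx, , drop = FALSE])
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  cols <- bio3d::atom2xyz(idx)
  nm <- nrow(xyz)
  arr <- array(NA_real_, dim = c(length(idx), 3L, nm))
  for (m in seq_len(nm))
    arr[, , m] <- matrix(xyz[m, cols], ncol = 3L, byrow = TRUE)
  newTrajectory(arr, topo, timeStep)
}

#' Construct a Trajectory
#'
#' @param coords nAtoms x 3 x nFrames array (a single N x 3 matrix is
#'   promoted to one frame).
#' @param topology a [ProteinStructure-class].
#' @param timeStep ns per frame.
#' @return a [Trajectory-class].
#' @export
newTrajectory <- function(coords, topology, timeStep = 0.001) {
  if (length(dim(coords)) == 2L)
    coords <- array(coords, dim = c(dim(coords), 1L))
  new("Trajectory", coords = coords, topology = topology,
      timeStep = timeStep)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @param frames frame indices to write (default all).
#' @return `path`, invisibly.
#' @export
writeMultiModel <- function(traj, path, frames = seq_len(nFrames(traj))) {
  a <- traj@topology@atoms
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    out[[i]] <- c(sprintf("MODEL     %4d", i),
                  .pdbAtomLine(a$serial, a$atomName, a$residueName,
                               a$chainId, a$residueNumber, a$insert,
                               traj@coords[, 1, f], traj@coords[, 2, f],
                               traj@coords[, 3, f], a$occupancy, a$bFactor),
                  "ENDMDL")
  }
  writeLines(c(unlist(out), "END"), path)
  invisible(path)
}

#' Extract one frame of a trajectory as a ProteinStructure
#'
#' @param traj a [Trajectory-class].
#' @param frame frame index.
#' @return a [ProteinStructure-class].
#' @export
frameStructure <- function(traj, frame) {
  stopifnot(frame >= 1L, frame <= nFrames(traj))
  setStructureCoords(traj@topology, traj@coords[, , frame])
}
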