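#' Construct a DomainScheme
#'
#' @param name,first,last vectors describing non-overlapping domain ranges.
#' @param referencePair two residue numbers defining the end-to-end
#'   distance d.
#' @param analysisRanges optional data.frame (`name`, `first`, `last`) of
#'   additional, possibly overlapping ranges.
#' @param notes free-text annotations.
#' @return a [DomainScheme-class].
#' @export
newDomainScheme <- function(name, first, last, referencePair,
                            analysisRanges = NULL, notes = character()) {
  d <- data.frame(name = as.character(name), first = as.integer(first),
                  last = as.integer(last), stringsAsFactors = FALSE)
  if (is.null(analysisRanges))
    analysisRanges <- data.frame(name = character(), first = integer(),
                                 last = integer(), stringsAsFactors = FALSE)
  new("DomainScheme", domains = d, analysisRanges = analysisRanges,
      referencePair = as.integer(referencePair), notes = notes)
}

#' The KIT cytoplasmic-domain residue scheme
#'
#' Returns the domain decomposition of the full-length KIT cytoplasmic
#' domain in the author numbering of PDB entry 1T45: juxtamembrane region
#' (JMR), kinase N-lobe, kinase insert domain (KID, strict Q694-T753),
#' kinase C-lobe and C-terminal domain (K936-V976). The elongated KID
#' (F689-D768, the strict KID plus ten flanking kinase-domain residues at
#' each end) and the kinase domain (KD) are carried as overlapping
#' analysis ranges. The reference pair for the end-to-end distance d is
#' (F689, D768), the residues flanking the KID.
#'
#' Note the boundary tension at residue 936: the crystallographic template
#' ends at V936 while the C-terminal domain is defined to start at K936;
#' the scheme keeps both values verbatim and records the clash in `notes`.
#'
#' @return a [DomainScheme-class].
#' @export
#' @examples
#' kitDomainScheme()
kitDomainScheme <- function() {
  newDomainScheme(
    name  = c("JMR", "N-lobe", "KID", "C-lobe", "C-term"),
    first = c(547L, 582L, 694L, 754L, 936L),
    last  = c(581L, 693L, 753L, 935L, 976L),
    referencePair = c(689L, 768L),
    analysisRanges = data.frame(
      name = c("KID-elongated", "KD"),
      first = c(689L, 582L), last = c(768L, 935L),
      stringsAsFactors = FALSE),
    notes = paste("C-term start K936 coincides with the template's final",
                  "residue V936; both author values kept verbatim"))
}

#' Look up a named range in a scheme
#'
#' Searches the domains first, then the analysis ranges.
#'
#' @param scheme a [DomainScheme-class].
#' @param name range name.
#' @return integer vector of residue numbers `first:last`.
#' @export
domainResidues <- function(scheme, name) {
  d <- rbind(scheme@domains, scheme@analysisRanges)
  i <- match(name, d$name)
  if (is.na(i)) stop("no domain or range named '", name, "' in scheme")
  seq.int(d$first[i], d$last[i])
}

#' Read / write a domain scheme as a plain-text config file
#'
#' The format is line-oriented: `domain <name> <first> <last>`,
#' `range <name> <first> <last>` (overlapping analysis ranges) and
#' `reference_pair <a> <b>`; `#` starts a comment.
#'
#' @param path file path.
#' @return `readDomainScheme` returns a [DomainScheme-class];
#'   `writeDomainScheme` returns `path` invisibly.
#' @export
readDomainScheme <- function(path) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*", "", ln))
  ln <- ln[nzchar(ln)]
  tok <- strsplit(ln, "[[:space:]]+")
  kind <- vapply(tok, `[`, "", 1L)
  getRanges <- function(k) {
    t2 <- tok[kind == k]
    data.frame(name = vapply(t2, `[`, "", 2L),
               first = as.integer(vapply(t2, `[`, "", 3L)),
               last = as.integer(vapply(t2, `[`, "", 4L)),
               stringsAsFactors = FALSE)
  }
  dom <- getRanges("domain")
  rng <- getRanges("range")
  rp <- tok[kind == "reference_pair"]
  if (length(rp) != 1L) stop("config must contain exactly one reference_pair")
  newDomainScheme(dom$name, dom$first, dom$last,
                  as.integer(rp[[1]][2:3]), analysisRanges = rng)
}

#' @rdname readDomainScheme
#' @param scheme a [DomainScheme-class].
#' @export
writeDomainScheme <- function(scheme, path) {
  d <- scheme@domains
  r <- scheme@analysisRanges
  writeLines(c(sprintf("domain %s %d %d", d$name, d$first, d$last),
               if (nrow(r)) sprintf("range %s %d %d", r$name, r$first, r$last),
               sprintf("reference_pair %d %d", scheme@referencePair[1],
                       scheme@referencePair[2])), path)
  invisible(path)
}

#' Atom selections
#'
#' `atomSelection()` builds a predicate over atoms (by atom-name set
#' and/or residue-number restriction); `caSelection()` is the ubiquitous
#' Calpha selection, optionally restricted to a named domain of a scheme.
#' `applySelection()` resolves a selection against a structure or a
#' trajectory topology into a stable, sorted integer index vector —
#' identical for every frame of a trajectory by construction.
#'
#' @param atomNames character vector of atom names; `character()` = all.
#' @param residues integer residue numbers; `integer()` = all.
#' @return `atomSelection`/`caSelection`: an [AtomSelection-class];
#'   `applySelection`: integer atom indices; `selectCoords`: an N x 3
#'   matrix (structure) or N x 3 x F array (trajectory).
#' @export
#' @examples
#' bp <- generateBeadProtein(c(4, 6, 4), seed = 1)
#' applySelection(caSelection(), bp$structure)
atomSelection <- function(atomNames = character(), residues = integer()) {
  new("AtomSelection", atomNames = as.character(atomNames),
      residues = as.integer(residues))
}

#' @rdname atomSelection
#' @param scheme optional [DomainScheme-class] for `domain`.
#' @param domain optional domain/range name restricting the selection.
#' @export
caSelection <- function(scheme = NULL, domain = NULL) {
  res <- if (!is.null(domain)) domainResidues(scheme, domain) else integer()
  atomSelection("CA", res)
}

#' @rdname atomSelection
#' @param selection an [AtomSelection-class].
#' @param x a [ProteinStructure-class] or [Trajectory-class].
#' @export
applySelection <- function(selection, x) {
  s <- if (is(x, "Trajectory")) x@topology else x
  a <- s@atoms
  keep <- rep(TRUE, nrow(a))
  if (length(selection@atomNames))
    keep <- keep & a$atomName %in% selection@atomNames
  if (length(selection@residues))
    keep <- keep & a$residueNumber %in% selection@residues
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("empty atom selection (atoms: ",
         paste(selection@atomNames, collapse = ","),
         if (length(selection@residues))
           paste0("; residues ", min(selection@residues), "-",
                  max(selection@residues)), ")")
  idx
}

#' @rdname atomSelection
#' @export
selectCoords <- function(x, selection) {
  idx <- applySelection(selection, x)
  if (is(x, "Trajectory")) x@coords[idx, , , drop = FALSE]
  else coords(x)[idx, , drop = FALSE]
}
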