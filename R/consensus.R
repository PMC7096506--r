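#' Trajectory metric report for one candidate model
#'
#' Assembles the candidate-comparison metric suite over the production
#' window (after `burnIn` frames): per-domain RMSD mean/sd (each domain
#' fitted on itself, reference = initial conformation), per-domain mean
#' RMSF, the end-to-end distance d mean/sd and its deviation from the
#' crystallographic reference, the KID radius-of-gyration mean/sd, the
#' secondary-structure conservation of the kinase lobes against a
#' template assignment (when available), and a plateau flag per RMSD
#' series (ordinary-least-squares slope over the final quarter within
#' twice its standard error).
#'
#' @param traj a [Trajectory-class].
#' @param scheme a [DomainScheme-class]; all its domains must be present
#'   in the topology.
#' @param dRef reference end-to-end distance, Angstrom.
#' @param templateSS optional reference SS assignment (string or vector
#'   over the chain residues) for the conservation score.
#' @param ssTimelineObj optional precomputed [SSTimeline-class] (used
#'   when the trajectory lacks full backbones, e.g. bead models).
#' @param burnIn frames discarded before computing statistics.
#' @param id candidate identifier.
#' @param rgDomain domain whose compactness is tracked (default "KID").
#' @param conservationDomains domains entering the SS-conservation score
#'   (default the kinase lobes).
#' @return a [CandidateReport-class].
#' @export
candidateMetrics <- function(traj, scheme, dRef, templateSS = NULL,
                             ssTimelineObj = NULL, burnIn = 0L,
                             id = "candidate", rgDomain = "KID",
                             conservationDomains = c("N-lobe", "C-lobe")) {
  if (burnIn >= nFrames(traj))
    stop("burnIn (", burnIn, ") must be smaller than the frame count (",
         nFrames(traj), ")")
  prod <- seq.int(burnIn + 1L, nFrames(traj))
  topoRes <- unique(traj@topology@atoms$residueNumber)
  dm <- domains(scheme)
  for (nm in dm$name)
    if (!any(domainResidues(scheme, nm) %in% topoRes))
      stop("domain '", nm, "' absent from the trajectory topology")
  rmsdMean <- rmsdSd <- rmsfMean <- stats::setNames(numeric(nrow(dm)),
                                                    dm$name)
  plateau <- stats::setNames(logical(nrow(dm)), dm$name)
  for (nm in dm$name) {
    sel <- caSelection(scheme, nm)
    s <- rmsdSeries(traj, sel, referenceFrame = 1L, label = nm)
    v <- s@values[prod]
    rmsdMean[nm] <- mean(v)
    rmsdSd[nm] <- stats::sd(v)
    plateau[nm] <- .isPlateau(s@values)
    rmsfMean[nm] <- mean(rmsf(traj, sel, burnIn = burnIn))
  }
  dSeries <- endToEndSeries(traj, scheme)
  dv <- dSeries@values[prod]
  rg <- rgSeries(traj, caSelection(scheme, rgDomain))
  rgv <- rg@values[prod]
  cons <- NA_real_
  tl <- ssTimelineObj
  if (!is.null(templateSS)) {
    if (is.null(tl)) {
      bbOk <- all(c("N", "CA", "C", "O") %in% traj@topology@atoms$atomName)
      if (bbOk) tl <- ssTimeline(traj, stridePs = traj@timeStep * 1000)
    }
    if (!is.null(tl)) {
      region <- unlist(lapply(intersect(conservationDomains, dm$name),
                              function(nm) domainResidues(scheme, nm)))
      cons <- ssConservation(tl, templateSS, region = region)
    }
  }
  new("CandidateReport", id = id,
      domainRmsdMean = rmsdMean, domainRmsdSd = rmsdSd,
      domainRmsfMean = rmsfMean,
      dMean = mean(dv), dSd = stats::sd(dv), dDev = abs(mean(dv) - dRef),
      rgMean = mean(rgv), rgSd = stats::sd(rgv),
      ssConservation = cons, plateau = plateau)
}

# OLS slope over the final quarter; stable when |slope| < 2 * se(slope)
.isPlateau <- function(values) {
  n <- length(values)
  tail <- values[seq.int(max(1L, n - n %/% 4L + 1L), n)]
  if (length(tail) < 3L || stats::sd(tail) == 0) return(TRUE)
  t <- seq_along(tail)
  fit <- stats::lm(tail ~ t)
  co <- summary(fit)$coefficients
  abs(co[2L, 1L]) < 2 * co[2L, 2L]
}

.reportMetricTable <- function(reports) {
  data.frame(
    id = vapply(reports, function(r) r@id, ""),
    rmsdMean = vapply(reports, function(r) mean(r@domainRmsdMean), 0),
    rmsdSd = vapply(reports, function(r) mean(r@domainRmsdSd), 0),
    rmsfMean = vapply(reports, function(r) mean(r@domainRmsfMean), 0),
    dDev = vapply(reports, function(r) r@dDev, 0),
    rgSd = vapply(reports, function(r) r@rgSd, 0),
    ssConservation = vapply(reports, function(r) r@ssConservation, 0),
    stringsAsFactors = FALSE)
}

#' Consensus ranking of candidate reports
#'
#' Ranks the candidates independently on each metric — lower is better
#' for the mean RMSD, RMSD variability, mean RMSF, |d - dRef| and Rg
#' variability; higher is better for SS conservation — and aggregates by
#' unweighted rank sum (Borda). Ties on the aggregate are broken by
#' |d - dRef|, then by id; a metric that is NA for any candidate is
#' dropped from the aggregation and noted.
#'
#' @param reports list of [CandidateReport-class] (>= 2).
#' @param weights optional named numeric weights per metric
#'   (`rmsdMean`, `rmsdSd`, `rmsfMean`, `dDev`, `rgSd`,
#'   `ssConservation`).
#' @return a [ConsensusRanking-class].
#' @export
consensusRank <- function(reports, weights = NULL) {
  if (length(reports) < 2L) stop("need at least 2 candidate reports")
  tb <- .reportMetricTable(reports)
  lowerBetter <- c(rmsdMean = TRUE, rmsdSd = TRUE, rmsfMean = TRUE,
                   dDev = TRUE, rgSd = TRUE, ssConservation = FALSE)
  notes <- character(0)
  metrics <- names(lowerBetter)
  drop <- metrics[vapply(metrics, function(m) any(is.na(tb[[m]])), TRUE)]
  if (length(drop)) {
    notes <- c(notes, paste("metric(s) dropped (NA for some candidate):",
                            paste(drop, collapse = ", ")))
    metrics <- setdiff(metrics, drop)
  }
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(metrics)),
                                                   metrics)
  rk <- sapply(metrics, function(m) {
    x <- tb[[m]]
    if (!lowerBetter[[m]]) x <- -x
    rank(x, ties.method = "min")
  })
  rk <- matrix(rk, nrow = nrow(tb),
               dimnames = list(tb$id, metrics))
  score <- drop(rk %*% weights[metrics])
  if (anyDuplicated(score))
    notes <- c(notes, "aggregate tie broken by |d - dRef| then id")
  ord <- order(score, tb$dDev, tb$id)
  new("ConsensusRanking", ranking = tb$id[ord],
      rankTable = as.data.frame(rk), scores = stats::setNames(score, tb$id),
      notes = notes)
}

#' Write a consensus report as JSON
#'
#' @param ranking a [ConsensusRanking-class].
#' @param reports the list of [CandidateReport-class] that produced it.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeConsensusReport <- function(ranking, reports, path) {
  jsonlite::write_json(
    list(ranking = ranking@ranking, scores = as.list(ranking@scores),
         perMetricRanks = ranking@rankTable,
         metrics = .reportMetricTable(reports), notes = ranking@notes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
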