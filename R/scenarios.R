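# apply a fusion/fission event list to a duplicated ancestral karyotype.
# A genome is a named list of data.frames (anc, copy, seg) giving the
# ordered segment copies each chromosome carries.
baseGenome <- function(nAncestral, segmentsPer) {
  g <- list()
  for (k in seq_len(nAncestral))
    for (cp in 1:2)
      g[[sprintf("c%d.%d", k, cp)]] <-
        data.frame(anc = k, copy = cp, seg = seq_len(segmentsPer))
  g
}

applyEvent <- function(genome, ev) {
  if (ev$type == "fusion") {
    for (ch in c(ev$chr1, ev$chr2))
      if (is.null(genome[[ch]]))
        stop("fusion references missing chromosome: ", ch)
    merged <- rbind(genome[[ev$chr1]], genome[[ev$chr2]])
    genome[[ev$chr1]] <- NULL
    genome[[ev$chr2]] <- NULL
    genome[[paste(ev$chr1, ev$chr2, sep = "+")]] <- merged
  } else if (ev$type == "fission") {
    ch <- genome[[ev$chr]]
    if (is.null(ch))
      stop("fission references missing chromosome: ", ev$chr)
    b <- ev$breakpoint
    if (b < 1 || b >= nrow(ch))
      stop("fission breakpoint outside chromosome: ", ev$chr)
    genome[[ev$chr]] <- NULL
    genome[[paste0(ev$chr, "-1")]] <- ch[seq_len(b), , drop = FALSE]
    genome[[paste0(ev$chr, "-2")]] <-
      ch[(b + 1):nrow(ch), , drop = FALSE]
  } else stop("unknown event type: ", ev$type)
  genome
}

# returns list(speciesA = genome, speciesB = genome) after all events.
# Fission breakpoints are interpreted on the segment resolution given by
# segmentsPer (breakpoint = number of leading segment copies retained).
applyScenario <- function(scenario, segmentsPer = 10L) {
  common <- baseGenome(scenario@nAncestral, segmentsPer)
  evs <- scenario@events
  lin <- vapply(evs, `[[`, "", "lineage")
  for (ev in evs[lin == "common"]) common <- applyEvent(common, ev)
  gA <- common
  gB <- common
  for (ev in evs[lin == "speciesA"]) gA <- applyEvent(gA, ev)
  for (ev in evs[lin == "speciesB"]) gB <- applyEvent(gB, ev)
  list(speciesA = gA, speciesB = gB)
}

#' Simulation settings for a duplicated, rearranged genome history
#'
#' Combines a \linkS4class{RearrangementScenario} with the number of
#' conserved segments each ancestral chromosome contributes and a seed.
#'
#' @param scenario a \linkS4class{RearrangementScenario} (or arguments
#'   \code{nAncestral}/\code{events} to build one).
#' @param segmentsPer conserved segments per ancestral chromosome copy
#'   (>= 1).
#' @param seed integer seed.
#' @return list of class "WGDHistory".
#' @export
wgdHistory <- function(scenario, segmentsPer = 10L, seed = 1L) {
  stopifnot(is(scenario, "RearrangementScenario"), segmentsPer >= 1)
  structure(list(scenario = scenario,
                 segmentsPer = as.integer(segmentsPer),
                 seed = as.integer(seed)),
            class = "WGDHistory")
}

#' Simulate conserved-segment tables for two post-duplication species
#'
#' Applies the whole-genome duplication and the scenario's fusion and
#' fission events, then reports, for every segment copy, the chromosome
#' that carries it in each descendant species.  With probability
#' \code{confusion} a segment's detected partner in species B is
#' reassigned to the chromosome carrying the paralogous copy, emulating
#' the vague orthology assignment between ohnologous chromosomes of
#' species that diverged soon after the duplication.
#'
#' @param history a \code{\link{wgdHistory}}.
#' @param confusion paralog-confusion probability in [0, 1).
#' @return data.frame (segment_id, chrA, chrB) with attributes
#'   \code{trueChrB} (assignments before confusion) and \code{genomes}
#'   (the two chromosome contents).
#' @export
simulateWGDSegments <- function(history, confusion = 0) {
  stopifnot(confusion >= 0, confusion < 1)
  set.seed(history$seed)
  gen <- applyScenario(history$scenario, history$segmentsPer)
  locate <- function(genome, anc, copy, seg) {
    for (nm in names(genome)) {
      ch <- genome[[nm]]
      if (any(ch$anc == anc & ch$copy == copy & ch$seg == seg))
        return(nm)
    }
    NA_character_
  }
  segs <- do.call(rbind, unname(gen$speciesA))
  segs <- segs[order(segs$anc, segs$copy, segs$seg), ]
  chrA <- character(nrow(segs))
  chrB <- character(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    chrA[i] <- locate(gen$speciesA, segs$anc[i], segs$copy[i],
                      segs$seg[i])
    chrB[i] <- locate(gen$speciesB, segs$anc[i], segs$copy[i],
                      segs$seg[i])
  }
  trueChrB <- chrB
  flip <- runif(nrow(segs)) < confusion
  for (i in which(flip)) {
    para <- locate(gen$speciesB, segs$anc[i], 3L - segs$copy[i],
                   segs$seg[i])
    if (!is.na(para)) chrB[i] <- para
  }
  out <- data.frame(
    segment_id = sprintf("s%d.%d.%d", segs$anc, segs$copy, segs$seg),
    chrA = chrA, chrB = chrB)
  attr(out, "trueChrB") <- trueChrB
  attr(out, "genomes") <- gen
  out
}

#' Predict the qualitative Oxford-grid pattern of a scenario
#'
#' Applies duplication and the scenario's events, then classifies each
#' chromosome pair: "ortho" (large cell expected) when the two
#' chromosomes carry the same post-duplication segment copies, "para"
#' (small cell expected) when they carry paralogous copies of the same
#' ancestral region, "empty" otherwise.
#'
#' @param scenario a \linkS4class{RearrangementScenario}.
#' @param segmentsPer segment resolution used to interpret fission
#'   breakpoints (default 10).
#' @return character matrix of "ortho"/"para"/"empty" with species-A
#'   chromosomes as rows and species-B chromosomes as columns.
#' @export
predictGrid <- function(scenario, segmentsPer = 10L) {
  gen <- applyScenario(scenario, segmentsPer)
  nmA <- sort(names(gen$speciesA))
  nmB <- sort(names(gen$speciesB))
  pat <- matrix("empty", length(nmA), length(nmB),
                dimnames = list(nmA, nmB))
  key <- function(df) paste(df$anc, df$copy, df$seg)
  pkey <- function(df) paste(df$anc, 3L - df$copy, df$seg)
  for (a in nmA) for (b in nmB) {
    ka <- key(gen$speciesA[[a]])
    kb <- key(gen$speciesB[[b]])
    if (any(ka %in% kb)) pat[a, b] <- "ortho"
    else if (any(pkey(gen$speciesA[[a]]) %in% kb)) pat[a, b] <- "para"
  }
  pat
}

# congruence of an observed count grid with a predicted pattern, under
# the best relabelling of chromosomes (rows and columns permuted
# independently). Cells below tSmall that mismatch a predicted-empty
# cell are ignorable noise.
gridCongruence <- function(observed, pattern, tSmall = 3) {
  if (!all(dim(observed) == dim(pattern))) return(-Inf)
  n <- nrow(observed)
  m <- ncol(observed)
  if (factorial(n) * factorial(m) > 1e6)
    stop("grid too large for exhaustive relabelling")
  Pn <- allPerms(n)
  Pm <- allPerms(m)
  score <- function(obs, pat) {
    sum(obs > 0 & pat != "empty") -
      sum(obs >= tSmall & pat == "empty") -
      sum(obs == 0 & pat != "empty")
  }
  best <- -Inf
  for (i in seq_len(nrow(Pn)))
    for (j in seq_len(nrow(Pm))) {
      s <- score(observed[Pn[i, ], Pm[j, ], drop = FALSE], pattern)
      if (s > best) best <- s
    }
  best
}

#' Rank rearrangement scenarios against an observed Oxford grid
#'
#' Each candidate's predicted pattern is scored for congruence with the
#' observed grid: matching nonzero/nonempty cells count +1, an observed
#' cell of at least \code{tSmall} segments over a predicted-empty cell
#' counts -1, and a predicted-nonempty cell with no observed segments
#' counts -1; observed cells below \code{tSmall} over predicted-empty
#' cells are ignorable noise.  Chromosome labels are free, so the score
#' is maximised over row and column relabellings; scenarios whose
#' chromosome counts do not match the grid are incomparable (-Inf).
#' Ties are broken by fewer events (parsimony), then input order.
#'
#' @param observed an \linkS4class{OxfordGrid} or count matrix.
#' @param scenarios list of \linkS4class{RearrangementScenario}s.
#' @param segmentsPer segment resolution for fission breakpoints.
#' @param tSmall small-cell noise threshold (default 3).
#' @return data.frame ranked best-first: label, congruence, n_events.
#' @export
rankScenarios <- function(observed, scenarios, segmentsPer = 10L,
                          tSmall = 3) {
  stopifnot(length(scenarios) >= 1)
  obs <- if (is(observed, "OxfordGrid")) gridCounts(observed) else
    observed
  res <- data.frame(
    label = vapply(scenarios, slot, "", "label"),
    congruence = vapply(scenarios, function(s)
      gridCongruence(obs, predictGrid(s, segmentsPer), tSmall),
      numeric(1)),
    n_events = vapply(scenarios, function(s) length(s@events),
                      numeric(1)))
  res[order(-res$congruence, res$n_events, seq_len(nrow(res))), ]
}
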