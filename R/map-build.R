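#' Assemble a genetic map from grouped, ordered markers
#'
#' Positions are cumulative Kosambi distances over adjacent-pair
#' recombination fractions; unlinked adjacencies are capped at
#' \code{rfMax} before the transform to keep distances finite.
#'
#' @param gm the genotype matrix the linkage was computed from (used for
#'   per-marker typed counts).
#' @param pl a \linkS4class{PairwiseLinkage}.
#' @param groups list of marker-id vectors (see
#'   \code{\link{groupMarkers}}); each is ordered internally with
#'   \code{\link{orderMarkers}}.
#' @param sex map label.
#' @param rfMax cap on adjacent recombination fractions (default
#'   0.4999).
#' @param exhaustiveMax passed to \code{\link{orderMarkers}}.
#' @return a \linkS4class{GeneticMap}.
#' @export
assembleMap <- function(gm, pl, groups, sex = "female",
                        rfMax = 0.4999, exhaustiveMax = 8) {
  typed <- rowSums(!is.na(gm@geno))
  names(typed) <- gm@markerInfo$marker_id
  rows <- lapply(seq_along(groups), function(g) {
    o <- orderMarkers(groups[[g]], pl, exhaustiveMax)
    r <- if (length(o) > 1)
      pmin(pl@rf[cbind(o[-length(o)], o[-1])], rfMax) else numeric()
    data.frame(linkage_group = g, rank = seq_along(o), marker_id = o,
               position_cM = c(0, cumsum(kosambiCM(r))),
               n_typed = as.integer(typed[o]))
  })
  GeneticMap(do.call(rbind, rows), sex = sex)
}

#' Error-LOD scan for apparent tight double crossovers
#'
#' A genotype whose two flanking genotypes agree with each other and
#' disagree with it implies a double crossover in two short intervals;
#' such calls are far more often genotyping errors.  The error LOD is
#' log10[ eps (1-rL)(1-rR) / ((1-eps) rL rR) ] with rL, rR the
#' recombination fractions of the flanking intervals and eps the prior
#' error probability.  Observed adjacent recombination fractions are
#' themselves inflated by genotyping error (two independent calls
#' disagree with probability e2 = 2 eps (1 - eps) even at zero
#' distance), so the flank fractions taken from the map intervals are
#' first deconvolved, r = (r_obs - e2) / (1 - 2 e2), then floored at
#' \code{rMin}; without this, co-located marker stacks would never
#' present the tight flanks the scan relies on.  Calls with error LOD
#' above \code{threshold} are replaced by missing values.  Terminal
#' markers have one flank and are not scanned.
#'
#' @param map an ordered \linkS4class{GeneticMap}.
#' @param gm the \linkS4class{GenotypeMatrix} behind it.
#' @param epsilon prior genotyping-error probability (0 < eps < 0.5).
#' @param threshold masking threshold on the error LOD (default 2).
#' @param rMin floor for flanking-interval recombination fractions.
#' @return list with \code{genotypes}, the corrected matrix, and
#'   \code{flags}, a data.frame (marker_id, individual, error_lod,
#'   masked) of every apparent double crossover examined.
#' @export
#' @rdname errorLodScan
#' @param rL,rR flanking-interval recombination fractions.
#' @export
errorLod <- function(rL, rR, epsilon = 0.01)
  log10(epsilon * (1 - rL) * (1 - rR) /
          ((1 - epsilon) * rL * rR))

#' @export
errorLodScan <- function(map, gm, epsilon = 0.01, threshold = 2,
                         rMin = 1e-4) {
  stopifnot(epsilon > 0, epsilon < 0.5)
  g <- gm@geno
  ids <- gm@markerInfo$marker_id
  tb <- mapTable(map)
  flags <- list()
  for (grp in split(tb, tb$linkage_group)) {
    grp <- grp[order(grp$rank), ]
    o <- match(grp$marker_id, ids)
    if (length(o) < 3) next
    e2 <- 2 * epsilon * (1 - epsilon)
    rObs <- inverseKosambi(diff(grp$position_cM))
    r <- pmax((rObs - e2) / (1 - 2 * e2), rMin)
    for (k in 2:(length(o) - 1L)) {
      up <- g[o[k - 1L], ]
      mid <- g[o[k], ]
      dn <- g[o[k + 1L], ]
      hit <- !is.na(up) & !is.na(mid) & !is.na(dn) &
        up == dn & mid != up
      if (!any(hit)) next
      elod <- errorLod(r[k - 1L], r[k], epsilon)
      masked <- elod > threshold
      if (masked) g[o[k], hit] <- NA_character_
      flags[[length(flags) + 1L]] <- data.frame(
        marker_id = grp$marker_id[k],
        individual = colnames(g)[hit],
        error_lod = elod, masked = masked)
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(marker_id = character(), individual = character(),
               error_lod = numeric(), masked = logical())
  list(genotypes = initialize(gm, geno = g), flags = flags)
}

#' Build one sex map end to end
#'
#' The per-sex mapping pass: completeness filter, two-point linkage, LOD
#' grouping, SARF ordering with Kosambi positions, error-LOD masking,
#' then one reconstruction pass (re-filter, re-link, re-group, re-order)
#' on the corrected genotypes.
#'
#' @param gm recoded sex-specific \linkS4class{GenotypeMatrix}.
#' @param sex map label.
#' @param minTyped completeness threshold (NULL = 95% rule).
#' @param lodGroup grouping LOD threshold (default 7.0).
#' @param epsilon,errorLodMax error-scan parameters.
#' @param rfMax,exhaustiveMax see \code{\link{assembleMap}}.
#' @return list: \code{map} (a \linkS4class{GeneticMap}),
#'   \code{genotypes} (corrected, filtered), \code{linkage} (the final
#'   \linkS4class{PairwiseLinkage}), \code{groups}, \code{singletons},
#'   \code{flags} (error-scan table).
#' @export
buildSexMap <- function(gm, sex = "female", minTyped = NULL,
                        lodGroup = 7, epsilon = 0.01, errorLodMax = 2,
                        rfMax = 0.4999, exhaustiveMax = 8) {
  pass <- function(x) {
    x <- filterMissingness(x, minTyped)$genotypes
    pl <- pairwiseLinkage(x)
    grp <- groupMarkers(pl, lodGroup)
    map <- assembleMap(x, pl, grp$groups, sex, rfMax, exhaustiveMax)
    list(genotypes = x, linkage = pl, groups = grp$groups,
         singletons = grp$singletons, map = map)
  }
  p1 <- pass(gm)
  scan <- errorLodScan(p1$map, p1$genotypes, epsilon, errorLodMax)
  p2 <- pass(scan$genotypes)
  c(p2, list(flags = scan$flags))
}

#' Pair female and male linkage groups through shared loci
#'
#' Groups are paired when they share at least \code{minShared} physical
#' loci (bridge markers heterozygous in both parents, or SNP markers
#' co-located in a common locus, both identified by \code{locus_id}).
#' When two or more male groups pair to one female group and any
#' cross-group marker pair reaches \code{mergeLod}, the male groups are
#' merged (the male map should then be rebuilt on the merged grouping).
#'
#' @param femaleMap,maleMap \linkS4class{GeneticMap}s.
#' @param markerInfo data.frame with marker_id and locus_id covering the
#'   markers of both maps (e.g. \code{markerInfo(gm)} of the full
#'   family).
#' @param maleLinkage optional \linkS4class{PairwiseLinkage} for the
#'   male dataset, needed to test cross-group linkage before merging.
#' @param minShared minimum shared loci to call a pairing (default 2).
#' @param mergeLod LOD threshold for merging split male groups
#'   (default 4.0).
#' @return list: \code{pairs}, data.frame (female_group, male_group,
#'   n_shared_loci); \code{merges}, list of male-group index vectors to
#'   merge; \code{maleGroups}, the male grouping after merging (list of
#'   marker-id vectors); \code{unpairedFemale}, \code{unpairedMale}.
#' @export
pairSexMaps <- function(femaleMap, maleMap, markerInfo,
                        maleLinkage = NULL, minShared = 2,
                        mergeLod = 4) {
  loc <- setNames(markerInfo$locus_id, markerInfo$marker_id)
  ftb <- mapTable(femaleMap)
  mtb <- mapTable(maleMap)
  fgrp <- split(ftb$marker_id, ftb$linkage_group)
  mgrp <- split(mtb$marker_id, mtb$linkage_group)
  shared <- matrix(0L, length(fgrp), length(mgrp),
                   dimnames = list(names(fgrp), names(mgrp)))
  for (i in seq_along(fgrp))
    for (j in seq_along(mgrp))
      shared[i, j] <- length(intersect(unique(loc[fgrp[[i]]]),
                                       unique(loc[mgrp[[j]]])))
  # each male group pairs to the female group with most shared loci
  pairs <- data.frame(female_group = integer(), male_group = integer(),
                      n_shared_loci = integer())
  for (j in seq_along(mgrp)) {
    i <- which.max(shared[, j])
    if (shared[i, j] >= minShared)
      pairs <- rbind(pairs, data.frame(
        female_group = i, male_group = j,
        n_shared_loci = shared[i, j]))
  }
  merges <- list()
  for (i in unique(pairs$female_group)) {
    mj <- pairs$male_group[pairs$female_group == i]
    if (length(mj) < 2 || is.null(maleLinkage)) next
    # merge male groups whose members show cross-group linkage
    keepSet <- mj[1]
    for (j in mj[-1]) {
      cross <- maleLinkage@lod[unlist(mgrp[keepSet]), mgrp[[j]],
                               drop = FALSE]
      if (max(cross) >= mergeLod) keepSet <- c(keepSet, j)
    }
    if (length(keepSet) > 1) merges[[length(merges) + 1L]] <- keepSet
  }
  maleGroups <- mgrp
  for (m in merges) {
    maleGroups[[m[1]]] <- sort(unlist(maleGroups[m]))
    maleGroups[m[-1]] <- NULL
  }
  list(pairs = pairs, merges = merges,
       maleGroups = lapply(unname(maleGroups), as.character),
       unpairedFemale = setdiff(seq_along(fgrp), pairs$female_group),
       unpairedMale = setdiff(seq_along(mgrp), pairs$male_group))
}

#' Merge co-segregating markers into unique map positions
#'
#' Markers with zero observed recombinants between them (R = 0 over at
#' least one informative progeny) occupy one map position; binning is the
#' transitive closure of that relation.  The unique-position count m and
#' the mean adjacent-position interval d are the natural inputs to the
#' Chakravarti length correction and the coverage formula when markers
#' stack at shared positions.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param pl the \linkS4class{PairwiseLinkage} behind it.
#' @return data.frame, one row per linkage group: linkage_group,
#'   n_markers, m_positions, length_cM, mean_interval_cM.
#' @export
binCosegregating <- function(map, pl) {
  tb <- mapTable(map)
  out <- lapply(split(tb, tb$linkage_group), function(grp) {
    grp <- grp[order(grp$rank), ]
    ids <- grp$marker_id
    if (length(ids) == 1) {
      m <- 1L
      pos <- grp$position_cM
    } else {
      coseg <- pl@R[ids, ids, drop = FALSE] == 0 &
        pl@N[ids, ids, drop = FALSE] >= 1
      gr <- igraph::graph_from_adjacency_matrix(coseg,
                                                mode = "undirected",
                                                diag = FALSE)
      comp <- igraph::components(gr)
      m <- comp$no
      pos <- vapply(split(grp$position_cM, comp$membership), min,
                    numeric(1))
    }
    pos <- sort(pos)
    data.frame(linkage_group = grp$linkage_group[1],
               n_markers = length(ids), m_positions = m,
               length_cM = max(grp$position_cM),
               mean_interval_cM = if (m > 1) mean(diff(pos)) else NA)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarise a genetic map: lengths, corrected lengths, coverage
#'
#' Applies the Chakravarti correction (m+1)/(m-1) per linkage group and
#' the coverage formula c = 1 - exp(-2dn/L).  By default m counts unique
#' co-segregation-binned positions (see \code{\link{binCosegregating}});
#' set \code{useUniquePositions = FALSE} to use raw marker counts.  The
#' average interval d is the total observed length divided by the number
#' of adjacent intervals, and coverage uses the corrected total length.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param pl the matching \linkS4class{PairwiseLinkage} (required for
#'   unique-position counts).
#' @param useUniquePositions logical; bin co-segregating markers before
#'   computing m and d.
#' @return list with \code{per_group} (linkage_group, n_markers, m,
#'   length_cM, corrected_cM) and \code{totals} (observed_cM,
#'   corrected_cM, n_markers, d_cM, coverage).
#' @export
mapSummary <- function(map, pl = NULL, useUniquePositions = TRUE) {
  tb <- mapTable(map)
  if (useUniquePositions) {
    if (is.null(pl))
      stop("unique-position summary needs the PairwiseLinkage")
    bins <- binCosegregating(map, pl)
    m <- bins$m_positions
    len <- bins$length_cM
    nm <- bins$n_markers
    grp <- bins$linkage_group
  } else {
    grp <- as.integer(names(split(tb, tb$linkage_group)))
    nm <- vapply(split(tb, tb$linkage_group), nrow, integer(1))
    len <- vapply(split(tb$position_cM, tb$linkage_group), max,
                  numeric(1))
    m <- nm
  }
  corr <- correctedLength(len, m)
  nUnits <- sum(m)
  d <- sum(len) / max(sum(m - 1), 1)
  cov <- genomeCoverage(d, nUnits, corr$total)
  list(per_group = data.frame(linkage_group = grp, n_markers = nm,
                              m = m, length_cM = len,
                              corrected_cM = corr$per_group),
       totals = list(observed_cM = sum(len),
                     corrected_cM = corr$total,
                     n_markers = sum(nm), m = nUnits, d_cM = d,
                     coverage = cov))
}
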