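#' Assign markers to scaffolds with the two-fold bit-score rule
#'
#' Hits with E-value above \code{evalueMax} are discarded.  For each
#' marker the remaining hits are collapsed to the best bit score per
#' scaffold; the marker is assigned to the top-scoring scaffold unless a
#' second scaffold scores within a factor of \code{ratio} (default 2) of
#' the best, in which case the assignment is ambiguous and withheld.
#' Multiple passing hits to the same scaffold never block assignment.
#'
#' @param hits data.frame with at least columns qseqid, sseqid, evalue,
#'   bitscore (BLAST outfmt-6 names, see \code{\link{readHitTable}}).
#' @param evalueMax E-value cutoff (default 1e-20).
#' @param ratio required best/second bit-score ratio (default 2).
#' @return data.frame: marker_id, scaffold_id (NA unless assigned),
#'   status ("assigned", "ambiguous" or "no_hit"), best_bit,
#'   second_bit.  Row order follows sorted marker id, so the result is
#'   invariant to hit-record input order.
#' @export
assignMarkers <- function(hits, evalueMax = 1e-20, ratio = 2) {
  keep <- hits$evalue <= evalueMax
  byq <- split(hits[keep, c("sseqid", "bitscore")], hits$qseqid[keep])
  res <- lapply(sort(unique(hits$qseqid)), function(q) {
    h <- byq[[q]]
    if (is.null(h) || !nrow(h))
      return(data.frame(marker_id = q, scaffold_id = NA_character_,
                        status = "no_hit", best_bit = NA_real_,
                        second_bit = NA_real_))
    perScf <- vapply(split(h$bitscore, h$sseqid), max, numeric(1))
    perScf <- sort(perScf, decreasing = TRUE)
    best <- perScf[1]
    second <- if (length(perScf) > 1) perScf[2] else NA_real_
    ambiguous <- length(perScf) > 1 && best < ratio * second
    data.frame(marker_id = q,
               scaffold_id = if (ambiguous) NA_character_ else
                 names(perScf)[1],
               status = if (ambiguous) "ambiguous" else "assigned",
               best_bit = best, second_bit = second)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# marker-level anchor table: assignment joined with map positions
anchorPoints <- function(assignments, map) {
  tb <- mapTable(map)
  a <- assignments[assignments$status == "assigned", ]
  i <- match(a$marker_id, tb$marker_id)
  ok <- !is.na(i)
  data.frame(marker_id = a$marker_id[ok],
             scaffold_id = a$scaffold_id[ok],
             linkage_group = tb$linkage_group[i[ok]],
             position_cM = tb$position_cM[i[ok]])
}

#' Summarise scaffold anchors on the sex maps
#'
#' Joins marker assignments with map positions and aggregates per
#' scaffold: the linkage group(s) its markers map to per sex and a
#' single anchor position per sex, the median cM of its markers (robust
#' to a single bad marker).  A scaffold whose markers span more than one
#' linkage group in either sex is conflict-flagged.
#'
#' @param assignments output of \code{\link{assignMarkers}}.
#' @param femaleMap,maleMap \linkS4class{GeneticMap}s (maleMap may be
#'   NULL).
#' @param scaffoldLengths data.frame with scaffold_id and length_bp.
#' @return data.frame, one row per scaffold with any anchor:
#'   scaffold_id, length_bp, n_markers, female_group, female_cM,
#'   male_group, male_cM (NA where unanchored on that sex), conflict.
#' @export
anchorScaffolds <- function(assignments, femaleMap, maleMap = NULL,
                            scaffoldLengths) {
  fap <- anchorPoints(assignments, femaleMap)
  map <- if (!is.null(maleMap)) anchorPoints(assignments, maleMap) else
    fap[0, ]
  scfs <- sort(unique(c(fap$scaffold_id, map$scaffold_id)))
  one <- function(s) {
    f <- fap[fap$scaffold_id == s, ]
    m <- map[map$scaffold_id == s, ]
    fg <- unique(f$linkage_group)
    mg <- unique(m$linkage_group)
    data.frame(
      scaffold_id = s,
      length_bp = scaffoldLengths$length_bp[
        match(s, scaffoldLengths$scaffold_id)],
      n_markers = length(unique(c(f$marker_id, m$marker_id))),
      female_group = if (length(fg) == 1) fg else NA_integer_,
      female_cM = if (length(fg) == 1) median(f$position_cM) else
        NA_real_,
      male_group = if (length(mg) == 1) mg else NA_integer_,
      male_cM = if (length(mg) == 1) median(m$position_cM) else NA_real_,
      conflict = length(fg) > 1 || length(mg) > 1)
  }
  out <- do.call(rbind, lapply(scfs, one))
  rownames(out) <- NULL
  out
}

#' Order anchored scaffolds along linkage groups
#'
#' Implements the female-first ordering rule: (1) scaffolds with
#' distinct female anchor positions are ranked by female cM; (2) when
#' several scaffolds share one female anchor position, the tied set is
#' ranked by the male map only if the male map genetically separates
#' those scaffolds and their summed length exceeds the longest scaffold
#' at that position — otherwise only the longest scaffold is ranked and
#' the rest stay anchored-but-unordered; (3) scaffolds anchored only on
#' the male map are never ranked (their order against female-only
#' scaffolds is indeterminate); (4) orientation is always unknown.
#' Conflict-flagged scaffolds are excluded from ordering.
#'
#' @param anchored output of \code{\link{anchorScaffolds}}.
#' @return data.frame (AGP-like): linkage_group, rank (NA unless
#'   ordered), scaffold_id, length_bp, orientation ("?"),
#'   anchor_cM_female, anchor_cM_male, status ("ordered",
#'   "anchored_unordered", "male_only" or "conflict").
#' @export
orderScaffolds <- function(anchored) {
  rows <- list()
  addRow <- function(grp, rank, s, status) {
    i <- match(s, anchored$scaffold_id)
    rows[[length(rows) + 1L]] <<- data.frame(
      linkage_group = grp, rank = rank, scaffold_id = s,
      length_bp = anchored$length_bp[i], orientation = "?",
      anchor_cM_female = anchored$female_cM[i],
      anchor_cM_male = anchored$male_cM[i], status = status)
  }
  for (s in anchored$scaffold_id[anchored$conflict])
    addRow(NA_integer_, NA_integer_, s, "conflict")
  ok <- anchored[!anchored$conflict, ]
  maleOnly <- ok[is.na(ok$female_group) & !is.na(ok$male_group), ]
  for (i in seq_len(nrow(maleOnly)))
    addRow(maleOnly$male_group[i], NA_integer_,
           maleOnly$scaffold_id[i], "male_only")
  fem <- ok[!is.na(ok$female_group), ]
  for (g in sort(unique(fem$female_group))) {
    sub <- fem[fem$female_group == g, ]
    rank <- 0L
    for (p in sort(unique(sub$female_cM))) {
      tied <- sub[sub$female_cM == p, ]
      tied <- tied[order(-tied$length_bp, tied$scaffold_id), ]
      if (nrow(tied) == 1) {
        rank <- rank + 1L
        addRow(g, rank, tied$scaffold_id, "ordered")
        next
      }
      sep <- tied[!is.na(tied$male_cM), ]
      separable <- nrow(sep) >= 2 &&
        !anyDuplicated(sep$male_cM)
      if (separable && sum(sep$length_bp) > max(tied$length_bp)) {
        sep <- sep[order(sep$male_cM, sep$scaffold_id), ]
        for (s in sep$scaffold_id) {
          rank <- rank + 1L
          addRow(g, rank, s, "ordered")
        }
        for (s in setdiff(tied$scaffold_id, sep$scaffold_id))
          addRow(g, NA_integer_, s, "anchored_unordered")
      } else {
        rank <- rank + 1L
        addRow(g, rank, tied$scaffold_id[1], "ordered")
        for (s in tied$scaffold_id[-1])
          addRow(g, NA_integer_, s, "anchored_unordered")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$linkage_group, out$rank, out$scaffold_id), ]
}

#' Report scaffolds whose markers disagree with the maps
#'
#' Flags scaffolds whose assigned markers map to more than one linkage
#' group (inter-group conflict, a likely misassembly) or to loci
#' separated by more than \code{intraMax} cM within one group
#' (intra-group conflict).
#'
#' @param assignments output of \code{\link{assignMarkers}}.
#' @param maps list of \linkS4class{GeneticMap}s to check against.
#' @param intraMax intra-group distance threshold in cM (default 20).
#' @return data.frame: scaffold_id, n_markers, n_groups, max_span_cM,
#'   inter_group, intra_group.
#' @export
detectConflicts <- function(assignments, maps, intraMax = 20) {
  pts <- do.call(rbind, lapply(maps, function(m)
    cbind(anchorPoints(assignments, m), sex = m@sex)))
  out <- lapply(split(pts, pts$scaffold_id), function(p) {
    spans <- vapply(split(p, paste(p$sex, p$linkage_group)),
                    function(q) diff(range(q$position_cM)), numeric(1))
    nGrpPerSex <- vapply(split(p, p$sex),
                         function(q) length(unique(q$linkage_group)),
                         integer(1))
    data.frame(scaffold_id = p$scaffold_id[1],
               n_markers = length(unique(p$marker_id)),
               n_groups = max(nGrpPerSex),
               max_span_cM = max(spans),
               inter_group = any(nGrpPerSex > 1),
               intra_group = any(spans > intraMax))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
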