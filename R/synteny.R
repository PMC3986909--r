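#' Build an Oxford grid from a conserved-segment table
#'
#' Cell (i, j) counts the segments assigned to chromosome i of species A
#' and chromosome j of species B.  Segments unplaced in either species
#' (NA or "NA") are excluded and counted, so grid total + excluded equals
#' the table size.
#'
#' @param segments data.frame with a segment id column and one
#'   chromosome-assignment column per species.
#' @param speciesA,speciesB column names holding the two assignments
#'   (defaults "chrA", "chrB"); also used as species labels.
#' @return an \linkS4class{OxfordGrid}.
#' @export
buildGrid <- function(segments, speciesA = "chrA", speciesB = "chrB") {
  a <- segments[[speciesA]]
  b <- segments[[speciesB]]
  unplaced <- is.na(a) | is.na(b) | a == "NA" | b == "NA"
  counts <- unclass(table(a[!unplaced], b[!unplaced]))
  counts <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  new("OxfordGrid", counts = counts, species = c(speciesA, speciesB),
      nExcluded = sum(unplaced))
}

#' Classify syntenic boxes in an Oxford grid
#'
#' A syntenic box is any single grid cell holding at least \code{tBox}
#' segment pairs; a highly syntenic box holds at least \code{tHigh}.
#' Percentages follow the convention in-box / total gridded segments,
#' rounded to integer percent.
#'
#' @param grid an \linkS4class{OxfordGrid} or count matrix.
#' @param tBox box threshold (default 6).
#' @param tHigh high-box threshold (default 16).
#' @return list: n_boxes, in_box, in_box_pct, n_high_boxes, in_high,
#'   in_high_pct, out_of_box, out_pct, total.
#' @export
classifyBoxes <- function(grid, tBox = 6, tHigh = 16) {
  stopifnot(tBox >= 1)
  m <- if (is(grid, "OxfordGrid")) gridCounts(grid) else grid
  total <- sum(m)
  box <- m >= tBox
  high <- m >= tHigh
  pct <- function(x) if (total > 0) round(100 * x / total) else 0
  list(n_boxes = sum(box), in_box = sum(m[box]),
       in_box_pct = pct(sum(m[box])),
       n_high_boxes = sum(high), in_high = sum(m[high]),
       in_high_pct = pct(sum(m[high])),
       out_of_box = total - sum(m[box]),
       out_pct = pct(total - sum(m[box])), total = total)
}

#' Detect one-to-two chromosome correspondences
#'
#' For each outgroup chromosome (grid row), reports the two focal
#' chromosomes with the largest segment counts when together they hold
#' at least \code{minFraction} of the row total and each holds at least
#' \code{minCount} segments — the signature of a chromosome pair
#' descending from one pre-duplication chromosome.
#'
#' @param grid an \linkS4class{OxfordGrid} or count matrix with outgroup
#'   chromosomes as rows.
#' @param minFraction minimum joint share of the row (default 0.75).
#' @param minCount minimum per-chromosome count (default 3).
#' @return data.frame: outgroup_chrom, focal_1, focal_2, count_1,
#'   count_2, row_total.
#' @export
detectOneToTwo <- function(grid, minFraction = 0.75, minCount = 3) {
  m <- if (is(grid, "OxfordGrid")) gridCounts(grid) else grid
  out <- list()
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    tot <- sum(row)
    if (tot == 0 || ncol(m) < 2) next
    o <- order(-row, colnames(m))
    c1 <- row[o[1]]
    c2 <- row[o[2]]
    if (c1 >= minCount && c2 >= minCount &&
        (c1 + c2) >= minFraction * tot)
      out[[length(out) + 1L]] <- data.frame(
        outgroup_chrom = rownames(m)[i],
        focal_1 = colnames(m)[o[1]], focal_2 = colnames(m)[o[2]],
        count_1 = c1, count_2 = c2, row_total = tot)
  }
  if (!length(out))
    return(data.frame(outgroup_chrom = character(),
                      focal_1 = character(), focal_2 = character(),
                      count_1 = numeric(), count_2 = numeric(),
                      row_total = numeric()))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect ohnolog chromosome quadruplets
#'
#' A quadruplet (F1/F2 - S1/S2) is the two-to-two pattern expected of
#' chromosomes descending from one pre-duplication chromosome: both
#' members of a focal chromosome pair share at least \code{minCount}
#' segments with both members of a sister-species paralogous pair.
#' Detection is symmetric in the orderings within each pair.
#'
#' @param grid focal-vs-sister \linkS4class{OxfordGrid} or count matrix
#'   (focal chromosomes as rows).
#' @param focalPairs data.frame with columns focal_1, focal_2 (e.g. from
#'   \code{\link{detectOneToTwo}} against an unduplicated outgroup).
#' @param sisterPairs data.frame with columns sister_1, sister_2, the
#'   known paralogous chromosome pairs of the sister species.
#' @param minCount minimum segments per supporting cell (default 3).
#' @return data.frame: focal_1, focal_2, sister_1, sister_2 and the four
#'   supporting cell counts.
#' @export
detectOhnologQuadruplets <- function(grid, focalPairs, sisterPairs,
                                     minCount = 3) {
  m <- if (is(grid, "OxfordGrid")) gridCounts(grid) else grid
  cellOf <- function(f, s)
    if (f %in% rownames(m) && s %in% colnames(m)) m[f, s] else 0
  out <- list()
  for (i in seq_len(nrow(focalPairs)))
    for (j in seq_len(nrow(sisterPairs))) {
      f1 <- focalPairs$focal_1[i]
      f2 <- focalPairs$focal_2[i]
      s1 <- sisterPairs$sister_1[j]
      s2 <- sisterPairs$sister_2[j]
      cc <- c(cellOf(f1, s1), cellOf(f1, s2), cellOf(f2, s1),
              cellOf(f2, s2))
      if (all(cc >= minCount))
        out[[length(out) + 1L]] <- data.frame(
          focal_1 = f1, focal_2 = f2, sister_1 = s1, sister_2 = s2,
          n_f1s1 = cc[1], n_f1s2 = cc[2], n_f2s1 = cc[3],
          n_f2s2 = cc[4])
    }
  if (!length(out))
    return(data.frame(focal_1 = character(), focal_2 = character(),
                      sister_1 = character(), sister_2 = character(),
                      n_f1s1 = numeric(), n_f1s2 = numeric(),
                      n_f2s1 = numeric(), n_f2s2 = numeric()))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
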