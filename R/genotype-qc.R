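#' @describeIn GenotypeMatrix subset markers (i) and individuals (j).
#' @param x,i,j,drop,... matrix-style subsetting arguments; \code{i} may
#'   be marker ids, indices or a logical vector.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nMarkers(x))
  if (is.character(i)) i <- match(i, x@markerInfo$marker_id)
  if (missing(j)) j <- seq_len(nIndividuals(x))
  new("GenotypeMatrix", geno = x@geno[i, j, drop = FALSE],
      markerInfo = x@markerInfo[i, , drop = FALSE])
})

#' Recode to the pseudo-testcross convention
#'
#' Under the backcross model a "B/H" segregation type is a synonym of
#' "A/H", so every "B" call becomes "A".  Idempotent; everything else is
#' untouched.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @return the recoded \linkS4class{GenotypeMatrix}.
#' @export
recodePseudoTestcross <- function(gm) {
  g <- gm@geno
  g[!is.na(g) & g == "B"] <- "A"
  initialize(gm, geno = g)
}

#' Filter markers by genotyping completeness
#'
#' Keeps markers with at least \code{minTyped} non-missing calls.  The
#' default reproduces a ">95% of individuals" rule,
#' \code{ceiling(0.95 * n)} (88 when n = 92).
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param minTyped minimum non-missing calls; NULL for the 95% default.
#' @return list with \code{genotypes} (filtered matrix),
#'   \code{retained} and \code{dropped} marker ids.
#' @export
filterMissingness <- function(gm, minTyped = NULL) {
  n <- nIndividuals(gm)
  if (is.null(minTyped)) minTyped <- ceiling(0.95 * n)
  stopifnot(minTyped >= 0, minTyped <= n)
  typed <- rowSums(!is.na(gm@geno))
  keep <- typed >= minTyped
  list(genotypes = gm[which(keep)],
       retained = gm@markerInfo$marker_id[keep],
       dropped = gm@markerInfo$marker_id[!keep])
}

#' Mendelian segregation-distortion test
#'
#' Chi-square goodness-of-fit of the homozygote:heterozygote counts
#' against the 1:1 backcross expectation, one degree of freedom, no
#' continuity correction: chi2 = (nA - nH)^2 / (nA + nH).  Markers with
#' P below \code{alpha} are flagged for exclusion.  Only non-missing
#' calls enter the counts; "A" and "B" both count as the homozygous
#' class.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param alpha exclusion threshold on the p-value (default 0.001,
#'   equivalently chi2 > 10.828).
#' @return data.frame: marker_id, count_A, count_H, chi_square, p_value,
#'   excluded.  Markers with zero informative calls get NA statistics,
#'   are flagged excluded, and raise a warning.
#' @export
segregationTest <- function(gm, alpha = 0.001) {
  g <- gm@geno
  nH <- rowSums(!is.na(g) & g == "H")
  nA <- rowSums(!is.na(g) & g != "H")
  tot <- nA + nH
  chi <- ifelse(tot > 0, (nA - nH)^2 / tot, NA_real_)
  p <- pchisq(chi, df = 1, lower.tail = FALSE)
  excl <- ifelse(is.na(p), TRUE, p < alpha)
  if (any(tot == 0))
    warning(sum(tot == 0),
            " marker(s) with no informative calls dropped")
  data.frame(marker_id = gm@markerInfo$marker_id,
             count_A = nA, count_H = nH, chi_square = chi,
             p_value = p, excluded = excl, row.names = NULL)
}

#' Split a genotype matrix into sex-specific pseudo-testcross datasets
#'
#' Dam-informative markers segregate through the female map and
#' sire-informative markers through the male map; markers heterozygous in
#' both parents are copied into both datasets and flagged as bridge
#' markers for pairing the sex maps.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @return list with \code{dam} and \code{sire}
#'   \linkS4class{GenotypeMatrix} objects and \code{bridge}, the ids of
#'   both-informative markers.
#' @export
splitByParent <- function(gm) {
  ip <- gm@markerInfo$informative_parent
  bad <- !(ip %in% PARENT_CODES)
  if (any(bad)) {
    warning("dropping ", sum(bad),
            " marker(s) with unknown parent label")
    gm <- gm[which(!bad)]
    ip <- ip[!bad]
  }
  list(dam = gm[which(ip %in% c("dam", "both"))],
       sire = gm[which(ip %in% c("sire", "both"))],
       bridge = gm@markerInfo$marker_id[ip == "both"])
}

#' Run the full genotype-QC funnel
#'
#' Recodes B to A, drops markers under the completeness threshold, tests
#' segregation distortion, removes distorted markers (they are retained
#' in the audit report) and splits the survivors by informative parent.
#'
#' @param gm raw \linkS4class{GenotypeMatrix}.
#' @param minTyped completeness threshold (NULL = 95% rule).
#' @param distortionP distortion exclusion p-value (default 0.001).
#' @return list: \code{dam}, \code{sire}, \code{bridge} as in
#'   \code{\link{splitByParent}}; \code{report}, the per-marker QC table
#'   (marker_id, n_typed, chi_square, p_value, action); \code{funnel},
#'   named marker counts after each step.
#' @export
applyGenotypeQC <- function(gm, minTyped = NULL, distortionP = 0.001) {
  n0 <- nMarkers(gm)
  gm <- recodePseudoTestcross(gm)
  fm <- filterMissingness(gm, minTyped)
  dist <- segregationTest(fm$genotypes, distortionP)
  keep <- dist$marker_id[!dist$excluded]
  out <- fm$genotypes[keep]
  typedAll <- rowSums(!is.na(gm@geno))
  report <- data.frame(
    marker_id = gm@markerInfo$marker_id,
    n_typed = typedAll,
    chi_square = dist$chi_square[match(gm@markerInfo$marker_id,
                                       dist$marker_id)],
    p_value = dist$p_value[match(gm@markerInfo$marker_id,
                                 dist$marker_id)],
    action = ifelse(gm@markerInfo$marker_id %in% keep, "retained",
                    ifelse(gm@markerInfo$marker_id %in% fm$dropped,
                           "dropped_missingness", "dropped_distortion")))
  c(splitByParent(out),
    list(report = report,
         funnel = c(input = n0, after_missingness = length(fm$retained),
                    after_distortion = length(keep))))
}
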