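#' Genotyping noise model
#'
#' Per-call missingness and symmetric genotype error (a called genotype is
#' flipped to the other backcross class, homozygote <-> heterozygote).
#' Stands in for the real genotyping noise that error-LOD masking
#' corrects.
#'
#' @param missingRate probability a call is missing, in [0, 1] (1 masks
#'   everything).
#' @param errorRate probability a called genotype is flipped, in [0, 1).
#' @return a list of class \code{"NoiseModel"}.
#' @export
noiseModel <- function(missingRate = 0.02, errorRate = 0.01) {
  stopifnot(missingRate >= 0, missingRate <= 1,
            errorRate >= 0, errorRate < 1)
  structure(list(missingRate = missingRate, errorRate = errorRate),
            class = "NoiseModel")
}

#' Simulate a pseudo-testcross mapping family
#'
#' Generates backcross-coded genotypes for a full-sib family from a true
#' marker map.  For each parent, progeny and chromosome, the transmitted
#' parental phase is a two-state chain along the ordered loci whose switch
#' probability between adjacent loci is the inverse-Kosambi recombination
#' fraction of the interval (a modelling simplification that makes
#' adjacent recombination fractions exactly consistent with the Kosambi
#' convention; no crossover interference beyond it).
#'
#' Each locus of the true map is informative in the dam, the sire, or
#' both.  A both-informative locus is emitted as a co-located pair of
#' markers (a dam-read and a sire-read sharing the \code{locus_id}),
#' mirroring SNPs co-located in a common RAD locus; such shared loci are
#' what pairs the sex maps.  Markers are coded "A"/"H" or, for a random
#' half of markers, "B"/"H" (the homozygous class may be the alternate
#' allele, as in raw SNP calls); genotype errors then flip
#' homozygote <-> heterozygote with \code{errorRate} and calls are masked
#' with \code{missingRate}.
#'
#' @param trueMap true map data.frame (chrom, marker_id, pos_cM, pos_bp)
#'   from \code{\link{simulateGenome}}; each row is one locus.
#' @param nProgeny number of progeny (>= 2); default 92, a typical
#'   full-sib family.
#' @param noise a \code{\link{noiseModel}}.
#' @param parentProbs probabilities that a locus is dam-, sire- or
#'   both-informative.
#' @param snpsPerLocus mean SNP markers emitted per locus (1 to 2; the
#'   excess over 1 is the probability of a second, co-located marker).
#'   Restriction-site loci of ~100 bp typically carry more than one
#'   segregating site (about 1.5 on real ddRAD data), and the resulting
#'   zero-recombination marker stacks are what give the error-LOD scan
#'   the tight flanking intervals it needs; the default reproduces
#'   that.
#' @param seed integer seed.
#' @return list with \code{genotypes}, a \linkS4class{GenotypeMatrix},
#'   and \code{markerTruth}, a data.frame (marker_id, locus_id, chrom,
#'   pos_cM, pos_bp, informative_parent, hom_code) with the generating
#'   truth for each emitted marker.
#' @export
simulateFamily <- function(trueMap, nProgeny = 92,
                           noise = noiseModel(),
                           parentProbs = c(dam = 0.375, sire = 0.375,
                                           both = 0.25),
                           snpsPerLocus = 1.5, seed = 1L) {
  if (nProgeny < 2) stop("need at least 2 progeny")
  stopifnot(snpsPerLocus >= 1, snpsPerLocus <= 2)
  set.seed(seed)
  parentProbs <- parentProbs / sum(parentProbs)
  locType <- sample(names(parentProbs), nrow(trueMap), replace = TRUE,
                    prob = parentProbs)

  # transmitted phase per parent: one chain over all loci per chromosome
  chain <- function() {
    states <- matrix(0L, nrow(trueMap), nProgeny)
    for (ch in split(seq_len(nrow(trueMap)), trueMap$chrom)) {
      pos <- trueMap$pos_cM[ch]
      r <- inverseKosambi(diff(pos))
      sw <- rbind(sample(0:1, nProgeny, replace = TRUE),
                  matrix(as.integer(
                    runif((length(ch) - 1L) * nProgeny) <
                      rep(r, nProgeny)),
                    length(ch) - 1L, nProgeny))
      states[ch, ] <- apply(sw, 2, cumsum) %% 2L
    }
    states
  }
  damState <- chain()
  sireState <- chain()

  # expand loci into emitted markers; a locus may carry a second
  # co-located SNP tracking the same parental chain
  twin <- runif(nrow(trueMap)) < (snpsPerLocus - 1)
  emit <- list()
  for (i in seq_len(nrow(trueMap))) {
    parents <- switch(locType[i], dam = "dam", sire = "sire",
                      both = c("dam", "sire"))
    for (p in parents) {
      suffix <- if (locType[i] == "both")
        paste0("_", substr(p, 1, 1)) else ""
      for (s in seq_len(1L + twin[i])) {
        snpTag <- if (twin[i]) c("a", "b")[s] else ""
        emit[[length(emit) + 1L]] <- data.frame(
          locus_row = i,
          marker_id = paste0(trueMap$marker_id[i], suffix, snpTag),
          locus_id = trueMap$marker_id[i],
          chrom = trueMap$chrom[i], pos_cM = trueMap$pos_cM[i],
          pos_bp = trueMap$pos_bp[i], informative_parent = p)
      }
    }
  }
  truth <- do.call(rbind, emit)
  truth$hom_code <- sample(c("A", "B"), nrow(truth), replace = TRUE)

  state <- matrix(0L, nrow(truth), nProgeny)
  isDam <- truth$informative_parent == "dam"
  state[isDam, ] <- damState[truth$locus_row[isDam], , drop = FALSE]
  state[!isDam, ] <- sireState[truth$locus_row[!isDam], , drop = FALSE]

  # apply noise: symmetric flips, then missingness
  flip <- matrix(runif(length(state)) < noise$errorRate, nrow(state))
  state <- (state + flip) %% 2L
  geno <- ifelse(state == 1L, "H", truth$hom_code)
  geno[matrix(runif(length(geno)) < noise$missingRate,
              nrow(geno))] <- NA_character_
  dimnames(geno) <- list(truth$marker_id,
                         sprintf("ind%03d", seq_len(nProgeny)))
  gm <- GenotypeMatrix(geno,
                       informative_parent = truth$informative_parent,
                       marker_id = truth$marker_id,
                       locus_id = truth$locus_id)
  truth$locus_row <- NULL
  rownames(truth) <- NULL
  list(genotypes = gm, markerTruth = truth)
}
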