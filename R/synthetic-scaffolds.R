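#' Fragment a simulated genome into scaffolds with a synthetic hit table
#'
#' Tiles each chromosome with non-overlapping scaffold intervals (an
#' exact tiling: lengths sum to the chromosome length), records which
#' scaffold carries each marker, and emits a similarity hit table in
#' which each marker hits its true scaffold with a high bit score.  A
#' configurable fraction of markers receive a second, decoy hit on
#' another scaffold whose true-to-decoy bit-score ratio is drawn
#' uniformly from a range spanning 2.0, so the two-fold ambiguity rule is
#' exercised on both sides: a marker whose ratio is below 2 must be left
#' unassigned, one at or above 2 must still be assigned to the true
#' scaffold.
#'
#' @param genome output of \code{\link{simulateGenome}} (spec + true
#'   map).
#' @param scaffoldsPerChromosome number of scaffolds each chromosome is
#'   broken into.
#' @param anchoredFraction fraction of markers that receive any hit at
#'   all (markers without hits emulate loci whose sequence finds no
#'   scaffold).
#' @param decoyFraction fraction of hit markers that also get a decoy
#'   hit.
#' @param decoyRatioRange range of the true/decoy bit-score ratio,
#'   uniform draw; default c(1.2, 2.8) straddles the two-fold rule.
#' @param seed integer seed.
#' @return list: \code{scaffolds} (scaffold_id, chrom, start, end,
#'   length_bp), \code{markerTruth} (marker_id, scaffold_id,
#'   decoy_scaffold, decoy_ratio; NA where absent), and \code{hits}, a
#'   12-column BLAST-outfmt6-style data.frame.
#' @export
fragmentIntoScaffolds <- function(genome, scaffoldsPerChromosome = 10,
                                  anchoredFraction = 1,
                                  decoyFraction = 0,
                                  decoyRatioRange = c(1.2, 2.8),
                                  seed = 1L) {
  set.seed(seed)
  spec <- genome$spec
  map <- genome$map
  scf <- list()
  for (k in seq_len(spec$nChromosomes)) {
    L <- spec$lengthsBp[k]
    nS <- min(scaffoldsPerChromosome, L)
    cuts <- if (nS > 1) sort(sample(L - 1L, nS - 1L)) else integer()
    start <- c(1, cuts + 1)
    end <- c(cuts, L)
    scf[[k]] <- data.frame(
      scaffold_id = sprintf("scf%02d_%03d", k, seq_len(nS)),
      chrom = k, start = start, end = end,
      length_bp = end - start + 1)
  }
  scf <- do.call(rbind, scf)
  rownames(scf) <- NULL

  # marker -> containing scaffold
  truthScf <- vapply(seq_len(nrow(map)), function(i) {
    cand <- scf$chrom == map$chrom[i] & scf$start <= map$pos_bp[i] &
      scf$end >= map$pos_bp[i]
    scf$scaffold_id[which(cand)[1]]
  }, character(1))

  hasHit <- runif(nrow(map)) < anchoredFraction
  hasDecoy <- hasHit & runif(nrow(map)) < decoyFraction
  trueBit <- round(runif(nrow(map), 180, 220), 1)
  ratio <- runif(nrow(map), decoyRatioRange[1], decoyRatioRange[2])
  decoyScf <- rep(NA_character_, nrow(map))

  mkHit <- function(q, s, bit, e, sstart) data.frame(
    qseqid = q, sseqid = s, pident = 98, length = 100, mismatch = 2,
    gapopen = 0, qstart = 1, qend = 100, sstart = sstart,
    send = sstart + 99, evalue = e, bitscore = bit)
  hits <- list()
  for (i in which(hasHit)) {
    srow <- match(truthScf[i], scf$scaffold_id)
    hits[[length(hits) + 1L]] <- mkHit(
      map$marker_id[i], truthScf[i], trueBit[i], 1e-40,
      map$pos_bp[i] - scf$start[srow] + 1)
    if (hasDecoy[i]) {
      other <- sample(setdiff(seq_len(nrow(scf)), srow), 1)
      decoyScf[i] <- scf$scaffold_id[other]
      hits[[length(hits) + 1L]] <- mkHit(
        map$marker_id[i], decoyScf[i],
        round(trueBit[i] / ratio[i], 1), 1e-30,
        sample(max(scf$length_bp[other] - 99, 1), 1))
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    mkHit(character(), character(), numeric(), numeric(), integer())[0, ]
  list(scaffolds = scf,
       markerTruth = data.frame(
         marker_id = map$marker_id, chrom = map$chrom,
         scaffold_id = ifelse(hasHit, truthScf, NA),
         decoy_scaffold = decoyScf,
         decoy_ratio = ifelse(hasDecoy, ratio, NA)),
       hits = hits)
}
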