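#' Specification of a synthetic genome
#'
#' Describes the karyotype used by the simulators: chromosome count and
#' per-chromosome physical (bp) and genetic (cM) lengths.  The defaults
#' emulate a 19-chromosome diploid karyotype (2n = 38) with chromosomes of
#' roughly 60 Mb and 92 cM, the scale of an eel-like teleost map.
#'
#' @param nChromosomes number of chromosomes (>= 1).
#' @param lengthsBp per-chromosome physical lengths in bp.
#' @param lengthsCM per-chromosome genetic lengths in cM.
#' @param seed integer seed stored with the spec and used by
#'   \code{\link{simulateGenome}}.
#' @return a list of class \code{"GenomeSpec"}.
#' @export
genomeSpec <- function(nChromosomes = 19,
                       lengthsBp = rep(6e7, nChromosomes),
                       lengthsCM = rep(92, nChromosomes),
                       seed = 1L) {
  stopifnot(nChromosomes >= 1,
            length(lengthsBp) == nChromosomes,
            length(lengthsCM) == nChromosomes)
  if (any(lengthsBp <= 0) || any(lengthsCM <= 0))
    stop("all chromosome lengths must be positive")
  structure(list(nChromosomes = as.integer(nChromosomes),
                 lengthsBp = lengthsBp, lengthsCM = lengthsCM,
                 seed = as.integer(seed)),
            class = "GenomeSpec")
}

#' Restriction enzymes used for double digestion
#'
#' An enzyme is a recognition site plus the cut offset: the number of
#' bases of the site left of the cut.  \code{enzymeBamHI()} is G|GATCC
#' (offset 1), \code{enzymeMspI()} is C|CGG (offset 1).
#'
#' @param site recognition sequence (non-empty character).
#' @param cutAfter bases of the site preceding the cut (0..nchar(site)).
#' @return list with elements \code{site} and \code{cutAfter}.
#' @name enzymes
NULL

#' @rdname enzymes
#' @export
restrictionEnzyme <- function(site, cutAfter) {
  stopifnot(nchar(site) >= 1, cutAfter >= 0, cutAfter <= nchar(site))
  list(site = toupper(site), cutAfter = as.integer(cutAfter))
}

#' @rdname enzymes
#' @export
enzymeBamHI <- function() restrictionEnzyme("GGATCC", 1L)

#' @rdname enzymes
#' @export
enzymeMspI <- function() restrictionEnzyme("CCGG", 1L)

# all cut positions of an enzyme on a sequence: a cut at position p falls
# between bases p and p+1 (1-based). Overlapping site matches are found.
enzymeCuts <- function(seq, enzyme) {
  hits <- Biostrings::matchPattern(enzyme$site, seq)
  BiocGenerics::start(hits) + enzyme$cutAfter - 1L
}

#' In-silico double digestion with size selection
#'
#' Cuts a sequence with two restriction enzymes and returns the fragments
#' bounded by one cut of each enzyme (in either order along the sequence,
#' with no internal cut of either enzyme) whose length falls in the
#' size-selection window.  These are the loci a ddRAD library recovers.
#' Coordinates are 1-based inclusive.
#'
#' @param seq a \code{DNAString} or single character string.
#' @param enzyme1,enzyme2 enzymes from \code{\link{restrictionEnzyme}};
#'   defaults BamHI (G|GATCC) and MspI (C|CGG).
#' @param sizeWindow numeric(2), inclusive fragment-length window in bp;
#'   the default 120-180 bp models a tight gel size selection around
#'   150 bp.
#' @return list with \code{fragments} (data.frame start, end, length,
#'   left_enzyme, right_enzyme) and \code{cutCounts} (named counts of cut
#'   sites per enzyme).
#' @examples
#' digestGenome("AAGGATCCTTTTCCGGAA", sizeWindow = c(5, 15))
#' @export
digestGenome <- function(seq, enzyme1 = enzymeBamHI(),
                         enzyme2 = enzymeMspI(),
                         sizeWindow = c(120, 180)) {
  stopifnot(sizeWindow[1] <= sizeWindow[2])
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  c1 <- enzymeCuts(seq, enzyme1)
  c2 <- enzymeCuts(seq, enzyme2)
  cuts <- data.frame(pos = c(c1, c2),
                     enzyme = rep(c("enzyme1", "enzyme2"),
                                  c(length(c1), length(c2))))
  cuts <- cuts[order(cuts$pos), , drop = FALSE]
  frag <- data.frame(start = integer(), end = integer(),
                     length = integer(), left_enzyme = character(),
                     right_enzyme = character())
  if (nrow(cuts) >= 2) {
    i <- seq_len(nrow(cuts) - 1L)
    keep <- cuts$enzyme[i] != cuts$enzyme[i + 1L] &
      cuts$pos[i + 1L] > cuts$pos[i]
    len <- cuts$pos[i + 1L] - cuts$pos[i]
    keep <- keep & len >= sizeWindow[1] & len <= sizeWindow[2]
    frag <- data.frame(start = cuts$pos[i][keep] + 1L,
                       end = cuts$pos[i + 1L][keep],
                       length = len[keep],
                       left_enzyme = cuts$enzyme[i][keep],
                       right_enzyme = cuts$enzyme[i + 1L][keep])
  }
  list(fragments = frag,
       cutCounts = c(enzyme1 = length(c1), enzyme2 = length(c2)))
}

#' Simulate a genome with a known marker map
#'
#' In the default, sequence-free mode, markers are placed at uniform
#' random genetic positions on each chromosome and physical positions are
#' interpolated assuming a uniform recombination rate.  In sequence mode a
#' uniform-random DNA sequence is generated per chromosome, digested with
#' the enzyme pair, and markers are placed on recoverable (size-selected,
#' two-enzyme) fragments, emulating ddRAD marker discovery.
#'
#' @param spec a \code{\link{genomeSpec}}.
#' @param markersPerChromosome markers to place on each chromosome.
#' @param mode "positions" (sequence-free, default) or "sequence".
#' @param enzyme1,enzyme2,sizeWindow digestion parameters (sequence mode).
#' @return list with \code{spec}, \code{sequences} (a \code{DNAStringSet}
#'   in sequence mode, else NULL) and \code{map}, the true map: a
#'   data.frame with columns chrom, marker_id, pos_cM, pos_bp, strictly
#'   increasing positions within each chromosome.
#' @export
simulateGenome <- function(spec, markersPerChromosome = 80,
                           mode = c("positions", "sequence"),
                           enzyme1 = enzymeBamHI(),
                           enzyme2 = enzymeMspI(),
                           sizeWindow = c(120, 180)) {
  mode <- match.arg(mode)
  set.seed(spec$seed)
  sequences <- NULL
  maps <- vector("list", spec$nChromosomes)
  if (mode == "sequence") {
    sequences <- Biostrings::DNAStringSet(vapply(
      seq_len(spec$nChromosomes),
      function(k) paste(sample(c("A", "C", "G", "T"), spec$lengthsBp[k],
                               replace = TRUE), collapse = ""),
      character(1)))
    names(sequences) <- paste0("chr", seq_len(spec$nChromosomes))
  }
  for (k in seq_len(spec$nChromosomes)) {
    Lc <- spec$lengthsCM[k]
    Lb <- spec$lengthsBp[k]
    if (mode == "positions") {
      pos_cM <- sort(runif(markersPerChromosome, 0, Lc))
      # uniform cM->bp interpolation; jitter away exact duplicates
      while (anyDuplicated(pos_cM))
        pos_cM <- sort(pos_cM + runif(length(pos_cM), 0, 1e-6))
      pos_bp <- pmax(1, round(pos_cM / Lc * Lb))
    } else {
      dg <- digestGenome(sequences[[k]], enzyme1, enzyme2, sizeWindow)
      fr <- dg$fragments
      n <- min(markersPerChromosome, nrow(fr))
      pick <- sort(sample(nrow(fr), n))
      pos_bp <- fr$start[pick]
      pos_cM <- pos_bp / Lb * Lc
    }
    maps[[k]] <- data.frame(
      chrom = rep(k, length(pos_cM)),
      marker_id = sprintf("M%02d_%04d", k, seq_along(pos_cM)),
      pos_cM = pos_cM, pos_bp = pos_bp)
  }
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  list(spec = spec, sequences = sequences, map = map)
}

#' Compare ddRAD and single-enzyme RAD read allocation
#'
#' Allocates a fixed read budget over the locus sets targeted by the two
#' protocols and reports locus recovery at a minimum depth.  The ddRAD
#' model samples reads only from size-selected two-enzyme fragments, so
#' the budget concentrates on few loci; the RAD model samples reads from
#' every flank of an enzyme-1 cut site (random shearing recovers both
#' sides), spreading the same budget over many more loci.
#'
#' @param sequences a \code{DNAStringSet} (or list of sequences).
#' @param enzyme1,enzyme2,sizeWindow digestion parameters.
#' @param nReads total read budget per protocol.
#' @param minDepth minimum depth for a locus to count as recovered.
#' @param seed integer seed.
#' @return data.frame, one row per protocol: n_loci, n_recovered,
#'   mean_depth (over recovered loci), frac_reads_on_recovered.
#' @export
compareDigestProtocols <- function(sequences, enzyme1 = enzymeBamHI(),
                                   enzyme2 = enzymeMspI(),
                                   sizeWindow = c(120, 180),
                                   nReads = 1e5, minDepth = 5,
                                   seed = 1L) {
  stopifnot(nReads >= 0)
  set.seed(seed)
  nDd <- 0L
  nE1 <- 0L
  for (s in as.list(sequences)) {
    dg <- digestGenome(s, enzyme1, enzyme2, sizeWindow)
    nDd <- nDd + nrow(dg$fragments)
    nE1 <- nE1 + as.integer(dg$cutCounts["enzyme1"])
  }
  nRad <- 2L * nE1  # one locus per cut-site flank
  oneProtocol <- function(protocol, nLoci) {
    if (nLoci == 0 || nReads == 0) {
      depth <- integer(nLoci)
    } else {
      depth <- as.integer(rmultinom(1, nReads, rep(1, nLoci)))
    }
    rec <- depth >= minDepth
    data.frame(protocol = protocol, n_loci = nLoci,
               n_recovered = sum(rec),
               mean_depth = if (any(rec)) mean(depth[rec]) else 0,
               frac_reads_on_recovered =
                 if (nReads > 0) sum(depth[rec]) / nReads else 0)
  }
  rbind(oneProtocol("ddRAD", nDd), oneProtocol("RAD", nRad))
}
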