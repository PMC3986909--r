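# Independent oracles and small builders used across the test files.

# brute-force minimum SARF by full permutation enumeration; permutations
# are generated by insertion (independent of the package's enumerator)
oracleMinSarf <- function(d) {
  n <- nrow(d)
  perms <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- matrix(0L, nrow(perms) * k, k)
    r <- 0L
    for (i in seq_len(nrow(perms))) for (p in 0:(k - 1L)) {
      r <- r + 1L
      out[r, ] <- append(perms[i, ], k, after = p)
    }
    perms <- out
  }
  s <- numeric(nrow(perms))
  for (k in seq_len(n - 1L))
    s <- s + d[perms[, k] + (perms[, k + 1L] - 1L) * n]
  min(s)
}

# brute-force syntenic-box scan by explicit double loop
oracleBoxes <- function(m, tBox, tHigh) {
  nb <- 0; inb <- 0; nh <- 0; inh <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] >= tBox) {
      nb <- nb + 1
      inb <- inb + m[i, j]
    }
    if (m[i, j] >= tHigh) {
      nh <- nh + 1
      inh <- inh + m[i, j]
    }
  }
  list(n_boxes = nb, in_box = inb, n_high_boxes = nh, in_high = inh,
       out_of_box = sum(m) - inb)
}

# PairwiseLinkage from an rf matrix (marker names from dimnames),
# with LOD computed at a nominal progeny count
plFromRf <- function(rf, N = 100) {
  ids <- rownames(rf)
  R <- round(rf * N)
  rhat <- pmax(R / N, 1e-6)
  lod <- R * log10(2 * rhat) + (N - R) * log10(2 * (1 - rhat))
  diag(lod) <- 0
  Nm <- matrix(N, nrow(rf), ncol(rf), dimnames = dimnames(rf))
  new("PairwiseLinkage", markers = ids, N = Nm, R = R, rf = rf,
      lod = lod)
}

# random symmetric rf matrix with named markers
randomRf <- function(n, lo = 0.01, hi = 0.49) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, lo, hi)
  m <- m + t(m)
  dimnames(m) <- list(sprintf("m%02d", 1:n), sprintf("m%02d", 1:n))
  m
}

# GenotypeMatrix from a plain character matrix
gmFrom <- function(g, parent = "dam") {
  rownames(g) <- sprintf("M%02d", seq_len(nrow(g)))
  GenotypeMatrix(g, informative_parent = parent)
}

# small simulated family shared by several tests
smallFamily <- function(nChrom = 3, markersPer = 30, nProgeny = 92,
                        seed = 101, ...) {
  spec <- genomeSpec(nChromosomes = nChrom,
                     lengthsBp = rep(5e6, nChrom),
                     lengthsCM = rep(90, nChrom), seed = seed)
  gen <- simulateGenome(spec, markersPerChromosome = markersPer)
  fam <- simulateFamily(gen$map, nProgeny = nProgeny, seed = seed + 1,
                        ...)
  list(spec = spec, genome = gen, fam = fam)
}

# genetic map taken directly from a simulated true map
trueMapAsGeneticMap <- function(genome, sex = "female") {
  tb <- do.call(rbind, lapply(split(genome$map, genome$map$chrom),
    function(g) data.frame(linkage_group = g$chrom[1],
                           rank = seq_len(nrow(g)),
                           marker_id = g$marker_id,
                           position_cM = g$pos_cM - g$pos_cM[1],
                           n_typed = 92L)))
  GeneticMap(tb, sex)
}
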