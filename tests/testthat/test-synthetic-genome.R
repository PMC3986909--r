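test_that("double digestion recovers exactly the bounded, size-selected fragments", {
  # hand enumeration: BamHI cut between 3|4, MspI cut between 13|14
  dg <- digestGenome("AAGGATCCTTTTCCGGAA", sizeWindow = c(5, 15))
  expect_equal(nrow(dg$fragments), 1)
  expect_equal(dg$fragments$start, 4)
  expect_equal(dg$fragments$end, 13)
  expect_equal(dg$fragments$length, 10)
  expect_equal(unname(dg$cutCounts), c(1, 1))
  # same sequence, window excluding the fragment
  expect_equal(nrow(digestGenome("AAGGATCCTTTTCCGGAA",
                                 sizeWindow = c(1, 2))$fragments), 0)
  # no recognition sites at all
  dg0 <- digestGenome("AAAAAAAAAA", sizeWindow = c(1, 100))
  expect_equal(nrow(dg0$fragments), 0)
  expect_equal(unname(dg0$cutCounts), c(0, 0))
  # two same-enzyme cuts in a row do not bound a fragment
  dg2 <- digestGenome("AAGGATCCTTGGATCCTTTTCCGGAA",
                      sizeWindow = c(1, 50))
  expect_true(all(dg2$fragments$left_enzyme !=
                    dg2$fragments$right_enzyme))
})

test_that("genome simulation is seed-deterministic with valid true maps", {
  spec <- genomeSpec(nChromosomes = 2, lengthsBp = c(1e4, 2e4),
                     lengthsCM = c(100, 80), seed = 1)
  a <- simulateGenome(spec, markersPerChromosome = 50)
  b <- simulateGenome(spec, markersPerChromosome = 50)
  expect_identical(a$map, b$map)
  expect_equal(length(unique(a$map$chrom)), 2)
  # positions in range and strictly increasing per chromosome
  for (g in split(a$map, a$map$chrom)) {
    expect_true(all(g$pos_cM >= 0 & g$pos_cM <= max(spec$lengthsCM)))
    expect_true(all(diff(g$pos_cM) > 0))
  }
  # 19-chromosome default spec
  big <- simulateGenome(genomeSpec(seed = 2), markersPerChromosome = 5)
  expect_equal(length(unique(big$map$chrom)), 19)
  expect_error(genomeSpec(nChromosomes = 1, lengthsBp = 0,
                          lengthsCM = 10), "positive")
})

test_that("sequence mode places markers on recoverable fragments", {
  spec <- genomeSpec(nChromosomes = 1, lengthsBp = 5e4,
                     lengthsCM = 50, seed = 4)
  gen <- simulateGenome(spec, markersPerChromosome = 10,
                        mode = "sequence", sizeWindow = c(50, 400))
  expect_s4_class(gen$sequences, "DNAStringSet")
  dg <- digestGenome(gen$sequences[[1]], sizeWindow = c(50, 400))
  expect_true(all(gen$map$pos_bp %in% dg$fragments$start))
})

test_that("ddRAD concentrates the read budget relative to RAD", {
  spec <- genomeSpec(nChromosomes = 1, lengthsBp = 2e5,
                     lengthsCM = 100, seed = 9)
  gen <- simulateGenome(spec, markersPerChromosome = 5,
                        mode = "sequence")
  cmp <- compareDigestProtocols(gen$sequences, nReads = 2e4, seed = 3)
  dd <- cmp[cmp$protocol == "ddRAD", ]
  rad <- cmp[cmp$protocol == "RAD", ]
  expect_lt(dd$n_loci, rad$n_loci)
  expect_gte(dd$frac_reads_on_recovered, rad$frac_reads_on_recovered)
  expect_gte(dd$mean_depth, rad$mean_depth)
  # zero reads recovers nothing under either protocol
  cmp0 <- compareDigestProtocols(gen$sequences, nReads = 0, seed = 3)
  expect_equal(cmp0$n_recovered, c(0, 0))
  # seed determinism
  expect_identical(cmp,
                   compareDigestProtocols(gen$sequences, nReads = 2e4,
                                          seed = 3))
})
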