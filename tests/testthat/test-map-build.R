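test_that("error LOD matches the flanking double-crossover likelihood ratio", {
  # hand evaluations of the closed form
  expect_equal(errorLod(0.01, 0.01, 0.01), 1.9956, tolerance = 1e-4)
  expect_equal(errorLod(0.005, 0.005, 0.01), 2.6021, tolerance = 1e-4)
  expect_lt(errorLod(0.01, 0.01, 0.01), 2)    # not masked
  expect_gt(errorLod(0.005, 0.005, 0.01), 2)  # masked
})

test_that("error scan masks planted tight double crossovers and only those", {
  # three co-located stacks 5 cM apart; the middle stack is tight
  ids <- sprintf("M%d", 1:6)
  pos <- c(0, 0.001, 5, 5.001, 10, 10.001)
  set.seed(2)
  chainG <- sample(c("A", "H"), 60, TRUE)
  g <- matrix(rep(chainG, each = 6), 6, 60)
  g[4, 7] <- ifelse(g[4, 7] == "A", "H", "A")  # isolated flip
  gm <- GenotypeMatrix(g, marker_id = ids)
  map <- GeneticMap(data.frame(linkage_group = 1, rank = 1:6,
                               marker_id = ids, position_cM = pos))
  res <- errorLodScan(map, gm, epsilon = 0.01)
  expect_true(is.na(genotypes(res$genotypes)[4, 7]))
  expect_equal(sum(is.na(genotypes(res$genotypes))), 1)
  expect_true(all(res$flags$masked))
  # a consistent genotype is never flagged
  res2 <- errorLodScan(map, GenotypeMatrix(matrix(rep(chainG, each = 6),
                                                  6, 60),
                                           marker_id = ids))
  expect_equal(nrow(res2$flags), 0)
})

test_that("masking never increases the apparent double-crossover count", {
  countDXO <- function(gm, map) {
    g <- genotypes(gm)
    tb <- mapTable(map)
    tot <- 0
    for (grp in split(tb, tb$linkage_group)) {
      o <- match(grp$marker_id[order(grp$rank)], rownames(g))
      for (k in 2:(length(o) - 1)) {
        up <- g[o[k - 1], ]; mid <- g[o[k], ]; dn <- g[o[k + 1], ]
        tot <- tot + sum(!is.na(up) & !is.na(mid) & !is.na(dn) &
                           up == dn & mid != up)
      }
    }
    tot
  }
  fm <- smallFamily(nChrom = 2, markersPer = 25, seed = 55)
  gm <- recodePseudoTestcross(splitByParent(fm$fam$genotypes)$dam)
  pl <- pairwiseLinkage(gm)
  gr <- groupMarkers(pl, 7)
  map <- assembleMap(gm, pl, gr$groups)
  before <- countDXO(gm, map)
  res <- errorLodScan(map, gm)
  expect_lte(countDXO(res$genotypes, map), before)
})

test_that("assembled maps start at zero with non-decreasing Kosambi positions", {
  fm <- smallFamily(nChrom = 2, markersPer = 20, seed = 12)
  out <- buildSexMap(recodePseudoTestcross(
    splitByParent(fm$fam$genotypes)$dam))
  tb <- mapTable(out$map)
  for (g in split(tb, tb$linkage_group)) {
    p <- g$position_cM[order(g$rank)]
    expect_equal(p[1], 0)
    expect_true(all(diff(p) >= 0))
  }
  expect_equal(unname(groupLengths(out$map)),
               unname(vapply(split(tb$position_cM, tb$linkage_group),
                             max, numeric(1))))
})

test_that("sex maps pair through shared loci and split male groups merge", {
  fm <- smallFamily(nChrom = 3, markersPer = 35, seed = 91)
  qc <- applyGenotypeQC(fm$fam$genotypes)
  fem <- buildSexMap(qc$dam, "female")
  mal <- buildSexMap(qc$sire, "male")
  pr <- pairSexMaps(fem$map, mal$map, markerInfo(fm$fam$genotypes),
                    mal$linkage)
  expect_gte(nrow(pr$pairs), 3)
  truth <- fm$fam$markerTruth
  # every pairing links groups carrying the same true chromosome
  ftb <- mapTable(fem$map)
  mtb <- mapTable(mal$map)
  chromOf <- function(tb, g) {
    ids <- tb$marker_id[tb$linkage_group == g]
    names(sort(-table(truth$chrom[match(ids, truth$marker_id)])))[1]
  }
  for (i in seq_len(nrow(pr$pairs)))
    expect_equal(chromOf(ftb, pr$pairs$female_group[i]),
                 chromOf(mtb, pr$pairs$male_group[i]))
  # no shared loci -> no pairs
  miNone <- markerInfo(fm$fam$genotypes)
  miNone$locus_id <- paste0(miNone$marker_id, "_x",
                            seq_along(miNone$marker_id))
  pr0 <- pairSexMaps(fem$map, mal$map, miNone, mal$linkage)
  expect_equal(nrow(pr0$pairs), 0)
})

test_that("co-segregation binning collapses identical markers transitively", {
  # M1 = M2 = M3 (zero recombinants), M4 distinct
  set.seed(4)
  base <- sample(c("A", "H"), 80, TRUE)
  other <- sample(c("A", "H"), 80, TRUE)
  g <- rbind(base, base, base, other)
  gm <- gmFrom(g)
  pl <- pairwiseLinkage(gm)
  map <- GeneticMap(data.frame(linkage_group = 1, rank = 1:4,
                               marker_id = paste0("M0", 1:4),
                               position_cM = c(0, 0, 0, 30)))
  bins <- binCosegregating(map, pl)
  expect_equal(bins$m_positions, 2)
  expect_equal(bins$n_markers, 4)
  # all identical -> single position; all distinct -> one per marker
  gmAll <- gmFrom(rbind(base, base, base))
  mapAll <- GeneticMap(data.frame(linkage_group = 1, rank = 1:3,
                                  marker_id = paste0("M0", 1:3),
                                  position_cM = c(0, 0, 0)))
  expect_equal(binCosegregating(mapAll,
                                pairwiseLinkage(gmAll))$m_positions, 1)
})

test_that("map summary wires Chakravarti correction and coverage together", {
  fm <- smallFamily(nChrom = 2, markersPer = 25, seed = 66)
  out <- buildSexMap(recodePseudoTestcross(
    splitByParent(fm$fam$genotypes)$dam))
  sm <- mapSummary(out$map, out$linkage)
  expect_true(all(sm$per_group$corrected_cM >=
                    sm$per_group$length_cM, na.rm = TRUE))
  expect_equal(sm$totals$corrected_cM,
               sum(sm$per_group$corrected_cM, na.rm = TRUE))
  expect_true(sm$totals$coverage > 0 && sm$totals$coverage < 1)
  raw <- mapSummary(out$map, out$linkage, useUniquePositions = FALSE)
  expect_gte(raw$totals$n_markers, sm$totals$m)
})
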