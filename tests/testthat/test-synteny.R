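test_that("Oxford grids count segment pairs and track exclusions", {
  seg <- data.frame(segment_id = c("s1", "s2", "s3"),
                    chrA = c("chr1", "chr1", "chr2"),
                    chrB = c("chrX", "chrX", NA))
  g <- buildGrid(seg)
  expect_equal(gridCounts(g)["chr1", "chrX"], 2)
  expect_equal(sum(gridCounts(g)), 2)
  expect_equal(g@nExcluded, 1)
  # permuting table rows leaves the grid unchanged
  g2 <- buildGrid(seg[c(3, 1, 2), ])
  expect_identical(gridCounts(g), gridCounts(g2))
})

test_that("box classification matches direct counts and edge thresholds", {
  m <- matrix(c(7, 0, 1, 16), 2, 2)  # [[7,1],[0,16]] row-major
  b <- classifyBoxes(m, tBox = 6, tHigh = 16)
  expect_equal(b$n_boxes, 2)
  expect_equal(b$in_box, 23)
  expect_equal(b$out_of_box, 1)
  expect_equal(b$n_high_boxes, 1)
  expect_equal(b$in_high, 16)
  expect_equal(b$in_box_pct, round(100 * 23 / 24))
  empty <- classifyBoxes(matrix(0, 3, 3))
  expect_equal(empty$in_box, 0)
  expect_equal(empty$total, 0)
  all1 <- classifyBoxes(m, tBox = 1)
  expect_equal(all1$in_box, sum(m))
  expect_equal(all1$out_of_box, 0)
})

test_that("box classification equals the brute-force cell scan on random grids", {
  set.seed(23)
  for (i in 1:50) {
    m <- matrix(rpois(35, sample(1:8, 1)), 5, 7)
    b <- classifyBoxes(m, tBox = 6, tHigh = 16)
    o <- oracleBoxes(m, 6, 16)
    expect_equal(b[c("n_boxes", "in_box", "n_high_boxes", "in_high",
                     "out_of_box")], o)
  }
})

test_that("one-to-two detection applies the fraction and count thresholds", {
  m <- rbind(Loc21 = c(Aja3 = 10, Aja16 = 6, Aja1 = 1),
             LocOne = c(Aja3 = 15, Aja16 = 1, Aja1 = 0),
             LocThin = c(Aja3 = 2, Aja16 = 2, Aja1 = 2))
  res <- detectOneToTwo(m)
  expect_equal(res$outgroup_chrom, "Loc21")
  expect_setequal(c(res$focal_1, res$focal_2), c("Aja3", "Aja16"))
  expect_equal(res$count_1, 10)
  # concentrated row: second chromosome below min_count
  expect_false("LocOne" %in% res$outgroup_chrom)
  # row spread thinly fails both thresholds
  thin <- detectOneToTwo(rbind(r = c(a = 2, b = 2, c = 2, d = 2,
                                     e = 2)))
  expect_equal(nrow(thin), 0)
})

test_that("ohnolog quadruplets require the full two-to-two pattern", {
  m <- matrix(c(10, 4, 5, 8,
                0, 0, 0, 0), 4, 2,
              dimnames = list(c("A3", "A16", "A4", "A7"),
                              c("O12", "O9")))
  m["A3", ] <- c(10, 4)
  m["A16", ] <- c(5, 8)
  m["A4", ] <- c(0, 0)
  m["A7", ] <- c(0, 0)
  fp <- data.frame(focal_1 = c("A3", "A4"), focal_2 = c("A16", "A7"))
  sp <- data.frame(sister_1 = "O12", sister_2 = "O9")
  q <- detectOhnologQuadruplets(m, fp, sp)
  expect_equal(nrow(q), 1)
  expect_equal(q$focal_1, "A3")
  # symmetric in pair orderings
  fp2 <- data.frame(focal_1 = c("A16"), focal_2 = c("A3"))
  sp2 <- data.frame(sister_1 = "O9", sister_2 = "O12")
  expect_equal(nrow(detectOhnologQuadruplets(m, fp2, sp2)), 1)
  # no cross-pair counts -> nothing
  expect_equal(nrow(detectOhnologQuadruplets(m * 0, fp, sp)), 0)
})

test_that("simulated WGD tables conserve segments and show the planted structure", {
  sc <- RearrangementScenario(2, list(), "none")
  h <- wgdHistory(sc, segmentsPer = 10, seed = 6)
  segs <- simulateWGDSegments(h, confusion = 0)
  expect_equal(nrow(segs), 2 * 2 * 10)      # conservation
  g <- gridCounts(buildGrid(segs))
  # block-diagonal: four cells of 10, one per duplicate pair
  expect_equal(sort(as.vector(g), decreasing = TRUE)[1:4], rep(10, 4))
  expect_equal(sum(g), 40)
  expect_equal(sum(g > 0), 4)
  # with confusion the total is conserved and paralog cells appear
  segs2 <- simulateWGDSegments(wgdHistory(sc, 10, 6), confusion = 0.4)
  expect_equal(nrow(segs2), 40)
  expect_gt(sum(gridCounts(buildGrid(segs2)) > 0), 4)
})
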