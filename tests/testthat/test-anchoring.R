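mkHits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(qseqid = r[[1]], sseqid = r[[2]], pident = 98,
               length = 100, mismatch = 2, gapopen = 0, qstart = 1,
               qend = 100, sstart = 1, send = 100,
               evalue = as.numeric(r[[3]]),
               bitscore = as.numeric(r[[4]]))))
}

test_that("two-fold bit-score rule assigns, withholds and filters as specified", {
  # 200 vs 90 on different scaffolds: ratio 2.22 >= 2 -> assigned
  a <- assignMarkers(mkHits(list("q1", "s1", 1e-40, 200),
                            list("q1", "s2", 1e-40, 90)))
  expect_equal(a$status, "assigned")
  expect_equal(a$scaffold_id, "s1")
  # 200 vs 150: ratio < 2 -> unassigned
  b <- assignMarkers(mkHits(list("q1", "s1", 1e-40, 200),
                            list("q1", "s2", 1e-40, 150)))
  expect_equal(b$status, "ambiguous")
  expect_true(is.na(b$scaffold_id))
  # E-value cutoff on single hits
  expect_equal(assignMarkers(mkHits(list("q1", "s1", 1e-30,
                                         200)))$status, "assigned")
  expect_equal(assignMarkers(mkHits(list("q1", "s1", 1e-10,
                                         200)))$status, "no_hit")
  # multiple passing hits to the same scaffold do not block assignment
  d <- assignMarkers(mkHits(list("q1", "s1", 1e-40, 200),
                            list("q1", "s1", 1e-40, 150)))
  expect_equal(d$status, "assigned")
  # exactly two-fold is not "less than two-fold": assigned
  e <- assignMarkers(mkHits(list("q1", "s1", 1e-40, 200),
                            list("q1", "s2", 1e-40, 100)))
  expect_equal(e$status, "assigned")
})

test_that("assignment is invariant to hit-record input order", {
  h <- mkHits(list("q1", "s1", 1e-40, 200), list("q1", "s2", 1e-40, 90),
              list("q2", "s3", 1e-40, 120), list("q2", "s4", 1e-40, 80),
              list("q3", "s5", 1e-25, 140))
  set.seed(5)
  for (i in 1:5)
    expect_identical(assignMarkers(h[sample(nrow(h)), ]),
                     assignMarkers(h))
})

test_that("scaffold ordering follows the female-first rule with its tie branches", {
  mkAnch <- function(id, len, fg, fcm, mg = NA, mcm = NA)
    data.frame(scaffold_id = id, length_bp = len, n_markers = 1,
               female_group = fg, female_cM = fcm, male_group = mg,
               male_cM = mcm, conflict = FALSE)
  # distinct female positions: rank = position order
  anch <- rbind(mkAnch("s1", 100, 1, 30), mkAnch("s2", 100, 1, 10),
                mkAnch("s3", 100, 1, 20))
  ord <- orderScaffolds(anch)
  expect_equal(ord$scaffold_id[order(ord$rank)], c("s2", "s3", "s1"))
  # tie, male separates 50+40 kb but sum 90 < 100 kb: largest only
  tie1 <- rbind(mkAnch("sA", 100e3, 1, 10),
                mkAnch("sB", 50e3, 1, 10, 1, 5),
                mkAnch("sC", 40e3, 1, 10, 1, 9))
  o1 <- orderScaffolds(tie1)
  expect_equal(o1$scaffold_id[o1$status == "ordered"], "sA")
  expect_setequal(o1$scaffold_id[o1$status == "anchored_unordered"],
                  c("sB", "sC"))
  # tie, male separates 90+80 kb, sum 170 > 100 kb: male order wins
  tie2 <- rbind(mkAnch("sA", 100e3, 1, 10),
                mkAnch("sB", 90e3, 1, 10, 1, 9),
                mkAnch("sC", 80e3, 1, 10, 1, 5))
  o2 <- orderScaffolds(tie2)
  ranked <- o2[o2$status == "ordered", ]
  expect_equal(ranked$scaffold_id[order(ranked$rank)], c("sC", "sB"))
  expect_equal(o2$status[o2$scaffold_id == "sA"], "anchored_unordered")
  # male-only scaffolds are never ranked; conflicts are excluded
  mo <- rbind(mkAnch("s1", 10, 1, 5), mkAnch("s2", 10, NA, NA, 2, 7))
  mo$conflict[2] <- FALSE
  omo <- orderScaffolds(mo)
  expect_equal(omo$status[omo$scaffold_id == "s2"], "male_only")
  cf <- mkAnch("s9", 10, 1, 5)
  cf$conflict <- TRUE
  expect_equal(orderScaffolds(rbind(anch, cf))$status[
    orderScaffolds(rbind(anch, cf))$scaffold_id == "s9"], "conflict")
})

test_that("conflict detection flags inter-group and wide intra-group scaffolds", {
  fmap <- GeneticMap(data.frame(
    linkage_group = rep(c(1, 5), each = 3), rank = rep(1:3, 2),
    marker_id = paste0("q", 1:6),
    position_cM = c(0, 10, 12, 0, 5, 40)))
  asg <- data.frame(marker_id = paste0("q", 1:6),
                    scaffold_id = c("sNear", "sNear", "sInter",
                                    "sInter", "sFar", "sFar"),
                    status = "assigned", best_bit = 200,
                    second_bit = NA)
  cf <- detectConflicts(asg, list(fmap))
  expect_false(cf$inter_group[cf$scaffold_id == "sNear"])   # 10 vs 12 cM
  expect_false(cf$intra_group[cf$scaffold_id == "sNear"])
  expect_true(cf$inter_group[cf$scaffold_id == "sInter"])   # LG1 + LG5
  expect_true(cf$intra_group[cf$scaffold_id == "sFar"])     # 5 vs 40 cM
})

test_that("every anchored scaffold ends in exactly one status; truth is recovered without decoys", {
  fm <- smallFamily(nChrom = 3, markersPer = 25, seed = 14)
  fmap <- trueMapAsGeneticMap(fm$genome)
  fs <- fragmentIntoScaffolds(fm$genome, scaffoldsPerChromosome = 6,
                              seed = 2)
  # tiling invariant: scaffold lengths sum to chromosome lengths
  bychrom <- vapply(split(fs$scaffolds$length_bp, fs$scaffolds$chrom),
                    sum, numeric(1))
  expect_equal(unname(bychrom), fm$spec$lengthsBp)
  asg <- assignMarkers(fs$hits)
  expect_true(all(asg$status == "assigned"))
  expect_equal(asg$scaffold_id,
               fs$markerTruth$scaffold_id[match(asg$marker_id,
                                                fs$markerTruth$marker_id)])
  anch <- anchorScaffolds(asg, fmap, NULL, fs$scaffolds)
  ord <- orderScaffolds(anch)
  expect_equal(anyDuplicated(ord$scaffold_id), 0)
  expect_true(all(ord$status %in% c("ordered", "anchored_unordered",
                                    "male_only", "conflict")))
  # ordered ranks match true bp order where female anchors are distinct
  oo <- ord[ord$status == "ordered", ]
  for (g in split(oo, oo$linkage_group)) {
    tstart <- fs$scaffolds$start[match(g$scaffold_id,
                                       fs$scaffolds$scaffold_id)]
    expect_equal(cor(g$rank, tstart, method = "spearman"), 1)
  }
})
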