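test_that("pseudo-testcross recoding turns B into A and is idempotent", {
  g <- matrix(c("A", "B", "H", NA), 4, 1)
  gm <- gmFrom(g)
  rec <- recodePseudoTestcross(gm)
  expect_equal(unname(genotypes(rec)[, 1]), c("A", "A", "H", NA))
  expect_identical(genotypes(recodePseudoTestcross(rec)),
                   genotypes(rec))
  # matrix with no B untouched
  g2 <- matrix(c("A", "H", "H", NA), 2, 2)
  expect_identical(genotypes(recodePseudoTestcross(gmFrom(g2))), {
    x <- g2
    rownames(x) <- c("M01", "M02")
    colnames(x) <- c("ind1", "ind2")
    x
  })
})

test_that("missingness filter keeps exactly markers typed at the threshold", {
  set.seed(1)
  n <- 92
  g <- matrix("A", 3, n)
  g[1, 1:4] <- NA   # typed in 88 -> retained at the 95% rule
  g[2, 1:5] <- NA   # typed in 87 -> dropped
  gm <- gmFrom(g)
  res <- filterMissingness(gm)   # default: ceiling(0.95 * 92) = 88
  expect_true("M01" %in% res$retained)
  expect_true("M02" %in% res$dropped)
  expect_equal(filterMissingness(gm, 0)$retained, paste0("M0", 1:3))
  gAll <- gmFrom(matrix(NA_character_, 1, 5))
  expect_equal(filterMissingness(gAll, 1)$dropped, "M01")
})

test_that("segregation test reproduces the 1-df chi-square decisions", {
  mk <- function(nA, nH) gmFrom(matrix(rep(c("A", "H"), c(nA, nH)),
                                       1, nA + nH))
  even <- segregationTest(mk(46, 46))
  expect_equal(even$chi_square, 0)
  expect_false(even$excluded)
  mid <- segregationTest(mk(60, 32))   # 784/92 ~ 8.52, retained
  expect_equal(mid$chi_square, 784 / 92, tolerance = 1e-12)
  expect_false(mid$excluded)
  bad <- segregationTest(mk(70, 22))   # 2304/92 ~ 25.04, excluded
  expect_equal(bad$chi_square, 2304 / 92, tolerance = 1e-12)
  expect_true(bad$excluded)
  expect_warning(z <- segregationTest(gmFrom(matrix(NA_character_,
                                                    1, 4))),
                 "no informative")
  expect_true(z$excluded)
})

test_that("chi-square statistic equals the generic goodness-of-fit computation", {
  for (n in c(1:10, 15, 20, 30)) for (a in 0:n) {
    gm <- gmFrom(matrix(rep(c("A", "H"), c(a, n - a)), 1, n))
    ours <- segregationTest(gm)$chi_square
    ref <- suppressWarnings(
      chisq.test(c(a, n - a), p = c(0.5, 0.5), correct = FALSE))
    expect_equal(ours, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("parent split partitions markers with bridge markers in both outputs", {
  g <- matrix("A", 5, 4)
  gm <- GenotypeMatrix(g, informative_parent = c("dam", "dam", "sire",
                                                 "both", "both"))
  sp <- splitByParent(gm)
  expect_equal(nMarkers(sp$dam), 4)
  expect_equal(nMarkers(sp$sire), 3)
  expect_equal(sp$bridge, c("M4", "M5"))
  expect_equal(nMarkers(sp$dam) + nMarkers(sp$sire) -
                 length(sp$bridge), 5)
  gm2 <- GenotypeMatrix(g[1:2, ], informative_parent = "dam")
  expect_equal(nMarkers(splitByParent(gm2)$sire), 0)
})

test_that("missingness and distortion filters commute", {
  fm <- smallFamily(markersPer = 25, seed = 77)
  gm <- recodePseudoTestcross(fm$fam$genotypes)
  a <- filterMissingness(gm, 88)$genotypes
  aIds <- segregationTest(a)
  routeA <- sort(aIds$marker_id[!aIds$excluded])
  d <- segregationTest(gm)
  b <- gm[d$marker_id[!d$excluded]]
  routeB <- sort(filterMissingness(b, 88)$retained)
  expect_identical(routeA, routeB)
})
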