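# Two-point estimation, grouping, seriation, splitting, map assembly.

test_that("rf MLE is self-consistent with the recursion on exact counts", {
  for (r in c(0.05, 0.1, 0.25)) {
    J <- twoLocusSelfingDistribution(r, 4)$joint
    counts <- matrix(1e6 * as.vector(J), 3, 3)
    est <- estimateRf(counts, 4)
    expect_equal(est$rf, r, tolerance = 1e-3)
  }
})

test_that("independent counts give r = 0.5 with LOD near zero", {
  m <- twoLocusSelfingDistribution(0.5, 4)
  counts <- matrix(940 * as.vector(m$joint), 3, 3)
  est <- estimateRf(counts, 4)
  expect_equal(est$rf, 0.5, tolerance = 5e-3)
  expect_lt(est$lod, 0.01)
})

test_that("perfect coupling gives r = 0 and the oracle log-likelihood LOD", {
  counts <- diag(c(41, 12, 41))
  est <- estimateRf(counts, 4)
  expect_identical(est$rf, 0)
  # direct evaluation of log10 L(0) - log10 L(0.5)
  p0 <- c(0.4375, 0.125, 0.4375)
  ll0 <- sum(c(41, 12, 41) * log10(p0))
  ll5 <- sum(c(41, 12, 41) * log10(p0^2))
  expect_equal(est$lod, ll0 - ll5, tolerance = 1e-6)
})

test_that("collapsed likelihood handles markers scored without heterozygotes", {
  J <- twoLocusSelfingDistribution(0.1, 4)$joint
  counts <- round(2e5 * J)
  # marker 1 mis-scored: hets recorded as BB
  collapsed <- counts
  collapsed[3, ] <- collapsed[2, ] + collapsed[3, ]
  collapsed[2, ] <- 0
  est <- estimateRf(collapsed, 4, collapse1 = TRUE)
  expect_equal(est$rf, 0.1, tolerance = 5e-3)
})

test_that("the rf/LOD matrix agrees with the per-pair estimator", {
  set.seed(31)
  x <- quickPop(quickGenome("1A", 100, 6), n = 94)
  v <- validateGenotypes(x)
  rfm <- estRfMatrix(v$kept, refineLod = 0)   # refine every pair
  calls <- genotypeCalls(v$kept)
  for (pair in list(c(1, 2), c(2, 5), c(1, 6))) {
    counts <- table(factor(calls[pair[1], ], 1:3),
                    factor(calls[pair[2], ], 1:3))
    est <- estimateRf(matrix(counts, 3, 3), 4)
    expect_equal(rfValues(rfm)[pair[1], pair[2]], est$rf, tolerance = 1e-4)
    expect_equal(lodValues(rfm)[pair[1], pair[2]], est$lod, tolerance = 1e-3)
  }
  expect_true(isSymmetric(rfValues(rfm)))
})

test_that("grouping requires both the LOD and the rf constraint per link", {
  rf <- matrix(0.5, 3, 3); lod <- matrix(0, 3, 3)
  rf[1, 2] <- rf[2, 1] <- 0.05; lod[1, 2] <- lod[2, 1] <- 20
  rf[1, 3] <- rf[3, 1] <- 0.05; lod[1, 3] <- lod[3, 1] <- 2.5   # LOD too low
  rfm <- rfMatrixFrom(c("a", "b", "c"), rf, lod)
  grp <- formLinkageGroups(rfm)
  expect_identical(grp$groups, list(c("a", "b")))
  expect_identical(grp$singletons, "c")

  # strong rf link but above rfMax is also rejected
  lod[1, 3] <- lod[3, 1] <- 20; rf[1, 3] <- rf[3, 1] <- 0.35
  grp2 <- formLinkageGroups(rfMatrixFrom(c("a", "b", "c"), rf, lod))
  expect_identical(grp2$singletons, "c")
})

test_that("grouping is transitive through chains", {
  rf <- matrix(0.5, 3, 3); lod <- matrix(0, 3, 3)
  rf[1, 2] <- rf[2, 1] <- 0.1; lod[1, 2] <- lod[2, 1] <- 10
  rf[2, 3] <- rf[3, 2] <- 0.1; lod[2, 3] <- lod[3, 2] <- 10
  grp <- formLinkageGroups(rfMatrixFrom(c("a", "b", "c"), rf, lod))
  expect_identical(grp$groups, list(c("a", "b", "c")))
})

test_that("three-marker ordering matches the exhaustive SARF optimum", {
  rf <- matrix(0, 3, 3)
  rf[1, 2] <- rf[2, 1] <- 0.05
  rf[2, 3] <- rf[3, 2] <- 0.05
  rf[1, 3] <- rf[3, 1] <- 0.10
  lod <- matrix(10, 3, 3)
  rfm <- rfMatrixFrom(c("A", "B", "C"), rf, lod)
  ord <- orderLinkageGroup(c("A", "B", "C"), rfm)
  expect_true(identical(ord$marker, c("A", "B", "C")) ||
                identical(ord$marker, c("C", "B", "A")))
  expect_equal(attr(ord, "sarf"), 0.10)
  expect_equal(ord$position,
               c(0, kosambi(0.05), 2 * kosambi(0.05)), tolerance = 1e-9)
})

test_that("noiseless simulated linkage group recovers the true order", {
  set.seed(32)
  g <- quickGenome("1A", 120, 8)
  x <- quickPop(g, n = 2000)
  rfm <- estRfMatrix(validateGenotypes(x)$kept)
  ord <- orderLinkageGroup(g$markers[["1A"]], rfm)
  truth <- g$markers[["1A"]]
  expect_true(identical(ord$marker, truth) ||
                identical(ord$marker, rev(truth)))
})

test_that("two markers order trivially with SARF = rf", {
  rf <- matrix(0, 2, 2); rf[1, 2] <- rf[2, 1] <- 0.2
  rfm <- rfMatrixFrom(c("a", "b"), rf, matrix(10, 2, 2))
  ord <- orderLinkageGroup(c("b", "a"), rfm)
  expect_equal(attr(ord, "sarf"), 0.2)
  expect_identical(sort(ord$marker), c("a", "b"))
})

test_that("splitting cuts at gaps of 35 cM inclusive and re-anchors", {
  lg <- data.frame(marker = c("a", "b", "c", "d"),
                   position = c(0, 10, 50, 62))
  out <- splitLinkageGroups(lg, gapCm = 35)
  expect_length(out, 2)
  expect_identical(out[[2]]$marker, c("c", "d"))
  expect_equal(out[[2]]$position, c(0, 12))

  exact <- data.frame(marker = c("a", "b"), position = c(0, 35))
  expect_length(splitLinkageGroups(exact, gapCm = 35), 2)
  expect_length(splitLinkageGroups(lg, gapCm = 60), 1)
})

test_that("map construction is invariant under individual permutation", {
  set.seed(33)
  x <- quickPop(quickGenome(), n = 80)
  map1 <- buildGeneticMap(x)
  xp <- x[, sample(ncol(x))]
  map2 <- buildGeneticMap(xp)
  expect_equal(mapTable(map1), mapTable(map2))
})

test_that("maps label linkage groups by majority assignment and count stats", {
  set.seed(34)
  g <- quickGenome(c("1A", "2A", "3A"), c(100, 90, 80), c(8, 7, 6))
  x <- quickPop(g, n = 120)
  map <- buildGeneticMap(x)
  tb <- mapTable(map)
  expect_setequal(unique(tb$chromosome), c("1A", "2A", "3A"))
  for (lg in unique(tb$lg))
    expect_identical(length(unique(tb$chromosome[tb$lg == lg])), 1L)
  st <- map@stats
  expect_identical(st$linkedMarkers, nrow(tb))
  expect_equal(mapLength(map), st$mapLength)
  expect_identical(st$nLG, length(unique(tb$lg)))
})

test_that("fully inbred populations are mapped with the inbred-limit model", {
  set.seed(35)
  x <- quickPop(quickGenome("1A", 80, 6), n = 94, k = Inf)
  map <- buildGeneticMap(x)
  expect_identical(nrow(mapTable(map)), 6L)
  expect_identical(length(unique(mapTable(map)$lg)), 1L)
})
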