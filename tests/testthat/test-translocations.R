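# Mapped and estRF translocation calls, merging, enrichment.

mkMap <- function(id, lgChrom, markers, assigned) {
  tb <- do.call(rbind, lapply(seq_along(lgChrom), function(i)
    data.frame(marker = markers[[i]], lg = sprintf("LG%02d", i),
               chromosome = lgChrom[i],
               position = seq(0, by = 5, length.out = length(markers[[i]])),
               stringsAsFactors = FALSE)))
  map <- methods::new("GeneticMap", populationId = id, table = tb,
                      sarf = numeric(), stats = list())
  list(map = map, assignments = assigned)
}

test_that("minority-assigned markers in a linkage group produce a mapped call", {
  mk <- c(sprintf("b%02d", 1:10), "t1", "t2")
  asg <- stats::setNames(c(rep("5B", 10), "7B", "7B"), mk)
  m <- mkMap("P1", "5B", list(mk), asg)
  calls <- mappedTranslocations(m$map, m$assignments)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$chrA, "5B")
  expect_identical(calls$chrB, "7B")
  expect_identical(calls$nMarkers, 2L)
  expect_false(calls$reciprocal)
  # requiring two minority markers still calls; three does not
  expect_identical(nrow(mappedTranslocations(m$map, m$assignments,
                                             minMinority = 3)), 0L)
})

test_that("chromosome-pure linkage groups produce no calls", {
  mk <- sprintf("b%02d", 1:8)
  asg <- stats::setNames(rep("2A", 8), mk)
  m <- mkMap("P1", "2A", list(mk), asg)
  expect_identical(nrow(mappedTranslocations(m$map, m$assignments)), 0L)
})

test_that("mirror-image calls are flagged reciprocal", {
  mk1 <- c(sprintf("a%02d", 1:6), "x1")
  mk2 <- c(sprintf("b%02d", 1:6), "y1")
  asg <- stats::setNames(c(rep("5B", 6), "7B", rep("7B", 6), "5B"),
                         c(mk1, mk2))
  m <- mkMap("P1", c("5B", "7B"), list(mk1, mk2), asg)
  calls <- mappedTranslocations(m$map, m$assignments)
  expect_identical(nrow(calls), 2L)
  expect_true(all(calls$reciprocal))
})

test_that("estRF calls need a strict LOD threshold and different chromosomes", {
  mk <- c("a1", "a2", "b1", "b2")
  rf <- matrix(0.5, 4, 4); lod <- matrix(0, 4, 4)
  lod[1, 2] <- lod[2, 1] <- 30       # same chromosome, ignored
  lod[1, 3] <- lod[3, 1] <- 7.0      # boundary: not called
  lod[2, 4] <- lod[4, 2] <- 7.1      # called
  rfm <- rfMatrixFrom(mk, rf, lod)
  chrom <- stats::setNames(c("1A", "1A", "2B", "2B"), mk)
  calls <- estRfTranslocations(rfm, chrom, lodThreshold = 7)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$chrA, "1A")
  expect_identical(calls$chrB, "2B")
  expect_equal(calls$maxLod, 7.1)
  expect_identical(calls$nPairs, 1L)
})

test_that("raising the threshold never adds calls", {
  set.seed(71)
  mk <- sprintf("m%02d", 1:12)
  lod <- matrix(runif(144, 0, 12), 12, 12); lod <- (lod + t(lod)) / 2
  rf <- matrix(0.3, 12, 12)
  rfm <- rfMatrixFrom(mk, rf, lod)
  chrom <- stats::setNames(rep(c("1A", "2A", "3A"), each = 4), mk)
  prev <- Inf
  for (thr in c(5, 7, 9, 11)) {
    n <- sum(estRfTranslocations(rfm, chrom, lodThreshold = thr)$nPairs)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("no-het markers are excluded from estRF calls", {
  mk <- c("a1", "b1")
  rf <- matrix(0.05, 2, 2); lod <- matrix(20, 2, 2)
  rfm <- rfMatrixFrom(mk, rf, lod)
  chrom <- stats::setNames(c("1A", "2B"), mk)
  expect_identical(nrow(estRfTranslocations(rfm, chrom)), 1L)
  expect_identical(nrow(estRfTranslocations(rfm, chrom, noHet = "a1")), 0L)
})

test_that("merging unions calls across methods without double counting", {
  mapped <- data.frame(population = "P1", method = "mapped",
                       chrA = "5B", chrB = "7B")
  estrf <- data.frame(population = c("P1", "P1", "P2"), method = "estrf",
                      chrA = c("5B", "1A", "3B"), chrB = c("7B", "2A", "7B"))
  mg <- mergeTranslocationCalls(mapped, estrf)
  expect_identical(nrow(mg$calls), 3L)
  both <- mg$calls[mg$calls$population == "P1" & mg$calls$chrA == "5B", ]
  expect_identical(both$methods, "estrf+mapped")
  expect_identical(
    mg$perPopulation$nTranslocations[mg$perPopulation$population == "P1"], 2L)
  expect_identical(mg$types$type[mg$types$chrA == "3B"], "T3B:7B")
  empty <- mergeTranslocationCalls(mapped[0, ], estrf[0, ])
  expect_identical(nrow(empty$calls), 0L)
})

test_that("carriers concentrated in one ancestral group are enriched", {
  groups <- stats::setNames(rep(paste0("G", 1:5), each = 11),
                            sprintf("P%02d", 1:55))
  uniformCarriers <- sprintf("P%02d", c(1, 12, 23, 34, 45))
  set.seed(72)
  resU <- ancestralEnrichment(uniformCarriers, groups)
  expect_gt(resU$p, 0.05)
  clustered <- sprintf("P%02d", 1:6)     # all in G1
  resC <- ancestralEnrichment(clustered, groups)
  expect_lt(resC$p, 0.05)
  expect_false(is.na(resC$pMonteCarlo))  # small expected cells -> MC route
  expect_identical(sum(resC$perGroup$observed), 6L)
  one <- stats::setNames(rep("G1", 10), sprintf("P%02d", 1:10))
  expect_warning(resS <- ancestralEnrichment("P01", one), "one ancestral")
  expect_true(is.na(resS$p))
})

test_that("a planted reciprocal translocation is seen by both routes", {
  set.seed(73)
  g <- quickGenome(c("5B", "7B"), c(120, 120), c(10, 10))
  x <- simulateSsdPopulation(simulationConfig(
    g, 94, 4,
    translocations = list(list(donor = "5B", segment = c(85, 115),
                               recipient = "7B", insertAt = 90,
                               reciprocal = TRUE)),
    missingRate = 0, errorRate = 0, populationId = "TP"))
  v <- validateGenotypes(x)
  rfm <- estRfMatrix(v$kept)
  asg <- stats::setNames(markerInfo(v$kept)$assignedChromosome,
                         rownames(genotypeCalls(v$kept)))
  ec <- estRfTranslocations(rfm, asg, lodThreshold = 7, noHet = v$noHet,
                            population = "TP")
  expect_true(any(ec$chrA == "5B" & ec$chrB == "7B"))
  map <- buildGeneticMap(x, rfm = rfm)
  mc <- mappedTranslocations(map, asg)
  expect_true(any(mc$chrA == "5B" & mc$chrB == "7B"))
})
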