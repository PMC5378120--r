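# The NAM-panel simulator: meiosis, SSD selfing, selection, noise.

test_that("a zero-length chromosome never recombines", {
  geom <- list(loci = data.frame(marker = c("m1", "m2"), chromosome = "c1",
                                 position = c(0, 0),
                                 nativeChromosome = "c1",
                                 nativePosition = c(0, 0), hidden = FALSE),
               lengths = c(c1 = 0))
  h1 <- c(1L, 1L); h2 <- c(0L, 0L)
  set.seed(1)
  for (i in 1:50) {
    g <- simulateMeiosis(h1, h2, geom)
    expect_true(all(g$gamete == g$gamete[1]))
    expect_identical(g$nCrossovers, 0L)
  }
})

test_that("crossover counts are Poisson(length/100) and adjacent rf is Haldane", {
  g <- genomeSpec(data.frame(name = "c1", length = 100),
                  positions = list(c1 = c(0, 1, 100)))
  geom <- realizeGeometry(g)
  h1 <- rep(1L, 3); h2 <- rep(0L, 3)
  set.seed(42)
  n <- 1e5
  nxo <- integer(n); rec <- logical(n)
  for (i in seq_len(n)) {
    gm <- simulateMeiosis(h1, h2, geom)
    nxo[i] <- gm$nCrossovers
    rec[i] <- gm$gamete[1] != gm$gamete[2]
  }
  expect_lt(abs(mean(nxo) - 1.00), 0.01)
  # Haldane r for d = 1 cM; 3.5 sigma Monte-Carlo band
  expect_lt(abs(mean(rec) - (1 - exp(-2 / 100)) / 2), 0.0011)
})

test_that("F4 genotype frequencies match the selfing expectation", {
  g <- genomeSpec(data.frame(name = "c1", length = 50),
                  markersPerChromosome = 3)
  set.seed(7)
  x <- simulateSsdPopulation(simulationConfig(g, nIndividuals = 1e4,
                                              generation = 4,
                                              missingRate = 0, errorRate = 0))
  freq <- tabulate(genotypeCalls(x), 3) / length(genotypeCalls(x))
  expect_equal(freq, c(0.4375, 0.125, 0.4375), tolerance = 0.01)
})

test_that("fully inbred populations carry no heterozygotes", {
  set.seed(8)
  x <- quickPop(quickGenome(), n = 50, k = Inf)
  expect_identical(sum(genotypeCalls(x) == 2L, na.rm = TRUE), 0L)
})

test_that("a lethal genotype class is eliminated by selection", {
  g <- genomeSpec(data.frame(name = "c1", length = 60),
                  markersPerChromosome = 3)
  sdlPos <- g$positions[["c1"]][2]
  set.seed(9)
  x <- simulateSsdPopulation(simulationConfig(
    g, nIndividuals = 300, generation = 4,
    sdl = list(list(chromosome = "c1", position = sdlPos,
                    weights = c(1, 1, 0))),
    missingRate = 0, errorRate = 0))
  atSdl <- genotypeCalls(x)[2, ]
  expect_identical(sum(atSdl == 3L, na.rm = TRUE), 0L)
})

test_that("observed two-locus classes match the recursion (independent routes)", {
  g <- genomeSpec(data.frame(name = "c1", length = 20),
                  positions = list(c1 = c(0, 20)))
  set.seed(10)
  x <- simulateSsdPopulation(simulationConfig(g, nIndividuals = 4000,
                                              generation = 4,
                                              missingRate = 0, errorRate = 0))
  calls <- genotypeCalls(x)
  # simulator recombines under Haldane; the recursion takes per-meiosis r
  r <- (1 - exp(-2 * 20 / 100)) / 2
  J <- twoLocusSelfingDistribution(r, 4)$joint
  obs <- table(factor(calls[1, ], 1:3), factor(calls[2, ], 1:3)) / ncol(calls)
  expect_lt(max(abs(as.vector(obs) - as.vector(J))), 0.02)
})

test_that("observation noise behaves as specified at the boundaries", {
  set.seed(11)
  x <- quickPop(quickGenome(), n = 40)
  x0 <- applyObservationNoise(x, 0, 0)
  expect_identical(genotypeCalls(x0), genotypeCalls(x))
  x1 <- applyObservationNoise(x, 1, 0)
  expect_true(all(is.na(genotypeCalls(x1))))
  expect_identical(simulationTruth(x1)$trueCalls,
                   simulationTruth(x)$trueCalls)
})

test_that("error flips are binomial and never produce the original code", {
  set.seed(12)
  calls <- matrix(1L, 1000, 100, dimnames = list(
    sprintf("M%04d", 1:1000), sprintf("I%03d", 1:100)))
  x <- makeRilGenotypes(calls, "pop", 4)
  xe <- applyObservationNoise(x, 0, 0.01)
  flips <- sum(genotypeCalls(xe) != 1L)
  expect_gt(flips, 1000 - 3 * 60)
  expect_lt(flips, 1000 + 3 * 60)
  expect_true(all(genotypeCalls(xe) %in% c(2L, 3L, 1L)))
})

test_that("seeded simulations are bit-reproducible", {
  g <- quickGenome()
  run <- function() {
    set.seed(99)
    simulateSsdPopulation(simulationConfig(g, 30, 4, missingRate = 0.05,
                                           errorRate = 0.01))
  }
  a <- run(); b <- run()
  expect_identical(genotypeCalls(a), genotypeCalls(b))
  expect_identical(simulationTruth(a)$xoCount, simulationTruth(b)$xoCount)
})

test_that("translocation geometry relocates the segment, inversions reflect it", {
  g <- genomeSpec(data.frame(name = c("5B", "7B"), length = c(100, 100)),
                  markersPerChromosome = c(5, 5))
  geo <- realizeGeometry(g, translocations = list(
    list(donor = "5B", segment = c(70, 100), recipient = "7B",
         insertAt = 80, reciprocal = FALSE)))
  moved <- geo$loci[geo$loci$nativeChromosome == "5B" &
                      geo$loci$nativePosition >= 70, ]
  expect_true(all(moved$chromosome == "7B"))
  expect_equal(moved$position, 80 + (moved$nativePosition - 70))
  expect_equal(unname(geo$lengths["7B"]), 130)

  gi <- realizeGeometry(g, inversions = list(
    list(chromosome = "5B", segment = c(25, 75))))
  inv <- gi$loci[gi$loci$nativeChromosome == "5B", ]
  inside <- inv$nativePosition >= 25 & inv$nativePosition <= 75
  expect_equal(inv$position[inside], 25 + 75 - inv$nativePosition[inside])
  expect_equal(inv$position[!inside], inv$nativePosition[!inside])
})

test_that("invalid configurations are rejected", {
  g <- quickGenome()
  expect_error(simulationConfig(g, nIndividuals = 1))
  expect_error(simulationConfig(g, missingRate = 1.5))
  expect_error(simulationConfig(g, sdl = list(list(chromosome = "1A",
                                                   position = 10,
                                                   weights = c(0, 0, 0)))))
  expect_error(genomeSpec(data.frame(name = "c1", length = -5)))
  expect_error(genomeSpec(data.frame(name = "c1", length = 10),
                          positions = list(c1 = c(5, 2))))
})
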