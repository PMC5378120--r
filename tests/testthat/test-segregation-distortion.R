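# HMM imputation, distortion scan, allele-ratio QC and hotspots.

test_that("imputation is the identity on clean, well-spaced data", {
  set.seed(61)
  g <- quickGenome("1A", 80, 8)
  x <- quickPop(g, n = 60)
  imp <- imputeGenotypes(x, trueGeneticMap(g))
  expect_identical(imp$calls, genotypeCalls(x))
  expect_true(all(abs(apply(imp$posterior, 1:2, sum) - 1) < 1e-9))
})

test_that("a flipped call between tight flanks is corrected or withheld", {
  g <- genomeSpec(data.frame(name = "1A", length = 2),
                  positions = list(`1A` = c(0, 1, 2)))
  calls <- matrix(rep(c(1L, 1L, 1L), 10), 3, 10,
                  dimnames = list(g$markers[["1A"]], sprintf("i%02d", 1:10)))
  calls[2, 1] <- 3L                        # isolated double flip
  x <- makeRilGenotypes(calls, "flip", 4)
  # with an error-tolerant model the flip is overridden by the flanks
  imp <- imputeGenotypes(x, trueGeneticMap(g), errorProb = 0.02)
  expect_identical(unname(imp$calls[2, 1]), 1L)
  # with the strict default neither state reaches the posterior floor:
  # the suspicious call is left missing rather than trusted
  imp0 <- imputeGenotypes(x, trueGeneticMap(g))
  expect_identical(unname(imp0$calls[2, 1]), NA_integer_)
  expect_gt(imp0$posterior[2, 1, 1], 0.05)  # flip no longer certain
})

test_that("an isolated marker falls back to prior-weighted emission", {
  g <- genomeSpec(data.frame(name = "1A", length = 10),
                  positions = list(`1A` = c(0)))
  calls <- matrix(c(2L, NA), 1, 2,
                  dimnames = list("1A.01", c("i1", "i2")))
  x <- makeRilGenotypes(calls, "iso", 4)
  imp <- imputeGenotypes(x, trueGeneticMap(g), errorProb = 1e-4)
  prior <- selfingGenotypeFrequencies(4)
  e <- c(1e-4 / 2, 1 - 1e-4, 1e-4 / 2)
  expect_equal(imp$posterior[1, 1, ], prior * e / sum(prior * e),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(imp$posterior[1, 2, ], unname(prior), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the distortion chi-square matches the direct formula", {
  calls <- matrix(c(rep(1L, 60), rep(2L, 10), rep(3L, 24)), 1, 94,
                  dimnames = list("mk", sprintf("i%02d", 1:94)))
  sc <- segregationScan(list(calls = calls, generation = 4))
  e <- c(0.4375, 0.125, 0.4375) * 94
  expect_equal(sc$chisq, sum((c(60, 10, 24) - e)^2 / e), tolerance = 1e-12)
  expect_identical(sc$direction, "Par_excess")

  perfect <- matrix(c(rep(1L, 41), rep(2L, 12), rep(3L, 41)), 1, 94,
                    dimnames = list("mk", sprintf("i%02d", 1:94)))
  sc2 <- segregationScan(list(calls = perfect, generation = 4))
  expect_lt(sc2$chisq, 0.1)
  expect_false(sc2$significant)
})

test_that("inbred populations are tested on the 1:1 homozygote ratio", {
  calls <- matrix(c(rep(1L, 70), rep(3L, 24)), 1, 94,
                  dimnames = list("mk", sprintf("i%02d", 1:94)))
  sc <- segregationScan(list(calls = calls, generation = Inf))
  expect_equal(sc$chisq, (70 - 47)^2 / 47 + (24 - 47)^2 / 47,
               tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up values and no-het markers are excluded", {
  calls <- do.call(rbind, lapply(1:4, function(i)
    matrix(c(rep(1L, 41), rep(2L, 12), rep(3L, 41)), 1, 94)))
  rownames(calls) <- paste0("m", 1:4)
  colnames(calls) <- sprintf("i%02d", 1:94)
  sc <- segregationScan(list(calls = calls, generation = 4),
                        noHet = "m4")
  expect_identical(nrow(sc), 3L)
  expect_false("m4" %in% sc$marker)
  expect_equal(stats::p.adjust(c(0.001, 0.01, 0.02, 0.05), "BH"),
               c(0.004, 0.02, 0.02 + 0.02 / 3, 0.05), tolerance = 1e-12)
})

test_that("a planted distortion locus is detected", {
  set.seed(62)
  g <- quickGenome("7B", 120, 5)
  sdlPos <- g$positions[["7B"]][3]
  x <- simulateSsdPopulation(simulationConfig(
    g, 94, 4, sdl = list(list(chromosome = "7B", position = sdlPos,
                              weights = c(1, 1, 0.4))),
    missingRate = 0, errorRate = 0))
  sc <- segregationScan(list(calls = genotypeCalls(x), generation = 4))
  expect_true(sc$significant[3])
  expect_identical(sc$direction[3], "Par_excess")
})

test_that("allele-ratio QC accepts neutral panels and flags biased ones", {
  set.seed(63)
  x <- quickPop(quickGenome(), n = 400)
  qc <- qcAlleleRatio(x)
  expect_false(qc$flag)
  expect_equal(qc$meanPar, 0.4375, tolerance = 0.03)
  expect_equal(qc$expected, 0.4375)

  biased <- matrix(sample(1:3, 50 * 94, TRUE, prob = c(0.60, 0.10, 0.30)),
                   50, 94, dimnames = list(sprintf("m%02d", 1:50),
                                           sprintf("i%02d", 1:94)))
  xb <- makeRilGenotypes(biased, "biased", 4)
  expect_true(qcAlleleRatio(xb)$flag)

  set.seed(64)
  xi <- quickPop(quickGenome(), n = 300, k = Inf)
  qi <- qcAlleleRatio(xi)
  expect_equal(qi$expected, 0.5)
  expect_equal(qi$meanPar, 0.5, tolerance = 0.04)
})

test_that("hotspots aggregate significant markers across populations", {
  cons <- methods::new("ConsensusMap",
                       table = data.frame(marker = paste0("m", 1:5),
                                          chromosome = "3B",
                                          position = c(0, 5, 12, 30, 44)),
                       K = c(`3B` = 1), diagnostics = data.frame(),
                       removed = data.frame())
  mkScan <- function(sig) data.frame(marker = paste0("m", 1:5),
                                     significant = sig,
                                     direction = "Par_excess")
  scans <- list(P1 = mkScan(c(TRUE, FALSE, FALSE, FALSE, FALSE)),
                P2 = mkScan(c(TRUE, FALSE, FALSE, FALSE, FALSE)),
                P3 = mkScan(c(TRUE, FALSE, FALSE, TRUE, FALSE)))
  hs <- sdlHotspots(scans, cons, minPops = 3)
  expect_identical(hs$byMarker$nPopulations[hs$byMarker$marker == "m1"], 3L)
  expect_true(hs$byMarker$hotspot[hs$byMarker$marker == "m1"])
  expect_false(any(hs$byMarker$hotspot[hs$byMarker$marker != "m1"]))
  empty <- sdlHotspots(list(P1 = mkScan(rep(FALSE, 5))), cons)
  expect_identical(nrow(empty$byMarker), 0L)
})
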