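# Obligate crossover counts and crossover-trait QTL mapping.

simpleMapTable <- function(markers, lg = "1A") {
  data.frame(marker = markers, lg = lg, chromosome = lg,
             position = seq(0, by = 10, length.out = length(markers)),
             stringsAsFactors = FALSE)
}

test_that("obligate crossover counting follows the transition rules", {
  tb <- simpleMapTable(c("a", "b", "c"))
  expect_identical(countCrossovers(c(a = 1L, b = 1L, c = 1L), tb), 0L)
  expect_identical(countCrossovers(c(a = 1L, b = 2L, c = 3L), tb), 2L)
  expect_identical(countCrossovers(c(a = 1L, b = NA, c = 3L), tb), 2L)
  expect_identical(countCrossovers(c(a = 1L, b = 3L, c = 1L), tb), 4L)
  # single-marker groups contribute nothing
  one <- simpleMapTable("a")
  expect_identical(countCrossovers(c(a = 3L), one), 0L)
})

test_that("counts are invariant to inserting missing calls", {
  tb5 <- simpleMapTable(c("a", "b", "c", "d", "e"))
  g <- c(a = 1L, b = 2L, c = NA, d = NA, e = 3L)
  expect_identical(countCrossovers(g, tb5),
                   countCrossovers(c(a = 1L, b = 2L, e = 3L),
                                   simpleMapTable(c("a", "b", "e"))))
})

test_that("sparser marker sets never see more obligate crossovers", {
  set.seed(81)
  g <- quickGenome("1A", 100, 20)
  x <- quickPop(g, n = 60)
  dense <- crossoverTrait(x, trueGeneticMap(g))
  sparseTb <- trueMapTable(g)[seq(1, 20, by = 2), ]
  sparse <- vapply(seq_len(ncol(x)), function(i)
    countCrossovers(genotypeCalls(x)[, i], sparseTb), integer(1))
  expect_true(all(sparse <= dense$counts))
  # counts track the realised crossover load of the lineage
  expect_gt(stats::cor(dense$counts, simulationTruth(x)$xoCount), 0.3)
  expect_error(crossoverTrait(x[, 0], trueGeneticMap(g)), "empty|2 individuals")
})

test_that("a constant trait yields a flat zero LOD curve", {
  set.seed(82)
  g <- quickGenome("1A", 80, 6)
  x <- quickPop(g, n = 40)
  imp <- imputeGenotypes(x, trueGeneticMap(g))
  sc <- qtlScan(rep(5, 40), imp)
  expect_true(all(sc$curve$lod == 0))
  expect_identical(nrow(sc$qtl), 0L)
})

test_that("the LOD curve is invariant under affine transforms of the trait", {
  set.seed(83)
  g <- quickGenome("1A", 80, 6)
  x <- quickPop(g, n = 60)
  imp <- imputeGenotypes(x, trueGeneticMap(g))
  y <- as.numeric(crossoverTrait(x, trueGeneticMap(g))$counts)
  l1 <- qtlScan(y, imp, lodThreshold = Inf)$curve$lod
  l2 <- qtlScan(3 * y - 7, imp, lodThreshold = Inf)$curve$lod
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("a detectable planted modifier is mapped near its true position", {
  # obligate counts only partially observe the meiotic rate (selfing hides
  # crossovers in fixed regions), so detection needs a large population
  set.seed(84)
  g <- quickGenome(c("1A", "2A"), c(120, 120), c(12, 12))
  x <- simulateSsdPopulation(simulationConfig(
    g, 1200, 4,
    xoModifier = list(chromosome = "1A", position = 60, effect = 1),
    missingRate = 0, errorRate = 0))
  imp <- imputeGenotypes(x, trueGeneticMap(g))
  tr <- crossoverTrait(x, trueGeneticMap(g), imputed = imp)
  sc <- qtlScan(tr, imp, lodThreshold = 2)
  expect_gt(nrow(sc$qtl), 0)
  top <- sc$qtl[which.max(sc$qtl$lod), ]
  expect_identical(top$chromosome, "1A")
  expect_lte(abs(top$position - 60), 15)
  expect_identical(top$increasingAllele, "other")
  # confidence interval contains the peak marker
  expect_true(top$marker %in% strsplit(top$ciMarkers, ",")[[1]])
  mq <- multipleQtlModel(sc, tr, imp)
  expect_true(top$marker %in% mq$qtl$marker)
})

test_that("common QTL projection needs the minimum population count", {
  cons <- methods::new("ConsensusMap",
                       table = data.frame(marker = paste0("m", 1:6),
                                          chromosome = "4A",
                                          position = seq(0, 50, by = 10)),
                       K = c(`4A` = 1), diagnostics = data.frame(),
                       removed = data.frame())
  qtl <- function(ci) data.frame(marker = ci[1], ciMarkers = paste(ci, collapse = ","))
  recs <- list(P1 = qtl(c("m2", "m3")), P2 = qtl(c("m2", "m3")),
               P3 = qtl(c("m3", "m4")), P4 = qtl(c("m3")),
               P5 = qtl(c("m6")))
  out <- projectCommonQtl(recs, cons, minPops = 4)
  expect_identical(out$regions$markers, "m3")
  expect_identical(out$regions$nPopulations, 4L)
  none <- projectCommonQtl(recs["P1"], cons, minPops = 4)
  expect_identical(nrow(none$regions), 0L)
})
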