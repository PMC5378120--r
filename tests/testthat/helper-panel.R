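# Shared fixtures: small genomes and populations built in code.

quickGenome <- function(chroms = c("1A", "2A"), len = c(100, 90),
                        mpc = c(10, 8)) {
  genomeSpec(data.frame(name = chroms, length = len),
             markersPerChromosome = mpc)
}

quickPop <- function(genome, n = 60, k = 4, seed = NULL, id = "P1", ...) {
  if (!is.null(seed)) set.seed(seed)
  simulateSsdPopulation(simulationConfig(genome, nIndividuals = n,
                                         generation = k, missingRate = 0,
                                         errorRate = 0, populationId = id,
                                         ...))
}

# the genome's true marker order/positions as a map table
trueMapTable <- function(genome) {
  do.call(rbind, lapply(genome$chromosomes$name, function(ch)
    data.frame(marker = genome$markers[[ch]], lg = ch, chromosome = ch,
               position = genome$positions[[ch]], stringsAsFactors = FALSE)))
}

trueGeneticMap <- function(genome, id = "truth") {
  methods::new("GeneticMap", populationId = id, table = trueMapTable(genome),
               sarf = numeric(), stats = list())
}

# hand-built RfMatrix from explicit rf / lod entries
rfMatrixFrom <- function(markers, rf, lod, k = 4) {
  dimnames(rf) <- dimnames(lod) <- list(markers, markers)
  diag(rf) <- NA; diag(lod) <- 0
  methods::new("RfMatrix", rf = rf, lod = lod, generation = k)
}
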