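# Meiosis-level simulator for NAM panels of selfed recombinant inbred
# lines.  Crossovers are Poisson with mean length/100 per chromosome (no
# interference, Haldane regime) and uniform positions; structural
# variants are expressed through a "realized geometry" that relocates
# (translocation) or reflects (inversion) marker positions for carrier
# crosses, so that rearranged blocks cosegregate with their physical
# location; selection acts as relative zygote survival at distortion
# loci each selfing round; single-seed descent keeps exactly one
# offspring per line per generation.

#' Genome specification for simulation
#'
#' @param chromosomes data.frame with columns `name` and `length` (cM > 0).
#' @param positions named list (by chromosome) of strictly increasing
#'   marker positions in cM; defaults to even spacing of
#'   `markersPerChromosome` markers from 0 to the chromosome length.
#' @param markersPerChromosome integer vector recycled over chromosomes.
#' @return a `genomeSpec` list: `chromosomes`, `positions`, `markers`
#'   (marker names per chromosome, `"<chrom>.<i>"`).
#' @export
genomeSpec <- function(chromosomes, positions = NULL,
                       markersPerChromosome = 12) {
  stopifnot(all(c("name", "length") %in% names(chromosomes)),
            all(chromosomes$length > 0),
            !anyDuplicated(chromosomes$name))
  if (is.null(positions)) {
    mpc <- rep_len(markersPerChromosome, nrow(chromosomes))
    positions <- lapply(seq_len(nrow(chromosomes)), function(i)
      seq(0, chromosomes$length[i], length.out = mpc[i]))
    names(positions) <- chromosomes$name
  }
  for (ch in chromosomes$name) {
    p <- positions[[ch]]
    if (is.null(p) || is.unsorted(p, strictly = TRUE) ||
        min(p) < 0 || max(p) > chromosomes$length[chromosomes$name == ch])
      stop("positions on ", ch, " must be strictly increasing within bounds")
  }
  markers <- lapply(chromosomes$name, function(ch)
    sprintf("%s.%02d", ch, seq_along(positions[[ch]])))
  names(markers) <- chromosomes$name
  structure(list(chromosomes = chromosomes, positions = positions,
                 markers = markers), class = "genomeSpec")
}

#' Wheat-like default genome: 21 chromosomes, sparse D genome
#'
#' Emulates the marker coverage of a KASP-genotyped hexaploid wheat NAM
#' population: chromosomes 1A-7A and 1B-7B carry 8-31 markers each, the
#' D-genome chromosomes are sparse (3-6 markers).  Genetic lengths are
#' set to typical per-chromosome map lengths (110-160 cM).
#'
#' @return a `genomeSpec`.
#' @export
wheatGenomeSpec <- function() {
  nm <- paste0(rep(1:7, each = 3), rep(c("A", "B", "D"), 7))
  len <- rep(c(150, 160, 120), 7)
  mpc <- rep(0L, 21)
  mpc[seq(1, 21, by = 3)] <- c(14L, 22L, 10L, 17L, 25L, 31L, 12L)  # A genome
  mpc[seq(2, 21, by = 3)] <- c(19L, 28L, 16L, 21L, 24L, 18L, 8L)   # B genome
  mpc[seq(3, 21, by = 3)] <- c(5L, 4L, 6L, 3L, 4L, 5L, 3L)         # D genome
  genomeSpec(data.frame(name = nm, length = len), markersPerChromosome = mpc)
}

#' Simulation configuration for one SSD population
#'
#' @param genome a [genomeSpec()].
#' @param nIndividuals number of lines (>= 2).
#' @param generation selfing generation k (4, 5, 6, or `Inf`).
#' @param translocations list of
#'   `list(donor =, segment = c(a, b), recipient =, insertAt =, reciprocal =)`.
#' @param inversions list of `list(chromosome =, segment = c(a, b))`.
#' @param sdl list of `list(chromosome =, position =, weights = c(AA, AB, BB))`
#'   relative zygote survival weights, applied each selfing round.
#' @param xoModifier `list(chromosome =, position =, effect =)`: additive
#'   shift of every per-chromosome expected crossover number per copy of
#'   the non-reference allele at the modifier locus.
#' @param missingRate,errorRate observation-noise rates in `[0, 1]`.
#' @param populationId,parents,ancestralGroup population descriptors.
#' @return a `simulationConfig` list.
#' @export
simulationConfig <- function(genome, nIndividuals = 94, generation = 4,
                             translocations = list(), inversions = list(),
                             sdl = list(), xoModifier = NULL,
                             missingRate = 0.02, errorRate = 0.005,
                             populationId = "SimPop",
                             parents = c("Par", "Other"),
                             ancestralGroup = NA_character_) {
  stopifnot(inherits(genome, "genomeSpec"), nIndividuals >= 2,
            is.infinite(generation) || generation >= 2,
            missingRate >= 0, missingRate <= 1,
            errorRate >= 0, errorRate <= 1)
  for (s in sdl)
    if (any(s$weights < 0) || all(s$weights == 0))
      stop("sdl weights must be non-negative and not all zero")
  structure(list(genome = genome, nIndividuals = nIndividuals,
                 generation = generation, translocations = translocations,
                 inversions = inversions, sdl = sdl,
                 xoModifier = xoModifier, missingRate = missingRate,
                 errorRate = errorRate, populationId = populationId,
                 parents = parents, ancestralGroup = ancestralGroup),
            class = "simulationConfig")
}

#' Realized marker geometry of a carrier cross
#'
#' Expresses structural variants carried by a cross as relocated marker
#' coordinates: a translocated segment's markers move to the recipient
#' chromosome at the insertion point (recipient markers beyond it shift
#' right; for reciprocal events the recipient interval of equal length
#' moves to the donor in exchange), and inverted segments have their
#' marker positions reflected in place.  Meiosis is simulated on these
#' effective coordinates, so rearranged blocks segregate with their
#' physical location while keeping their native (a-priori) chromosome
#' assignment in the marker metadata.
#'
#' @param genome a [genomeSpec()].
#' @param translocations,inversions as in [simulationConfig()].
#' @param extraLoci optional data.frame (`marker`, `chromosome`,
#'   `position`) of hidden loci (selection / modifier loci) to carry
#'   through meiosis without emitting them as markers.
#' @return list: `loci` data.frame (`marker`, `chromosome`, `position`,
#'   `nativeChromosome`, `nativePosition`, `hidden`), `lengths` named
#'   effective chromosome lengths.
#' @export
realizeGeometry <- function(genome, translocations = list(),
                            inversions = list(), extraLoci = NULL) {
  loci <- do.call(rbind, lapply(genome$chromosomes$name, function(ch)
    data.frame(marker = genome$markers[[ch]], chromosome = ch,
               position = genome$positions[[ch]],
               nativeChromosome = ch,
               nativePosition = genome$positions[[ch]],
               hidden = FALSE, stringsAsFactors = FALSE)))
  if (!is.null(extraLoci) && nrow(extraLoci)) {
    loci <- rbind(loci, data.frame(
      marker = extraLoci$marker, chromosome = extraLoci$chromosome,
      position = extraLoci$position,
      nativeChromosome = extraLoci$chromosome,
      nativePosition = extraLoci$position,
      hidden = TRUE, stringsAsFactors = FALSE))
  }
  lengths <- stats::setNames(genome$chromosomes$length,
                             genome$chromosomes$name)
  for (tr in translocations) {
    a <- tr$segment[1]; b <- tr$segment[2]
    if (a >= b) stop("translocation segment must be a proper interval")
    segLen <- b - a
    inSeg <- loci$chromosome == tr$donor & loci$position >= a &
      loci$position <= b
    if (isTRUE(tr$reciprocal)) {
      inRec <- loci$chromosome == tr$recipient &
        loci$position >= tr$insertAt & loci$position <= tr$insertAt + segLen
      loci$chromosome[inRec] <- tr$donor
      loci$position[inRec] <- a + (loci$position[inRec] - tr$insertAt)
      loci$chromosome[inSeg] <- tr$recipient
      loci$position[inSeg] <- tr$insertAt + (loci$position[inSeg] - a)
    } else {
      shift <- loci$chromosome == tr$recipient & loci$position > tr$insertAt
      loci$position[shift] <- loci$position[shift] + segLen
      loci$chromosome[inSeg] <- tr$recipient
      loci$position[inSeg] <- tr$insertAt + (loci$position[inSeg] - a)
      lengths[tr$recipient] <- lengths[tr$recipient] + segLen
    }
  }
  for (iv in inversions) {
    a <- iv$segment[1]; b <- iv$segment[2]
    inSeg <- loci$chromosome == iv$chromosome & loci$position >= a &
      loci$position <= b
    loci$position[inSeg] <- a + b - loci$position[inSeg]
  }
  rownames(loci) <- NULL
  list(loci = loci, lengths = lengths)
}

#' Simulate one meiosis
#'
#' Draws a gamete from a diplotype: per chromosome the crossover count is
#' Poisson with mean length(cM)/100 (no interference), crossover positions
#' are uniform, and the gamete is the alternating mosaic of the two
#' homologues starting from a random one.  Allele transmission follows the
#' effective (rearranged) marker coordinates of `geometry`.
#'
#' @param h1,h2 integer haplotype vectors (one allele per locus, in
#'   `geometry$loci` order; 1 = reference allele, 0 = alternative).
#' @param geometry a [realizeGeometry()] result.
#' @param xoExtra additive shift of every per-chromosome crossover mean
#'   (crossover-modifier effect, in crossovers per meiosis); default 0.
#' @return list: `gamete` integer vector, `nCrossovers` total drawn.
#' @export
simulateMeiosis <- function(h1, h2, geometry, xoExtra = 0) {
  prep <- geometry$prepared %||% .prepareGeometry(geometry)
  gam <- integer(prep$nLoci)
  nc <- length(prep$lengths)
  k <- stats::rpois(nc, pmax(0, prep$lengths / 100 + xoExtra))
  start <- stats::runif(nc) < 0.5          # TRUE: begin on homologue 1
  for (c in seq_len(nc)) {
    idx <- prep$idx[[c]]
    if (!length(idx)) next
    if (k[c] == 0L) {
      gam[idx] <- if (start[c]) h1[idx] else h2[idx]
    } else {
      seg <- findInterval(prep$pos[[c]],
                          sort(stats::runif(k[c], 0, prep$lengths[c])))
      src1 <- (seg %% 2L == 0L) == start[c]
      gam[idx] <- ifelse(src1, h1[idx], h2[idx])
    }
  }
  list(gamete = gam, nCrossovers = sum(k))
}

.prepareGeometry <- function(geometry) {
  loci <- geometry$loci
  chs <- names(geometry$lengths)
  idx <- lapply(chs, function(ch) which(loci$chromosome == ch))
  list(nLoci = nrow(loci),
       lengths = unname(geometry$lengths),
       idx = idx,
       pos = lapply(idx, function(i) loci$position[i]))
}

#' Simulate one selfed-RIL population by single-seed descent
#'
#' Starts every line from the F1 heterozygote of the two founders and
#' applies `k - 1` rounds of self-pollination with exactly one offspring
#' kept per line per generation.  Selection weights of distortion loci
#' act as relative zygote survival each round (rejection sampling);
#' lines for which all producible offspring have zero weight raise an
#' error.  A crossover modifier scales each meiosis' expected crossover
#' number according to the parent's genotype at the modifier locus.
#' Observation noise is applied afterwards via [applyObservationNoise()];
#' the truth record keeps the pre-noise calls.
#'
#' `generation = Inf` is simulated as 25 selfing rounds (residual
#' heterozygosity < 1e-7) and reported as fully inbred.
#'
#' @param config a [simulationConfig()].
#' @return a [RilGenotypes-class] whose `simulationTruth()` holds
#'   `trueCalls`, `xoCount` (realised crossovers per line, summed over
#'   the lineage's meioses), `geometry` and the planted variant lists.
#' @export
simulateSsdPopulation <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  genome <- config$genome
  extra <- .hiddenLoci(config)
  geom <- realizeGeometry(genome, config$translocations, config$inversions,
                          extraLoci = extra)
  geom$prepared <- .prepareGeometry(geom)
  loci <- geom$loci
  nl <- nrow(loci)
  k <- config$generation
  rounds <- if (is.infinite(k)) 25L else as.integer(k) - 1L
  n <- config$nIndividuals

  modIdx <- match(".xoMod", loci$marker)
  sdlIdx <- match(sprintf(".sdl%d", seq_along(config$sdl)), loci$marker)
  sdlW <- lapply(config$sdl, function(s) s$weights / max(s$weights))
  effPerAllele <- if (!is.null(config$xoModifier)) config$xoModifier$effect
                  else 0

  H1 <- matrix(1L, nl, n)   # reference-parent haplotype
  H2 <- matrix(0L, nl, n)
  xoCount <- integer(n)
  for (t in seq_len(rounds)) {
    for (i in seq_len(n)) {
      h1 <- H1[, i]; h2 <- H2[, i]
      extra <- 0
      if (!is.na(modIdx) && effPerAllele != 0) {
        dosB <- 2L - (h1[modIdx] + h2[modIdx])
        extra <- effPerAllele * dosB
      }
      ok <- FALSE
      for (attempt in seq_len(1000L)) {
        g1 <- simulateMeiosis(h1, h2, geom, xoExtra = extra)
        g2 <- simulateMeiosis(h1, h2, geom, xoExtra = extra)
        w <- 1
        for (s in seq_along(sdlW)) {
          gt <- 3L - (g1$gamete[sdlIdx[s]] + g2$gamete[sdlIdx[s]])
          w <- w * sdlW[[s]][gt]
        }
        if (w >= 1 || stats::runif(1) < w) { ok <- TRUE; break }
      }
      if (!ok) stop("selection weights eliminate all offspring of line ", i)
      H1[, i] <- g1$gamete; H2[, i] <- g2$gamete
      xoCount[i] <- xoCount[i] + g1$nCrossovers + g2$nCrossovers
    }
  }

  if (is.infinite(k)) {
    # drive residual heterozygosity (< 1e-7 after 25 rounds) to fixation
    het <- which(H1 != H2)
    if (length(het)) {
      pick <- stats::runif(length(het)) < 0.5
      H1[het] <- ifelse(pick, H1[het], H2[het])
      H2[het] <- H1[het]
    }
  }

  vis <- !loci$hidden
  callsTrue <- 3L - (H1[vis, , drop = FALSE] + H2[vis, , drop = FALSE])
  rownames(callsTrue) <- loci$marker[vis]
  colnames(callsTrue) <- sprintf("%s.L%03d", config$populationId, seq_len(n))

  truth <- list(trueCalls = callsTrue, xoCount = xoCount,
                geometry = geom,
                translocations = config$translocations,
                inversions = config$inversions,
                sdl = config$sdl, xoModifier = config$xoModifier)
  x <- makeRilGenotypes(callsTrue,
                        populationId = config$populationId,
                        generation = config$generation,
                        assignedChromosome = loci$nativeChromosome[vis],
                        parents = config$parents,
                        ancestralGroup = config$ancestralGroup,
                        truth = truth)
  applyObservationNoise(x, config$missingRate, config$errorRate)
}

.hiddenLoci <- function(config) {
  rows <- list()
  for (s in seq_along(config$sdl))
    rows[[length(rows) + 1L]] <- data.frame(
      marker = sprintf(".sdl%d", s),
      chromosome = config$sdl[[s]]$chromosome,
      position = config$sdl[[s]]$position, stringsAsFactors = FALSE)
  if (!is.null(config$xoModifier))
    rows[[length(rows) + 1L]] <- data.frame(
      marker = ".xoMod", chromosome = config$xoModifier$chromosome,
      position = config$xoModifier$position, stringsAsFactors = FALSE)
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Apply missing-data and genotyping-error noise to observed calls
#'
#' Each call is independently set missing with probability `missingRate`;
#' surviving calls are replaced by one of the two other genotype codes
#' (uniformly) with probability `errorRate`.  The simulation truth stored
#' in the object is untouched.
#'
#' @param x a [RilGenotypes-class].
#' @param missingRate,errorRate rates in `[0, 1]`.
#' @return a [RilGenotypes-class] with noisy calls.
#' @export
applyObservationNoise <- function(x, missingRate, errorRate) {
  stopifnot(missingRate >= 0, missingRate <= 1,
            errorRate >= 0, errorRate <= 1)
  calls <- genotypeCalls(x)
  nc <- length(calls)
  if (missingRate > 0)
    calls[stats::runif(nc) < missingRate] <- NA_integer_
  if (errorRate > 0) {
    hit <- which(!is.na(calls) & stats::runif(nc) < errorRate)
    if (length(hit)) {
      shift <- sample.int(2L, length(hit), replace = TRUE)
      calls[hit] <- ((calls[hit] - 1L + shift) %% 3L) + 1L
    }
  }
  SummarizedExperiment::assay(x, "calls") <- calls
  x
}

#' Simulate a NAM panel of SSD populations
#'
#' Convenience wrapper: builds one [simulateSsdPopulation()] per
#' configuration, deriving a deterministic per-population seed from
#' `seed` so panels are reproducible as a whole.
#'
#' @param configs list of [simulationConfig()] objects.
#' @param seed panel-level seed (integer) or `NULL` to use the current
#'   RNG state.
#' @return named list of [RilGenotypes-class] objects.
#' @export
simulateNamPanel <- function(configs, seed = NULL) {
  out <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    if (!is.null(seed)) set.seed((seed + 7919L * i) %% .Machine$integer.max)
    out[[i]] <- simulateSsdPopulation(configs[[i]])
  }
  names(out) <- vapply(configs, `[[`, character(1), "populationId")
  out
}
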