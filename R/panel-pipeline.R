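# End-to-end per-panel workflow: maps -> consensus -> map comparison ->
# segregation distortion -> translocations -> crossover QTL, with a
# Table-1-style per-population report.

#' Chromosomes absent from a map
#'
#' @param map a [GeneticMap-class].
#' @param expected character vector of expected chromosomes (for
#'   hexaploid wheat, the 21 chromosomes 1A-7D).
#' @return character vector of expected chromosomes with no linkage
#'   group labelled to them.
#' @export
missingChromosomes <- function(map, expected) {
  setdiff(expected, unique(mapTable(map)$chromosome))
}

#' Run the full NAM-panel analysis
#'
#' Orchestrates, per population: validation, pairwise rf/LOD estimation,
#' map construction, HMM imputation, segregation-distortion scan,
#' allele-ratio QC, translocation calling (mapped + estRF), crossover
#' trait and QTL mapping; then across the panel: consensus maps, map
#' comparisons (MDR, order congruence), distortion hotspots, merged
#' translocation types and common crossover QTL.  Populations failing
#' allele-ratio QC are retained with a flag but excluded from the panel
#' aggregate row.
#'
#' @param populations named list of [RilGenotypes-class] objects.
#' @param expectedChromosomes chromosomes the panel should cover.
#' @param K candidate consensus map intervals (default `1:3`).
#' @param lodMin,rfMax,maxMissing,gapCm map-construction parameters.
#' @param alpha significance level for the distortion scan.
#' @param translocLod strict LOD threshold for estRF calls (default 7).
#' @param qtlLod putative/confirmation QTL LOD threshold (default 2).
#' @param minPopsHotspot,minPopsQtl cross-population thresholds.
#' @param outDir optional directory for TSV artifacts.
#' @return list with `report` (per-population data.frame), `aggregate`
#'   (mean/sd/min/max over unflagged populations), and all stage
#'   artifacts (`maps`, `consensus`, `comparison`, `segdist`, `qc`,
#'   `hotspots`, `translocations`, `qtl`, `commonQtl`).
#' @export
runPanel <- function(populations, expectedChromosomes = NULL, K = 1:3,
                     lodMin = 3, rfMax = 0.3, maxMissing = 0.10,
                     gapCm = 35, alpha = 0.05, translocLod = 7,
                     qtlLod = 2, minPopsHotspot = 3, minPopsQtl = 4,
                     outDir = NULL) {
  if (is.null(names(populations)))
    names(populations) <- vapply(populations, populationId, character(1))
  maps <- list(); scans <- list(); qcs <- list(); traits <- list()
  qtls <- list(); mappedCalls <- list(); estrfCalls <- list()
  for (pid in names(populations)) {
    x <- populations[[pid]]
    res <- tryCatch({
      val <- validateGenotypes(x, maxMissing = maxMissing)
      rfm <- estRfMatrix(val$kept)
      map <- buildGeneticMap(x, lodMin = lodMin, rfMax = rfMax,
                             maxMissing = maxMissing, gapCm = gapCm,
                             rfm = rfm)
      keepOnMap <- val$kept[rownames(val$kept) %in% mapTable(map)$marker, ]
      imp <- imputeGenotypes(keepOnMap, map)
      scan <- segregationScan(imp, noHet = val$noHet, alpha = alpha)
      qc <- qcAlleleRatio(x)
      assignments <- stats::setNames(markerInfo(x)$assignedChromosome,
                                     markerInfo(x)$name)
      mapped <- mappedTranslocations(map, assignments)
      tbm <- mapTable(map)
      lgChrom <- stats::setNames(tbm$chromosome, tbm$marker)
      estrf <- estRfTranslocations(rfm, lgChrom, lodThreshold = translocLod,
                                   noHet = val$noHet, population = pid)
      trait <- crossoverTrait(x, map, imputed = imp)
      sc <- qtlScan(trait, imp, lodThreshold = qtlLod)
      mq <- multipleQtlModel(sc, trait, imp, lodThreshold = qtlLod)
      list(map = map, scan = scan, qc = qc, mapped = mapped,
           estrf = estrf, trait = trait, qtl = mq$qtl)
    }, error = function(e)
      stop("population '", pid, "': ", conditionMessage(e), call. = FALSE))
    maps[[pid]] <- res$map; scans[[pid]] <- res$scan
    qcs[[pid]] <- res$qc; traits[[pid]] <- res$trait
    qtls[[pid]] <- res$qtl
    mappedCalls[[pid]] <- res$mapped; estrfCalls[[pid]] <- res$estrf
  }

  consensus <- buildConsensusMap(maps, K = K)
  comparison <- compareMapsToConsensus(maps, consensus)
  hotspots <- sdlHotspots(scans, consensus, minPops = minPopsHotspot)
  transloc <- mergeTranslocationCalls(
    do.call(rbind, lapply(mappedCalls, `[`,
                          c("population", "method", "chrA", "chrB"))),
    do.call(rbind, lapply(estrfCalls, `[`,
                          c("population", "method", "chrA", "chrB"))))
  commonQtl <- projectCommonQtl(qtls, consensus, minPops = minPopsQtl)

  if (is.null(expectedChromosomes))
    expectedChromosomes <- sort(unique(unlist(
      lapply(maps, function(m) unique(mapTable(m)$chromosome)))))

  rows <- lapply(names(populations), function(pid) {
    map <- maps[[pid]]; st <- map@stats; scan <- scans[[pid]]
    nTr <- transloc$perPopulation$nTranslocations[
      match(pid, transloc$perPopulation$population)]
    ord <- comparison$order
    mdr <- comparison$mdr
    sig <- scan[scan$significant, , drop = FALSE]
    data.frame(
      population = pid,
      size = ncol(populations[[pid]]),
      linkedMarkers = st$linkedMarkers,
      cosegregatingMarkers = st$cosegregatingMarkers,
      mapLength = st$mapLength,
      nLG = st$nLG,
      missingChromosomes = paste(
        missingChromosomes(map, expectedChromosomes), collapse = ","),
      nIncongruent = sum(ord$population == pid & ord$class == "incongruent"),
      nExpanded = sum(mdr$population == pid & mdr$expanded),
      pctSDL = attr(scan, "percentDistorted"),
      nSdlPar = sum(sig$direction == "Par_excess"),
      nSdlOther = sum(sig$direction == "other_excess"),
      nTranslocations = if (length(nTr) && !is.na(nTr)) nTr else 0L,
      meanCrossovers = traits[[pid]]$mean,
      nCrossoverQtl = nrow(qtls[[pid]]),
      qcFlag = qcs[[pid]]$flag,
      stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL

  num <- vapply(report, is.numeric, logical(1))
  use <- !report$qcFlag
  aggregate <- do.call(rbind, lapply(c("mean", "sd", "min", "max"),
    function(f) {
      v <- vapply(report[use, num, drop = FALSE],
                  function(col) get(f)(col), numeric(1))
      data.frame(statistic = f, t(v), check.names = FALSE)
    }))
  rownames(aggregate) <- NULL

  out <- list(report = report, aggregate = aggregate, maps = maps,
              consensus = consensus, comparison = comparison,
              segdist = scans, qc = qcs, hotspots = hotspots,
              translocations = transloc, traits = traits, qtl = qtls,
              commonQtl = commonQtl)
  if (!is.null(outDir)) .writePanelArtifacts(out, outDir)
  out
}

.writePanelArtifacts <- function(panel, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(panel$report, "panel_report.tsv")
  tsv(mapTable(panel$consensus), "consensus_map.tsv")
  tsv(panel$comparison$mdr, "mdr.tsv")
  tsv(panel$comparison$order, "order_comparison.tsv")
  tsv(panel$translocations$calls, "translocation_calls.tsv")
  tsv(panel$translocations$types, "translocation_types.tsv")
  for (pid in names(panel$maps))
    writeGeneticMap(panel$maps[[pid]],
                    file.path(outDir, sprintf("map_%s.tsv", pid)))
  invisible(outDir)
}
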