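# Readers/writers for the package's plain-text formats and input validation.
#
# Genotype files use a rotated ("csvr"-like) CSV dialect: comment lines
# starting with '#', then a header row "marker,chromosome,<id1>,<id2>,...",
# then one row per marker with its name, a-priori chromosome assignment
# (may be empty) and one call per individual.  Population metadata
# (generation, parents, ancestral group) travel in a YAML sidecar.

DEFAULT_SYMBOLS <- c(AA = "A", AB = "H", BB = "B", missing = "-")

#' Construct a RilGenotypes object
#'
#' @param calls markers x individuals matrix; either integer codes
#'   (1 = AA, 2 = AB, 3 = BB, NA) or characters in the symbol map.
#' @param populationId population identifier.
#' @param generation selfing generation: 4, 5, 6 or `Inf`.
#' @param assignedChromosome a-priori chromosome per marker (NA allowed).
#' @param parents length-2 character (reference parent first).
#' @param ancestralGroup ancestral group of the non-reference parent.
#' @param assayType per-marker assay type ("SNP"/"SSR").
#' @param symbols symbol map used when `calls` is character.
#' @param truth optional simulation-truth list.
#' @return a [RilGenotypes-class].
#' @export
makeRilGenotypes <- function(calls, populationId, generation,
                             assignedChromosome = NULL,
                             parents = c("Par", "Other"),
                             ancestralGroup = NA_character_,
                             assayType = "SNP",
                             symbols = DEFAULT_SYMBOLS,
                             truth = list()) {
  calls <- as.matrix(calls)
  if (is.character(calls)) {
    m <- matrix(NA_integer_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
    for (g in 1:3) m[calls == symbols[g]] <- g
    bad <- !is.na(calls) & calls != symbols["missing"] & is.na(m)
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("unknown genotype code '%s' at marker '%s', individual '%s'",
                   calls[w[1], w[2]], rownames(calls)[w[1]] %||% w[1],
                   colnames(calls)[w[2]] %||% w[2]))
    }
    calls <- m
  }
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("M%03d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("I%03d", seq_len(ncol(calls)))
  if (anyDuplicated(rownames(calls)))
    stop("duplicate marker names: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "))
  if (is.null(assignedChromosome))
    assignedChromosome <- rep(NA_character_, nrow(calls))
  rd <- S4Vectors::DataFrame(
    assignedChromosome = as.character(assignedChromosome),
    assayType = rep_len(assayType, nrow(calls)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), rowData = rd)
  metadata(se) <- list(populationId = populationId,
                       generation = generation,
                       parents = parents,
                       ancestralGroup = ancestralGroup)
  methods::new("RilGenotypes", se, truth = truth)
}

#' Write / read genotype matrices in the rotated CSV dialect
#'
#' `writeGenotypes()` writes the calls plus a provenance comment header
#' and a YAML metadata sidecar at `<path>.yaml`; `readGenotypes()` reads
#' them back.  Round-trips are identity on the calls and metadata.
#'
#' @param x a [RilGenotypes-class].
#' @param path file path for the CSV.
#' @param symbols symbol map (default A/H/B/-).
#' @return `readGenotypes()` returns a [RilGenotypes-class].
#' @export
writeGenotypes <- function(x, path, symbols = DEFAULT_SYMBOLS) {
  calls <- genotypeCalls(x)
  sym <- matrix(symbols[["missing"]], nrow(calls), ncol(calls))
  for (g in 1:3) sym[!is.na(calls) & calls == g] <- symbols[[g]]
  info <- markerInfo(x)
  chr <- ifelse(is.na(info$assignedChromosome), "", info$assignedChromosome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nammap genotype file v%s",
                     as.character(utils::packageVersion("nammap"))), con)
  writeLines(paste(c("marker", "chromosome", colnames(calls)), collapse = ","), con)
  for (i in seq_len(nrow(calls)))
    writeLines(paste(c(rownames(calls)[i], chr[i], sym[i, ]), collapse = ","), con)
  meta <- list(populationId = populationId(x),
               generation = if (is.infinite(generation(x))) "inf"
                            else generation(x),
               parents = as.list(parents(x)),
               ancestralGroup = ancestralGroup(x))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeGenotypes
#' @param metadata optional metadata list overriding the YAML sidecar.
#' @export
readGenotypes <- function(path, symbols = DEFAULT_SYMBOLS, metadata = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("empty genotype file: ", path)
  cells <- strsplit(lines, ",", fixed = TRUE)
  header <- cells[[1]]
  if (length(header) < 3 || header[1] != "marker")
    stop("malformed genotype header in ", path)
  ids <- header[-(1:2)]
  body <- cells[-1]
  widths <- lengths(body)
  if (any(widths != length(header)))
    stop(sprintf("ragged row at line %d of %s",
                 which(widths != length(header))[1] + 1L, path))
  mk <- vapply(body, `[`, character(1), 1)
  if (anyDuplicated(mk))
    stop("duplicate marker names: ",
         paste(unique(mk[duplicated(mk)]), collapse = ", "))
  chr <- vapply(body, `[`, character(1), 2)
  chr[chr == ""] <- NA_character_
  callChr <- do.call(rbind, lapply(body, function(r) r[-(1:2)]))
  dimnames(callChr) <- list(mk, ids)
  if (is.null(metadata)) {
    side <- paste0(path, ".yaml")
    metadata <- if (file.exists(side)) yaml::read_yaml(side) else list()
  }
  gen <- metadata$generation %||% 4
  if (identical(gen, "inf")) gen <- Inf
  makeRilGenotypes(callChr,
                   populationId = metadata$populationId %||% basename(path),
                   generation = as.numeric(gen),
                   assignedChromosome = chr,
                   parents = unlist(metadata$parents) %||% c("Par", "Other"),
                   ancestralGroup = metadata$ancestralGroup %||% NA_character_,
                   symbols = symbols)
}

#' Write / read a genetic map as TSV
#'
#' Tab-separated with columns `marker`, `lg`, `chromosome`, `position`
#' and a provenance comment header.  `readGeneticMap()` validates that
#' positions are non-decreasing within each linkage group.
#'
#' @param map a [GeneticMap-class] or its `mapTable()` data.frame.
#' @param path file path.
#' @export
writeGeneticMap <- function(map, path) {
  tb <- if (methods::is(map, "GeneticMap")) mapTable(map) else map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nammap genetic map v%s",
                     as.character(utils::packageVersion("nammap"))), con)
  utils::write.table(tb, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneticMap
#' @param populationId id recorded in the returned object.
#' @return `readGeneticMap()` returns a [GeneticMap-class].
#' @export
readGeneticMap <- function(path, populationId = basename(path)) {
  raw <- readLines(path)
  keep <- !startsWith(raw, "#")
  tb <- utils::read.table(text = raw[keep], sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "character", "character"),
                          stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.numeric(tb$position))
  if (anyNA(pos) && nrow(tb))
    stop(sprintf("non-numeric cM position at line %d of %s",
                 which(keep)[which(is.na(pos))[1] + 1L], path))
  tb$position <- pos
  for (g in unique(tb$lg))
    if (is.unsorted(tb$position[tb$lg == g]))
      stop(sprintf("positions decrease within lg '%s' in %s", g, path))
  tb$chromosome[tb$chromosome %in% c("", "NA")] <- NA_character_
  methods::new("GeneticMap", populationId = populationId, table = tb,
               sarf = numeric(), stats = list())
}

#' Validate a genotype matrix: missing-data filter and no-het flags
#'
#' Drops markers whose missing fraction strictly exceeds `maxMissing`
#' (default 0.10; ties are kept) and flags markers without a single
#' heterozygote call in non-inbred (F4-F6) populations, where the likely
#' cause is mis-scored heterozygotes; flagged markers stay in the map but
#' are excluded from segregation-distortion and translocation analyses
#' downstream.  Validation is idempotent.
#'
#' @param x a [RilGenotypes-class].
#' @param maxMissing missing-fraction threshold.
#' @return list: `kept` ([RilGenotypes-class] with a `noHet` column in
#'   `rowData`), `dropped` (data.frame marker/missingFrac), `noHet`
#'   (character vector of flagged markers).
#' @export
validateGenotypes <- function(x, maxMissing = 0.10) {
  calls <- genotypeCalls(x)
  missFrac <- rowMeans(is.na(calls))
  drop <- missFrac > maxMissing
  kept <- x[!drop, ]
  ck <- genotypeCalls(kept)
  noHet <- if (is.finite(generation(x)))
    rowSums(ck == 2L, na.rm = TRUE) == 0L
  else rep(FALSE, nrow(ck))
  SummarizedExperiment::rowData(kept)$noHet <- noHet
  list(kept = kept,
       dropped = data.frame(marker = rownames(calls)[drop],
                            missingFrac = missFrac[drop],
                            row.names = NULL),
       noHet = rownames(ck)[noHet])
}
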