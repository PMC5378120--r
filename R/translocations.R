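# Translocation detection: chromosome-assignment conflicts within
# linkage groups ("mapped") and inter-chromosome linkage LOD signals in
# the pairwise recombination-fraction matrix ("estrf"); merging,
# type classification, and ancestral-group enrichment.

#' Mapped translocation calls from assignment conflicts
#'
#' Within each linkage group, markers whose a-priori chromosome
#' assignment disagrees with the group's majority label generate one
#' call per (population, minority chromosome, majority chromosome);
#' `minMinority` minority markers are required per call (default 1).
#' The reciprocal flag is set when the mirror-image call exists (a group
#' labelled to the minority chromosome containing markers assigned to
#' the majority chromosome).
#'
#' @param map a [GeneticMap-class].
#' @param assignments named character vector, marker -> a-priori
#'   chromosome (NA allowed).
#' @param minMinority minimum minority-marker support (default 1).
#' @return data.frame of calls: `population`, `method`, `chrA`, `chrB`
#'   (sorted pair), `minorityChromosome`, `lgChromosome`, `nMarkers`,
#'   `markers`, `reciprocal`.
#' @export
mappedTranslocations <- function(map, assignments, minMinority = 1) {
  tb <- mapTable(map)
  rows <- list()
  for (g in unique(tb$lg)) {
    sub <- tb[tb$lg == g, , drop = FALSE]
    maj <- sub$chromosome[1]
    if (is.na(maj)) next
    asg <- assignments[sub$marker]
    minority <- !is.na(asg) & asg != maj
    if (!any(minority)) next
    for (ch in unique(asg[minority])) {
      mk <- sub$marker[minority & asg == ch]
      if (length(mk) < minMinority) next
      pair <- sort(c(ch, maj))
      rows[[length(rows) + 1L]] <- data.frame(
        population = map@populationId, method = "mapped",
        chrA = pair[1], chrB = pair[2],
        minorityChromosome = ch, lgChromosome = maj,
        nMarkers = length(mk), markers = paste(mk, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(population = character(), method = character(),
                      chrA = character(), chrB = character(),
                      minorityChromosome = character(),
                      lgChromosome = character(), nMarkers = integer(),
                      markers = character(), reciprocal = logical()))
  out <- do.call(rbind, rows)
  mirror <- paste(out$minorityChromosome, out$lgChromosome)
  out$reciprocal <- paste(out$lgChromosome, out$minorityChromosome) %in% mirror
  out
}

#' estRF translocation calls from inter-chromosome linkage LOD
#'
#' Every marker pair whose two markers sit on different chromosomes but
#' show a two-point LOD strictly greater than `lodThreshold` (default
#' 7.0; set `lodThreshold = 10` for the conservative screening stage)
#' contributes to one call per (population, chromosome pair), aggregated
#' with the maximum LOD and the supporting pairs.  Markers without a
#' heterozygote call are excluded as linkage-unreliable.
#'
#' @param rfm an [RfMatrix-class].
#' @param chromosomes named character vector, marker -> chromosome (the
#'   linkage-group label or a-priori assignment; NA markers are skipped).
#' @param lodThreshold strict LOD threshold (default 7.0).
#' @param noHet markers to exclude.
#' @param population id recorded in the calls.
#' @return data.frame of calls: `population`, `method`, `chrA`, `chrB`,
#'   `maxLod`, `nPairs`, `markers`.
#' @export
estRfTranslocations <- function(rfm, chromosomes, lodThreshold = 7,
                                noHet = character(0),
                                population = NA_character_) {
  lod <- lodValues(rfm)
  mk <- rownames(lod)
  keep <- !(mk %in% noHet) & !is.na(chromosomes[mk])
  lod <- lod[keep, keep, drop = FALSE]
  mk <- mk[keep]
  chr <- chromosomes[mk]
  ut <- which(upper.tri(lod), arr.ind = TRUE)
  hit <- ut[!is.na(lod[ut]) & lod[ut] > lodThreshold &
              chr[ut[, 1]] != chr[ut[, 2]], , drop = FALSE]
  if (!nrow(hit))
    return(data.frame(population = character(), method = character(),
                      chrA = character(), chrB = character(),
                      maxLod = numeric(), nPairs = integer(),
                      markers = character()))
  pa <- pmin(chr[hit[, 1]], chr[hit[, 2]])
  pb <- pmax(chr[hit[, 1]], chr[hit[, 2]])
  key <- paste(pa, pb)
  out <- do.call(rbind, lapply(split(seq_len(nrow(hit)), key), function(i) {
    data.frame(population = population, method = "estrf",
               chrA = pa[i[1]], chrB = pb[i[1]],
               maxLod = max(lod[hit[i, , drop = FALSE]]),
               nPairs = length(i),
               markers = paste(sort(unique(c(mk[hit[i, 1]], mk[hit[i, 2]]))),
                               collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Merge and classify translocation calls across methods
#'
#' Union of mapped and estRF calls keyed by (population, chromosome
#' pair): a pair found by both methods in one population is counted
#' once.  Produces the per-population translocation counts and the type
#' table with canonical labels `T<chrA>:<chrB>` (chromosomes sorted) and
#' carrier populations.
#'
#' @param ... data.frames of calls from [mappedTranslocations()] and/or
#'   [estRfTranslocations()].
#' @return list: `calls` (union, with `methods` column), `perPopulation`
#'   (data.frame `population`, `nTranslocations`), `types` (data.frame
#'   `type`, `chrA`, `chrB`, `nCarriers`, `carriers`).
#' @export
mergeTranslocationCalls <- function(...) {
  all <- do.call(rbind, lapply(list(...), function(d)
    d[, c("population", "method", "chrA", "chrB"), drop = FALSE]))
  if (is.null(all) || !nrow(all)) {
    empty <- data.frame()
    return(list(calls = data.frame(population = character(),
                                   chrA = character(), chrB = character(),
                                   methods = character()),
                perPopulation = data.frame(population = character(),
                                           nTranslocations = integer()),
                types = data.frame(type = character(), chrA = character(),
                                   chrB = character(), nCarriers = integer(),
                                   carriers = character())))
  }
  key <- paste(all$population, all$chrA, all$chrB)
  calls <- do.call(rbind, lapply(split(all, key), function(d)
    data.frame(population = d$population[1], chrA = d$chrA[1],
               chrB = d$chrB[1],
               methods = paste(sort(unique(d$method)), collapse = "+"),
               stringsAsFactors = FALSE)))
  rownames(calls) <- NULL
  perPop <- as.data.frame(table(population = calls$population),
                          stringsAsFactors = FALSE)
  names(perPop)[2] <- "nTranslocations"
  tkey <- paste(calls$chrA, calls$chrB)
  types <- do.call(rbind, lapply(split(calls, tkey), function(d)
    data.frame(type = sprintf("T%s:%s", d$chrA[1], d$chrB[1]),
               chrA = d$chrA[1], chrB = d$chrB[1],
               nCarriers = length(unique(d$population)),
               carriers = paste(sort(unique(d$population)), collapse = ","),
               stringsAsFactors = FALSE)))
  rownames(types) <- NULL
  types <- types[order(-types$nCarriers, types$type), , drop = FALSE]
  rownames(types) <- NULL
  list(calls = calls, perPopulation = perPop, types = types)
}

#' Ancestral-group enrichment of a translocation type
#'
#' Tests whether the carriers of one translocation type are distributed
#' across the panel's ancestral groups differently from non-carriers:
#' chi-square on the 2 x G carrier/non-carrier contingency table, with a
#' Monte-Carlo p-value (resampling the table margins, default 1e4 draws)
#' whenever any expected cell falls below 5.  Both p-values are
#' reported, together with observed vs expected carriers per group.
#'
#' @param carriers character vector of carrier population ids.
#' @param groups named character vector, population id -> ancestral group.
#' @param alpha significance level (default 0.05).
#' @param B Monte-Carlo draws (default 1e4); the RNG is the caller's.
#' @return list: `table`, `chisq`, `pAsymptotic`, `pMonteCarlo`, `p`,
#'   `significant`, `perGroup` (observed vs expected carriers).
#' @export
ancestralEnrichment <- function(carriers, groups, alpha = 0.05, B = 1e4) {
  pops <- names(groups)
  if (length(unique(groups)) < 2) {
    warning("only one ancestral group represented; enrichment undefined")
    return(list(table = NULL, chisq = NA, pAsymptotic = NA,
                pMonteCarlo = NA, p = NA, significant = NA,
                perGroup = NULL))
  }
  carrier <- factor(pops %in% carriers, levels = c(FALSE, TRUE),
                    labels = c("non-carrier", "carrier"))
  tab <- table(carrier, group = groups)
  suppressWarnings(asy <- stats::chisq.test(tab, correct = FALSE))
  small <- any(asy$expected < 5)
  pMC <- NA_real_
  if (small) {
    mc <- stats::chisq.test(tab, simulate.p.value = TRUE, B = as.integer(B))
    pMC <- mc$p.value
  }
  p <- if (small) pMC else asy$p.value
  perGroup <- data.frame(group = colnames(tab),
                         observed = as.vector(tab["carrier", ]),
                         expected = as.vector(asy$expected["carrier", ]))
  list(table = tab, chisq = unname(asy$statistic),
       pAsymptotic = asy$p.value, pMonteCarlo = pMC, p = p,
       significant = !is.na(p) && p <= alpha, perGroup = perGroup)
}
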