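# Per-line crossover counts from obligate genotype transitions, and QTL
# mapping of the crossover trait by Haley-Knott regression on imputed
# allele dosages.

#' Count obligate crossovers in one line
#'
#' Scans consecutive non-missing genotypes per linkage group in map
#' order and sums obligate crossovers: an AA-AB or AB-BB transition
#' counts 1, AA-BB counts 2 (intercross convention); missing calls are
#' skipped.  Single-marker groups contribute 0.  With integer codes
#' 1/2/3 the obligate count of a transition is `|g1 - g2|`.
#'
#' @param geno named integer genotype vector (marker -> 1/2/3/NA).
#' @param mapTable data.frame (`marker`, `lg`, `position`) in map order.
#' @return integer crossover count.
#' @export
countCrossovers <- function(geno, mapTable) {
  total <- 0L
  for (g in unique(mapTable$lg)) {
    v <- geno[mapTable$marker[mapTable$lg == g]]
    v <- v[!is.na(v)]
    if (length(v) > 1) total <- total + sum(abs(diff(v)))
  }
  as.integer(total)
}

#' Per-line crossover counts as a quantitative trait
#'
#' Applies [countCrossovers()] to every individual, using imputed hard
#' calls when provided (recommended: raw mis-scored calls inflate
#' obligate counts).
#'
#' @param x a [RilGenotypes-class].
#' @param map a [GeneticMap-class].
#' @param imputed optional [imputeGenotypes()] result.
#' @return list: `populationId`, `counts` (named integer), `mean`, `sd`.
#' @export
crossoverTrait <- function(x, map, imputed = NULL) {
  if (ncol(x) == 0) stop("empty population")
  calls <- if (is.null(imputed)) genotypeCalls(x) else imputed$calls
  tb <- mapTable(map)
  tb <- tb[tb$marker %in% rownames(calls), , drop = FALSE]
  counts <- vapply(seq_len(ncol(calls)), function(i)
    countCrossovers(calls[, i], tb), integer(1))
  names(counts) <- colnames(calls)
  list(populationId = populationId(x), counts = counts,
       mean = mean(counts), sd = stats::sd(counts))
}

.dosageMatrix <- function(imputed) {
  # expected count of the reference-parent allele, markers x individuals
  2 * imputed$posterior[, , 1] + imputed$posterior[, , 2]
}

#' Single-QTL genome scan for the crossover trait
#'
#' Haley-Knott regression of the trait on the expected reference-allele
#' dosage from the imputation posteriors, marker by marker:
#' `LOD = (n/2) log10(RSS0 / RSS1)`.  Putative QTL are local LOD maxima
#' at or above `lodThreshold` (default 2.0), peaks closer than
#' `mergeCm` on one linkage group merged to the higher one.  The
#' additive effect is the regression slope per reference allele, so a
#' positive effect means the reference (Par) allele increases the
#' crossover count; the confidence-interval marker set is the 1.5-LOD
#' drop around the peak.
#'
#' @param trait a [crossoverTrait()] result (or numeric vector).
#' @param imputed an [imputeGenotypes()] result.
#' @param lodThreshold putative-QTL threshold (default 2.0).
#' @param mergeCm peak-merging distance (default 10).
#' @return list: `curve` (data.frame `marker`, `lg`, `chromosome`,
#'   `position`, `lod`, `effect`), `qtl` (putative peaks with
#'   `ciMarkers`).
#' @export
qtlScan <- function(trait, imputed, lodThreshold = 2, mergeCm = 10) {
  y <- if (is.list(trait)) trait$counts else trait
  D <- .dosageMatrix(imputed)
  stopifnot(ncol(D) == length(y))
  tb <- imputed$map
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  lod <- eff <- numeric(nrow(tb))
  if (rss0 > 0) {
    for (m in seq_len(nrow(tb))) {
      d <- D[tb$marker[m], ]
      if (stats::var(d) < 1e-12) { lod[m] <- 0; eff[m] <- 0; next }
      fit <- stats::lm.fit(cbind(1, d), y)
      rss1 <- sum(fit$residuals^2)
      lod[m] <- n / 2 * log10(rss0 / rss1)
      eff[m] <- fit$coefficients[2]
    }
  }
  curve <- data.frame(marker = tb$marker, lg = tb$lg,
                      chromosome = tb$chromosome, position = tb$position,
                      lod = lod, effect = eff, stringsAsFactors = FALSE)
  qtl <- .findPeaks(curve, lodThreshold, mergeCm)
  list(curve = curve, qtl = qtl)
}

.findPeaks <- function(curve, lodThreshold, mergeCm) {
  rows <- list()
  for (g in unique(curve$lg)) {
    sub <- curve[curve$lg == g, , drop = FALSE]
    l <- sub$lod
    M <- length(l)
    isPeak <- vapply(seq_len(M), function(i)
      l[i] >= lodThreshold &&
        (i == 1 || l[i] >= l[i - 1]) && (i == M || l[i] >= l[i + 1]),
      logical(1))
    pk <- which(isPeak)
    if (!length(pk)) next
    pk <- pk[order(-l[pk])]
    kept <- integer(0)
    for (i in pk)
      if (!length(kept) || all(abs(sub$position[i] - sub$position[kept]) > mergeCm))
        kept <- c(kept, i)
    for (i in kept) {
      drop <- l >= l[i] - 1.5
      lo <- i; while (lo > 1 && drop[lo - 1]) lo <- lo - 1
      hi <- i; while (hi < M && drop[hi + 1]) hi <- hi + 1
      rows[[length(rows) + 1L]] <- data.frame(
        lg = g, chromosome = sub$chromosome[1],
        marker = sub$marker[i], position = sub$position[i],
        lod = l[i], effect = sub$effect[i],
        increasingAllele = if (sub$effect[i] >= 0) "Par" else "other",
        ciMarkers = paste(sub$marker[lo:hi], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(lg = character(), chromosome = character(),
                      marker = character(), position = numeric(),
                      lod = numeric(), effect = numeric(),
                      increasingAllele = character(),
                      ciMarkers = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multiple-QTL confirmation of putative peaks
#'
#' Joint linear model with all putative QTL dosages (peaks closer than
#' `mergeCm` merged beforehand, higher LOD kept); each QTL's drop-one
#' LOD is `(n/2) log10(RSS(without) / RSS(full))` and peaks at or above
#' the threshold are retained.  The threshold is either the fixed
#' `lodThreshold` (default 2.0) or, with `nPermutations > 0`, the 95th
#' percentile of genome-wide maximum LODs over permutations of the
#' trait (seeded by the caller).
#'
#' @param scan a [qtlScan()] result.
#' @param trait the trait used for the scan.
#' @param imputed the [imputeGenotypes()] result used for the scan.
#' @param lodThreshold fixed retention threshold (default 2.0).
#' @param nPermutations permutation count (0 = use fixed threshold).
#' @param level permutation quantile (default 0.95).
#' @return list: `qtl` (retained records with `dropLod`), `threshold`,
#'   `permutationLods`.
#' @export
multipleQtlModel <- function(scan, trait, imputed, lodThreshold = 2,
                             nPermutations = 0, level = 0.95) {
  y <- if (is.list(trait)) trait$counts else trait
  qtl <- scan$qtl
  permLods <- NULL
  thr <- lodThreshold
  if (nPermutations > 0) {
    permLods <- vapply(seq_len(nPermutations), function(b) {
      yp <- sample(y)
      max(qtlScan(yp, imputed, lodThreshold = Inf)$curve$lod)
    }, numeric(1))
    thr <- stats::quantile(permLods, level, names = FALSE)
  }
  if (!nrow(qtl))
    return(list(qtl = qtl, threshold = thr, permutationLods = permLods))
  D <- .dosageMatrix(imputed)
  X <- t(D[qtl$marker, , drop = FALSE])
  # drop collinear dosages (merged peaks on tight maps)
  keep <- rep(TRUE, ncol(X))
  if (ncol(X) > 1) {
    qr <- qr(cbind(1, X))
    if (qr$rank < ncol(X) + 1) {
      used <- sort(qr$pivot[seq_len(qr$rank)])
      keep <- (seq_len(ncol(X)) + 1L) %in% used
    }
  }
  qtl <- qtl[keep, , drop = FALSE]
  X <- X[, keep, drop = FALSE]
  n <- length(y)
  full <- stats::lm.fit(cbind(1, X), y)
  rssF <- sum(full$residuals^2)
  dropLod <- vapply(seq_len(ncol(X)), function(j) {
    red <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), y)
    n / 2 * log10(sum(red$residuals^2) / rssF)
  }, numeric(1))
  qtl$dropLod <- dropLod
  qtl <- qtl[dropLod >= thr, , drop = FALSE]
  rownames(qtl) <- NULL
  list(qtl = qtl, threshold = thr, permutationLods = permLods)
}

#' Common crossover QTL across populations on the consensus map
#'
#' For each consensus marker, counts the populations whose QTL
#' confidence-interval marker set contains it; maximal runs of
#' consecutive consensus markers with at least `minPops` populations
#' form common-QTL regions.
#'
#' @param qtlRecords named list (by population) of QTL data.frames with
#'   a `ciMarkers` column (comma-separated).
#' @param consensus a [ConsensusMap-class].
#' @param minPops minimum populations per common QTL (default 4).
#' @return list: `byMarker` (counts per consensus marker), `regions`
#'   (data.frame `chromosome`, `startCm`, `endCm`, `markers`,
#'   `nPopulations`).
#' @export
projectCommonQtl <- function(qtlRecords, consensus, minPops = 4) {
  ct <- mapTable(consensus)
  count <- integer(nrow(ct))
  for (pop in names(qtlRecords)) {
    q <- qtlRecords[[pop]]
    if (is.null(q) || !nrow(q)) next
    ci <- unique(unlist(strsplit(q$ciMarkers, ",", fixed = TRUE)))
    count <- count + (ct$marker %in% ci)
  }
  byMarker <- data.frame(marker = ct$marker, chromosome = ct$chromosome,
                         position = ct$position, nPopulations = count,
                         stringsAsFactors = FALSE)
  regions <- list()
  for (ch in unique(ct$chromosome)) {
    sub <- byMarker[byMarker$chromosome == ch, , drop = FALSE]
    run <- rle(sub$nPopulations >= minPops)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    for (i in which(run$values)) {
      idx <- starts[i]:ends[i]
      regions[[length(regions) + 1L]] <- data.frame(
        chromosome = ch, startCm = min(sub$position[idx]),
        endCm = max(sub$position[idx]),
        markers = paste(sub$marker[idx], collapse = ","),
        nPopulations = max(sub$nPopulations[idx]),
        stringsAsFactors = FALSE)
    }
  }
  list(byMarker = byMarker,
       regions = if (length(regions)) do.call(rbind, regions) else
         data.frame(chromosome = character(), startCm = numeric(),
                    endCm = numeric(), markers = character(),
                    nPopulations = integer()))
}
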