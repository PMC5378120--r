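# Diversity statistics between biparental linkage groups and the
# consensus: marker-distance ratios with Tukey-fence outliers, and
# Spearman order correlations with incongruence classification.

#' Mean marker distance over the common-marker span
#'
#' The span of the shared markers divided by the number of intervals:
#' `MD = (pos(last common) - pos(first common)) / (n_common - 1)`,
#' evaluated in the map's own coordinates.
#'
#' @param lg data.frame (`marker`, `position`).
#' @param commonMarkers marker names shared with the other map (>= 2).
#' @return mean marker distance in cM/interval.
#' @export
meanMarkerDistance <- function(lg, commonMarkers) {
  at <- match(commonMarkers, lg$marker)
  if (anyNA(at)) stop("common markers missing from linkage group")
  if (length(at) < 2) stop("need at least 2 common markers")
  p <- lg$position[at]
  (max(p) - min(p)) / (length(at) - 1)
}

#' Marker-distance ratio of a biparental LG against the consensus
#'
#' MDR = MD(biparental) / MD(consensus), both mean marker distances taken
#' over the same set of shared markers.  Zero-length biparental LGs are
#' excluded upstream; a zero consensus span with a positive biparental
#' span yields an infinite ratio flagged for exclusion from the fences.
#'
#' @param bipLg,consensusLg data.frames (`marker`, `position`).
#' @param population,chromosome identifiers carried into the record.
#' @return one-row data.frame: `population`, `chromosome`, `nCommon`,
#'   `mdBip`, `mdCons`, `mdr`, `infinite`.
#' @export
markerDistanceRatio <- function(bipLg, consensusLg,
                                population = NA_character_,
                                chromosome = NA_character_) {
  cm <- intersect(bipLg$marker, consensusLg$marker)
  if (length(cm) < 2)
    return(data.frame(population = population, chromosome = chromosome,
                      nCommon = length(cm), mdBip = NA_real_,
                      mdCons = NA_real_, mdr = NA_real_, infinite = FALSE))
  mdB <- meanMarkerDistance(bipLg, cm)
  mdC <- meanMarkerDistance(consensusLg, cm)
  inf <- mdC == 0 && mdB > 0
  data.frame(population = population, chromosome = chromosome,
             nCommon = length(cm), mdBip = mdB, mdCons = mdC,
             mdr = if (inf) Inf else if (mdC == 0) NA_real_ else mdB / mdC,
             infinite = inf)
}

#' Flag MDR outliers with Tukey fences, per chromosome
#'
#' Within each chromosome group, ratios beyond 1.5 interquartile ranges
#' from the bordering quartiles (`Q1 - 1.5 IQR`, `Q3 + 1.5 IQR`;
#' quartiles by linear interpolation, type 7) are flagged `low` / `high`;
#' a `high` flag additionally counts as an expanded linkage group when it
#' rests on at least `minExpanded` shared markers.  Groups with fewer
#' than 4 finite records get no flags (with a warning); infinite or
#' missing ratios never enter the fences.
#'
#' @param records data.frame from rbind-ed [markerDistanceRatio()] rows.
#' @param minExpanded minimum `nCommon` for the expanded call (default 6).
#' @return `records` with `outlier` ("low"/"none"/"high") and `expanded`.
#' @export
flagMdrOutliers <- function(records, minExpanded = 6) {
  records$outlier <- "none"
  records$expanded <- FALSE
  for (ch in unique(records$chromosome)) {
    sel <- which(records$chromosome == ch & is.finite(records$mdr))
    if (length(sel) < 4) {
      if (length(sel)) warning("chromosome ", ch,
                               ": too few records for fences")
      next
    }
    q <- stats::quantile(records$mdr[sel], c(0.25, 0.75), type = 7,
                         names = FALSE)
    iqr <- q[2] - q[1]
    hi <- records$mdr[sel] > q[2] + 1.5 * iqr
    lo <- records$mdr[sel] < q[1] - 1.5 * iqr
    records$outlier[sel[hi]] <- "high"
    records$outlier[sel[lo]] <- "low"
    records$expanded[sel] <- hi & records$nCommon[sel] >= minExpanded
  }
  records
}

#' Marker-order correlation and incongruence class
#'
#' Spearman rank correlation of shared-marker positions between a
#' biparental linkage group and the consensus (average ranks on ties).
#' Classification on |rho|, orientation applied first, so a perfectly
#' reversed group is a flip rather than a rearrangement:
#' `|rho| <= 0.6` incongruent; `0.6 < |rho| <= 0.7` near_incongruent;
#' otherwise congruent.  Fewer than `minCommon` shared markers (default
#' 7) is classed `insufficient`.
#'
#' @param bipLg,consensusLg data.frames (`marker`, `position`).
#' @param minCommon minimum shared markers for a reliable comparison.
#' @param population,chromosome identifiers carried into the record.
#' @return one-row data.frame: `population`, `chromosome`, `nCommon`,
#'   `rho`, `class`.
#' @export
orderCorrelation <- function(bipLg, consensusLg, minCommon = 7,
                             population = NA_character_,
                             chromosome = NA_character_) {
  cm <- intersect(bipLg$marker, consensusLg$marker)
  n <- length(cm)
  rho <- NA_real_
  if (n >= 3) {
    p1 <- bipLg$position[match(cm, bipLg$marker)]
    p2 <- consensusLg$position[match(cm, consensusLg$marker)]
    rho <- suppressWarnings(stats::cor(p1, p2, method = "spearman"))
  }
  cls <- if (n < minCommon || is.na(rho)) "insufficient"
         else if (abs(rho) <= 0.6) "incongruent"
         else if (abs(rho) <= 0.7) "near_incongruent"
         else "congruent"
  data.frame(population = population, chromosome = chromosome,
             nCommon = n, rho = rho, class = cls,
             stringsAsFactors = FALSE)
}

#' Compare all linkage groups of a panel against the consensus
#'
#' Convenience wrapper producing the MDR table (with fences applied) and
#' the order-comparison table for every (population, linkage group) with
#' a chromosome label.  Linkage groups of length 0 cM are excluded from
#' the MDR analysis.
#'
#' @param maps list of [GeneticMap-class] objects.
#' @param consensus a [ConsensusMap-class].
#' @param minCommon,minExpanded see [orderCorrelation()] and
#'   [flagMdrOutliers()].
#' @return list: `mdr` data.frame, `order` data.frame.
#' @export
compareMapsToConsensus <- function(maps, consensus, minCommon = 7,
                                   minExpanded = 6) {
  ct <- mapTable(consensus)
  mdrRows <- list(); ordRows <- list()
  for (mp in maps) {
    tb <- mapTable(mp)
    for (g in unique(tb$lg)) {
      sub <- tb[tb$lg == g, , drop = FALSE]
      ch <- sub$chromosome[1]
      if (is.na(ch)) next
      cons <- ct[ct$chromosome == ch, c("marker", "position")]
      if (nrow(cons) < 2) next
      ordRows[[length(ordRows) + 1L]] <-
        orderCorrelation(sub, cons, minCommon = minCommon,
                         population = mp@populationId, chromosome = ch)
      if (max(sub$position) > 0)       # 0 cM LGs excluded from MDR
        mdrRows[[length(mdrRows) + 1L]] <-
          markerDistanceRatio(sub, cons, population = mp@populationId,
                              chromosome = ch)
    }
  }
  mdr <- if (length(mdrRows)) do.call(rbind, mdrRows) else
    data.frame(population = character(), chromosome = character(),
               nCommon = integer(), mdBip = numeric(), mdCons = numeric(),
               mdr = numeric(), infinite = logical())
  if (nrow(mdr)) mdr <- flagMdrOutliers(mdr, minExpanded = minExpanded)
  ord <- if (length(ordRows)) do.call(rbind, ordRows) else
    data.frame(population = character(), chromosome = character(),
               nCommon = integer(), rho = numeric(), class = character())
  list(mdr = mdr, order = ord)
}
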