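#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

GENO_LEVELS <- c("AA", "AB", "BB")

#' Genotypes of one selfed-RIL population
#'
#' A markers x individuals genotype container for a single biparental
#' population of selfed recombinant inbred lines, stored as a
#' [SummarizedExperiment::SummarizedExperiment] with one assay `"calls"`
#' holding integer codes (1 = AA, the reference-parent homozygote; 2 = AB;
#' 3 = BB; `NA` = missing).  Marker metadata (a-priori chromosome
#' assignment, assay type, no-heterozygote flag) live in `rowData`;
#' population descriptors (id, selfing generation, parents, ancestral
#' group of the non-reference parent) in `metadata`.
#'
#' The selfing generation `k` is 4, 5 or 6 for F4/F5/F6 single-seed-descent
#' material, or `Inf` for a fully inbred (riself-type) population.
#'
#' @slot truth optional list with simulation truth (true genotypes before
#'   observation noise, realised crossover counts, planted variants); empty
#'   for real data.
#'
#' @seealso [makeRilGenotypes()], [readGenotypes()], [simulateSsdPopulation()]
#' @export
setClass("RilGenotypes",
  contains = "SummarizedExperiment",
  slots = c(truth = "list"),
  prototype = prototype(truth = list())
)

setValidity("RilGenotypes", function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  else {
    cl <- SummarizedExperiment::assay(object, "calls")
    bad <- cl[!is.na(cl)]
    if (length(bad) && (!is.numeric(cl) || any(!bad %in% 1:3)))
      msg <- c(msg, "calls must be integer codes in {1,2,3} or NA")
  }
  md <- metadata(object)
  k <- md$generation
  if (is.null(k) || length(k) != 1L ||
      !(is.infinite(k) || (k == round(k) && k >= 2)))
    msg <- c(msg, "metadata$generation must be an integer >= 2 or Inf")
  if (ncol(object) < 2L)
    msg <- c(msg, "at least 2 individuals required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "marker names must be unique")
  if (length(msg)) msg else TRUE
})

#' Pairwise recombination-fraction estimates with linkage LOD
#'
#' Symmetric matrices of maximum-likelihood per-meiosis recombination
#' fractions and two-point linkage LOD scores for all marker pairs of one
#' population.  Diagonals are `NA` (rf) and 0 (LOD); pairs with no jointly
#' observed individuals are `NA`.
#'
#' @slot rf numeric matrix of estimated recombination fractions in `[0, 0.5]`.
#' @slot lod numeric matrix of two-point LOD scores (>= 0).
#' @slot generation selfing generation the estimates were computed under.
#' @export
setClass("RfMatrix",
  slots = c(rf = "matrix", lod = "matrix", generation = "numeric")
)

setValidity("RfMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@rf), dim(object@lod)))
    msg <- c(msg, "rf and lod must have identical dimensions")
  if (!isTRUE(all.equal(object@rf, t(object@rf))))
    msg <- c(msg, "rf must be symmetric")
  v <- object@rf[!is.na(object@rf)]
  if (length(v) && (min(v) < 0 || max(v) > 0.5))
    msg <- c(msg, "rf values must lie in [0, 0.5]")
  l <- object@lod[!is.na(object@lod)]
  if (length(l) && min(l) < -1e-8)
    msg <- c(msg, "lod values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A per-population genetic linkage map
#'
#' Ordered markers grouped into linkage groups with Kosambi cM positions
#' (origin 0 per group).  Each group carries a chromosome label assigned by
#' majority vote of the member markers' a-priori assignments, and the SARF
#' (sum of adjacent recombination fractions) of its order.
#'
#' @slot populationId population identifier.
#' @slot table data.frame with columns `marker`, `lg`, `chromosome`,
#'   `position` (cM, non-decreasing within an lg, first = 0).
#' @slot sarf named numeric, SARF per linkage group.
#' @slot stats list of map-level summaries (total length, linked and
#'   cosegregating marker counts, dropped markers, no-het flags).
#' @export
setClass("GeneticMap",
  slots = c(populationId = "character", table = "data.frame",
            sarf = "numeric", stats = "list"),
  prototype = prototype(populationId = NA_character_,
                        table = data.frame(marker = character(),
                                           lg = character(),
                                           chromosome = character(),
                                           position = numeric()),
                        sarf = numeric(), stats = list())
)

setValidity("GeneticMap", function(object) {
  tb <- object@table
  need <- c("marker", "lg", "chromosome", "position")
  if (!all(need %in% names(tb)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(tb$marker))
    msg <- c(msg, "marker names must be unique")
  for (g in unique(tb$lg)) {
    p <- tb$position[tb$lg == g]
    if (length(p) && (is.unsorted(p) || abs(p[1]) > 1e-9))
      msg <- c(msg, sprintf("positions in lg '%s' must be non-decreasing from 0", g))
  }
  if (length(msg)) msg else TRUE
})

#' A per-chromosome consensus map merged across populations
#'
#' Consensus marker orders and positions per chromosome, produced by
#' order-constrained L1 linear programming over oriented component linkage
#' groups, together with merge diagnostics (the maximum map interval K
#' used, per-component RMSE, and any order constraints removed to break
#' conflicts).
#'
#' @slot table data.frame with columns `marker`, `chromosome`, `position`.
#' @slot K named numeric, interval parameter chosen per chromosome.
#' @slot diagnostics data.frame of per-(chromosome, component) RMSE.
#' @slot removed data.frame of order constraints removed as conflicting.
#' @export
setClass("ConsensusMap",
  slots = c(table = "data.frame", K = "numeric",
            diagnostics = "data.frame", removed = "data.frame"),
  prototype = prototype(
    table = data.frame(marker = character(), chromosome = character(),
                       position = numeric()),
    K = numeric(),
    diagnostics = data.frame(),
    removed = data.frame())
)

setValidity("ConsensusMap", function(object) {
  tb <- object@table
  if (!all(c("marker", "chromosome", "position") %in% names(tb)))
    return("table needs columns marker, chromosome, position")
  msg <- character()
  for (ch in unique(tb$chromosome)) {
    p <- tb$position[tb$chromosome == ch]
    if (length(p) && (is.unsorted(p) || min(p) < -1e-9))
      msg <- c(msg, sprintf("positions on %s must be non-decreasing from 0", ch))
  }
  if (length(msg)) msg else TRUE
})
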