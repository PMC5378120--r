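#' @rdname RilGenotypes-class
#' @param object,x a `RilGenotypes`
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname RilGenotypes-class
#' @export
setGeneric("populationId", function(x) standardGeneric("populationId"))

#' @rdname RilGenotypes-class
#' @export
setGeneric("generation", function(x) standardGeneric("generation"))

#' @rdname RilGenotypes-class
#' @export
setGeneric("parents", function(x) standardGeneric("parents"))

#' @rdname RilGenotypes-class
#' @export
setGeneric("ancestralGroup", function(x) standardGeneric("ancestralGroup"))

#' @rdname RilGenotypes-class
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname RilGenotypes-class
#' @export
setGeneric("simulationTruth", function(x) standardGeneric("simulationTruth"))

#' @rdname GeneticMap-class
#' @param x a `GeneticMap` or `ConsensusMap`
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))

#' @rdname GeneticMap-class
#' @export
setGeneric("mapLength", function(x) standardGeneric("mapLength"))

#' @rdname GeneticMap-class
#' @export
setGeneric("linkageGroups", function(x) standardGeneric("linkageGroups"))

#' @rdname RfMatrix-class
#' @param x an `RfMatrix`
#' @export
setGeneric("rfValues", function(x) standardGeneric("rfValues"))

#' @rdname RfMatrix-class
#' @export
setGeneric("lodValues", function(x) standardGeneric("lodValues"))

## -- methods -----------------------------------------------------------

#' @rdname RilGenotypes-class
#' @export
setMethod("genotypeCalls", "RilGenotypes", function(x)
  SummarizedExperiment::assay(x, "calls"))

#' @rdname RilGenotypes-class
#' @export
setMethod("populationId", "RilGenotypes", function(x)
  metadata(x)$populationId)

#' @rdname RilGenotypes-class
#' @export
setMethod("generation", "RilGenotypes", function(x)
  metadata(x)$generation)

#' @rdname RilGenotypes-class
#' @export
setMethod("parents", "RilGenotypes", function(x)
  metadata(x)$parents)

#' @rdname RilGenotypes-class
#' @export
setMethod("ancestralGroup", "RilGenotypes", function(x)
  metadata(x)$ancestralGroup)

#' @rdname RilGenotypes-class
#' @export
setMethod("markerInfo", "RilGenotypes", function(x) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  rd$name <- rownames(x)
  rd[, c("name", setdiff(names(rd), "name")), drop = FALSE]
})

#' @rdname RilGenotypes-class
#' @export
setMethod("simulationTruth", "RilGenotypes", function(x) x@truth)

#' @rdname GeneticMap-class
#' @export
setMethod("mapTable", "GeneticMap", function(x) x@table)

#' @rdname ConsensusMap-class
#' @export
setMethod("mapTable", "ConsensusMap", function(x) x@table)

#' @rdname GeneticMap-class
#' @export
setMethod("mapLength", "GeneticMap", function(x) {
  lg <- split(x@table$position, x@table$lg)
  sum(vapply(lg, function(p) if (length(p)) max(p) else 0, numeric(1)))
})

#' @rdname GeneticMap-class
#' @export
setMethod("linkageGroups", "GeneticMap", function(x)
  split(x@table, x@table$lg))

#' @rdname RfMatrix-class
#' @export
setMethod("rfValues", "RfMatrix", function(x) x@rf)

#' @rdname RfMatrix-class
#' @export
setMethod("lodValues", "RfMatrix", function(x) x@lod)

setMethod("show", "RilGenotypes", function(object) {
  cat(sprintf("RilGenotypes '%s': %d markers x %d individuals, F%s\n",
              populationId(object), nrow(object), ncol(object),
              ifelse(is.infinite(generation(object)), "inf",
                     generation(object))))
  p <- parents(object)
  if (!is.null(p))
    cat(sprintf("  cross: %s x %s\n", p[1], p[2]))
  cl <- genotypeCalls(object)
  cat(sprintf("  missing: %.1f%%; het: %.1f%%\n",
              100 * mean(is.na(cl)), 100 * mean(cl == 2L, na.rm = TRUE)))
})

setMethod("show", "GeneticMap", function(object) {
  tb <- object@table
  cat(sprintf("GeneticMap '%s': %d markers in %d linkage groups, %.1f cM\n",
              object@populationId, nrow(tb), length(unique(tb$lg)),
              mapLength(object)))
})

setMethod("show", "RfMatrix", function(object) {
  cat(sprintf("RfMatrix: %d markers (F%s), %d pairs with LOD >= 3\n",
              nrow(object@rf),
              ifelse(is.infinite(object@generation), "inf", object@generation),
              sum(object@lod[upper.tri(object@lod)] >= 3, na.rm = TRUE)))
})

setMethod("show", "ConsensusMap", function(object) {
  tb <- object@table
  cat(sprintf("ConsensusMap: %d markers on %d chromosomes\n",
              nrow(tb), length(unique(tb$chromosome))))
  if (length(object@K))
    cat("  K:", paste(sprintf("%s=%d", names(object@K), object@K),
                      collapse = " "), "\n")
})
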