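#' Accessors for simulation and co-expression containers
#'
#' `plantedTruth()` returns the generator-side ground-truth record of a
#' [PlacodeSim] (planted DE features, ceRNA triples, modules, cis pairs);
#' `txSequences()` and `mirSequences()` return the transcript and mature-miRNA
#' sequences; `txExons()` the per-transcript exon structure; `simParams()` the
#' generator parameter list.
#'
#' @param x a `PlacodeSim` object.
#' @return See the individual descriptions.
#' @name PlacodeSim-accessors
#' @aliases plantedTruth txSequences mirSequences txExons generatorParams
#' @examples
#' sim <- simulatePlacodeData(simParams(nMrna = 60, nLnc = 12, nMir = 6,
#'                                      nTriples = 2, moduleSizes = c(8, 8),
#'                                      seed = 1))
#' names(plantedTruth(sim))
NULL

#' @rdname PlacodeSim-accessors
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))

#' @rdname PlacodeSim-accessors
#' @export
setGeneric("txSequences", function(x) standardGeneric("txSequences"))

#' @rdname PlacodeSim-accessors
#' @export
setGeneric("mirSequences", function(x) standardGeneric("mirSequences"))

#' @rdname PlacodeSim-accessors
#' @export
setGeneric("txExons", function(x) standardGeneric("txExons"))

#' @rdname PlacodeSim-accessors
#' @export
setGeneric("generatorParams", function(x) standardGeneric("generatorParams"))

#' Accessors for CoexprResult objects
#'
#' `softPower()` returns the chosen soft-thresholding power; `scaleFreeFit()`
#' the per-power scale-free fit table; `moduleLabels()` the per-gene module
#' labels (0 = unassigned/grey); `eigengenes()` the module eigengene matrix
#' (modules x samples, unit-norm rows); `traitAssociation()` the module-trait
#' correlation and p-value matrices; `hubSets()` the per-module hub gene sets.
#'
#' @param x a `CoexprResult` object.
#' @return See the individual descriptions.
#' @name CoexprResult-accessors
#' @aliases softPower scaleFreeFit moduleLabels eigengenes traitAssociation hubSets
NULL

#' @rdname CoexprResult-accessors
#' @export
setGeneric("softPower", function(x) standardGeneric("softPower"))

#' @rdname CoexprResult-accessors
#' @export
setGeneric("scaleFreeFit", function(x) standardGeneric("scaleFreeFit"))

#' @rdname CoexprResult-accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname CoexprResult-accessors
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))

#' @rdname CoexprResult-accessors
#' @export
setGeneric("traitAssociation", function(x) standardGeneric("traitAssociation"))

#' @rdname CoexprResult-accessors
#' @export
setGeneric("hubSets", function(x) standardGeneric("hubSets"))
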