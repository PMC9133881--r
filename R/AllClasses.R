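#' @include AllGenerics.R
NULL

#' PlacodeSim: a simulated multi-omic placode experiment
#'
#' Container for one synthetic experiment: a count matrix over mRNAs, lncRNA
#' candidates and miRNAs (rows) and samples of a condition x tissue x stage x
#' replicate design (columns), with transcript-level genomic ranges as
#' `rowRanges`, per-transcript exon structure, transcript and miRNA sequences,
#' the generator parameters, and the planted ground truth used for recovery
#' scoring.
#'
#' Extends [SummarizedExperiment::RangedSummarizedExperiment]; the usual
#' `assay()`, `colData()`, `rowRanges()` accessors apply. Row metadata carries
#' `biotype` (`mRNA`, `lncRNA_candidate`, `miRNA`), `tx_length` and `n_exons`.
#'
#' @slot exons a [GenomicRanges::GRangesList], one element per transcript.
#' @slot txSequences a [Biostrings::DNAStringSet] of transcript sequences.
#' @slot mirSequences a [Biostrings::DNAStringSet] of mature miRNA sequences
#'   (DNA alphabet; U written as T).
#' @slot truth list; the planted ground truth (see [simulatePlacodeData()]).
#' @slot params list; the generator parameters (see [simParams()]).
#'
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom GenomicRanges GRangesList
#' @importClassesFrom Biostrings DNAStringSet
#' @export
setClass("PlacodeSim",
  contains = "RangedSummarizedExperiment",
  slots = c(
    exons = "GRangesList",
    txSequences = "DNAStringSet",
    mirSequences = "DNAStringSet",
    truth = "list",
    params = "list"
  )
)

setValidity("PlacodeSim", function(object) {
  msg <- NULL
  cd <- SummarizedExperiment::colData(object)
  need <- c("condition", "tissue", "stage", "replicate")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"biotype" %in% colnames(rd))
    msg <- c(msg, "rowData must contain 'biotype'")
  if (is.null(msg)) TRUE else msg
})

#' @rdname PlacodeSim-accessors
#' @export
setMethod("plantedTruth", "PlacodeSim", function(x) x@truth)

#' @rdname PlacodeSim-accessors
#' @export
setMethod("txSequences", "PlacodeSim", function(x) x@txSequences)

#' @rdname PlacodeSim-accessors
#' @export
setMethod("mirSequences", "PlacodeSim", function(x) x@mirSequences)

#' @rdname PlacodeSim-accessors
#' @export
setMethod("txExons", "PlacodeSim", function(x) x@exons)

#' @rdname PlacodeSim-accessors
#' @export
setMethod("generatorParams", "PlacodeSim", function(x) x@params)

setMethod("show", "PlacodeSim", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("PlacodeSim with", nrow(object), "features x", ncol(object), "samples\n")
  cat("  biotypes:", paste(sprintf("%s (%d)", names(table(rd$biotype)),
                                   as.integer(table(rd$biotype))),
                           collapse = ", "), "\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  design: ", length(unique(cd$condition)), "conditions x",
      length(unique(cd$tissue)), "tissues x",
      length(unique(cd$stage)), "stages x",
      max(cd$replicate), "replicates\n")
  tr <- object@truth
  cat("  planted truth:", nrow(tr$triples), "ceRNA triples,",
      length(tr$modules), "modules,",
      nrow(tr$cis_pairs), "cis pairs\n")
})

#' CoexprResult: weighted co-expression analysis result
#'
#' Holds the chosen soft-thresholding power and scale-free fit table, the
#' per-gene module labels (0 = unassigned/grey), module eigengenes (first
#' principal components, unit-norm, modules x samples), variance explained,
#' module-trait correlation/p matrices and per-module hub gene sets.
#'
#' @slot power integer; chosen soft-thresholding power.
#' @slot fitIndices data.frame with columns `power`, `r2`, `meanK`.
#' @slot labels named integer vector of module labels per gene.
#' @slot eigengenes numeric matrix, modules x samples.
#' @slot varExplained named numeric; proportion of module variance carried by
#'   each eigengene.
#' @slot traitCor,traitP numeric matrices, modules x traits.
#' @slot hubs named list of character vectors (per-module hub genes).
#' @slot params list of parameters used.
#' @export
setClass("CoexprResult",
  slots = c(
    power = "integer",
    fitIndices = "data.frame",
    labels = "integer",
    eigengenes = "matrix",
    varExplained = "numeric",
    traitCor = "matrix",
    traitP = "matrix",
    hubs = "list",
    params = "list"
  )
)

setValidity("CoexprResult", function(object) {
  msg <- NULL
  if (length(object@power) != 1L || object@power < 1L)
    msg <- c(msg, "power must be a single integer >= 1")
  if (nrow(object@eigengenes) > 0) {
    nrm <- sqrt(rowSums(object@eigengenes^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "eigengenes must have unit norm")
  }
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by gene")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CoexprResult", function(object) {
  nmod <- sum(unique(object@labels) != 0)
  cat("CoexprResult: power =", object@power, "|", nmod, "modules |",
      sum(object@labels == 0), "unassigned genes\n")
  if (nrow(object@traitP) > 0) {
    sig <- which(object@traitP < 0.05, arr.ind = TRUE)
    cat("  module-trait cells with p < 0.05:", nrow(sig), "\n")
  }
})

#' @rdname CoexprResult-accessors
#' @export
setMethod("softPower", "CoexprResult", function(x) x@power)

#' @rdname CoexprResult-accessors
#' @export
setMethod("scaleFreeFit", "CoexprResult", function(x) x@fitIndices)

#' @rdname CoexprResult-accessors
#' @export
setMethod("moduleLabels", "CoexprResult", function(x) x@labels)

#' @rdname CoexprResult-accessors
#' @export
setMethod("eigengenes", "CoexprResult", function(x) x@eigengenes)

#' @rdname CoexprResult-accessors
#' @export
setMethod("traitAssociation", "CoexprResult",
          function(x) list(r = x@traitCor, p = x@traitP))

#' @rdname CoexprResult-accessors
#' @export
setMethod("hubSets", "CoexprResult", function(x) x@hubs)
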