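#' Tissue-specific DE sets
#'
#' Features differentially expressed in the focal tissue and not called DE
#' (in either direction) in any other tissue.
#'
#' @param deSets named list, one data.frame (`feature`, `direction`) per
#'   tissue, as from [deSet()].
#' @param focal focal tissue name; must be an element of `deSets`.
#' @return data.frame (`feature`, `direction`) of focal-specific DE features.
#' @export
tissueSpecificSets <- function(deSets, focal) {
  if (!length(deSets)) stop("deSets must not be empty")
  if (!focal %in% names(deSets)) stop("focal tissue not in deSets")
  others <- unlist(lapply(deSets[setdiff(names(deSets), focal)],
                          function(d) d$feature))
  d <- deSets[[focal]]
  d[!d$feature %in% others, , drop = FALSE]
}

#' Overlap of specific DE mRNAs with lncRNA and miRNA targets
#'
#' Genes that are focal-specific DE mRNAs and targets of the supplied DE
#' lncRNA edges and of the supplied DE miRNA edges, with per-gene provenance.
#'
#' @param specificDeMrna character vector of focal-specific DE mRNA ids.
#' @param lncEdges,mirEdges edge DataFrames (`regulator`, `target`); restrict
#'   them to DE regulators before calling.
#' @return A [S4Vectors::DataFrame] with `gene`, `lncRegulators`,
#'   `mirRegulators` (comma-separated provenance).
#' @export
overlapTargets <- function(specificDeMrna, lncEdges, mirEdges) {
  genes <- intersect(specificDeMrna,
                     intersect(unique(lncEdges$target),
                               unique(mirEdges$target)))
  prov <- function(edges, g)
    vapply(g, function(x) paste(sort(unique(
      edges$regulator[edges$target == x])), collapse = ","), "",
      USE.NAMES = FALSE)
  S4Vectors::DataFrame(gene = genes,
                       lncRegulators = prov(lncEdges, genes),
                       mirRegulators = prov(mirEdges, genes))
}

.trendModels <- list(
  model1 = c(lncRNA = "down", miRNA = "up", mRNA = "down"),
  model2 = c(lncRNA = "up", miRNA = "down", mRNA = "up"))

#' Assemble ceRNA triples under the two trend models
#'
#' Emits a triple (lncRNA, miRNA, mRNA) when a seed edge links the miRNA to
#' the lncRNA, a seed edge links the miRNA to the mRNA, and the DE directions
#' of the three members match one of the two trend models:
#' model1 = lncRNA down | miRNA up | mRNA down;
#' model2 = lncRNA up | miRNA down | mRNA up.
#' With `requireLncMrnaEdge = TRUE`, a direct lncRNA-mRNA (cis or trans) edge
#' is additionally required. Output is deduplicated and sorted
#' lexicographically by (lncRNA, miRNA, mRNA).
#'
#' @param lncDE,mirDE,mrnaDE data.frames (`feature`, `direction`) of DE calls.
#' @param lncMirEdges seed edges with miRNA as `regulator` and lncRNA as
#'   `target`.
#' @param mirMrnaEdges seed edges with miRNA as `regulator` and mRNA as
#'   `target`.
#' @param lncMrnaEdges optional cis/trans edges (lncRNA `regulator`, mRNA
#'   `target`); used for provenance and, if required, as a filter.
#' @param requireLncMrnaEdge require a direct lncRNA-mRNA edge (strict mode).
#' @return A [S4Vectors::DataFrame] with `lncRNA`, `miRNA`, `mRNA`, `model`,
#'   `hasLncMrnaEdge`.
#' @export
assembleTriples <- function(lncDE, mirDE, mrnaDE, lncMirEdges, mirMrnaEdges,
                            lncMrnaEdges = NULL,
                            requireLncMrnaEdge = FALSE) {
  dirOf <- function(d) stats::setNames(d$direction, d$feature)
  dL <- dirOf(lncDE); dM <- dirOf(mirDE); dG <- dirOf(mrnaDE)
  lgKey <- if (!is.null(lncMrnaEdges) && nrow(lncMrnaEdges))
    unique(paste(lncMrnaEdges$regulator, lncMrnaEdges$target, sep = "\r"))
  else character(0)
  out <- list()
  for (m in intersect(unique(lncMirEdges$regulator), names(dM))) {
    Ls <- intersect(lncMirEdges$target[lncMirEdges$regulator == m], names(dL))
    Gs <- intersect(mirMrnaEdges$target[mirMrnaEdges$regulator == m],
                    names(dG))
    if (!length(Ls) || !length(Gs)) next
    for (L in Ls) for (G in Gs) {
      sig <- c(lncRNA = unname(dL[[L]]), miRNA = unname(dM[[m]]),
               mRNA = unname(dG[[G]]))
      model <- names(.trendModels)[vapply(.trendModels,
                                          function(md) all(md == sig), TRUE)]
      if (!length(model)) next
      hasEdge <- paste(L, G, sep = "\r") %in% lgKey
      if (requireLncMrnaEdge && !hasEdge) next
      out[[length(out) + 1L]] <- data.frame(
        lncRNA = L, miRNA = m, mRNA = G, model = model[1],
        hasLncMrnaEdge = hasEdge, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(S4Vectors::DataFrame(lncRNA = character(0), miRNA = character(0),
                                mRNA = character(0), model = character(0),
                                hasLncMrnaEdge = logical(0)))
  df <- unique(do.call(rbind, out))
  df <- df[order(df$lncRNA, df$miRNA, df$mRNA), , drop = FALSE]
  rownames(df) <- NULL
  S4Vectors::DataFrame(df)
}

#' Prioritize triples by stage-associated co-expression modules
#'
#' Retains triples whose mRNA is a hub gene of a module significantly
#' associated (p < `pThreshold`) with the focal stage.
#'
#' @param triples output of [assembleTriples()].
#' @param coexprResult a [CoexprResult].
#' @param focalStage column name in the module-trait matrices.
#' @param pThreshold significance threshold (default 0.05, strict).
#' @return The retained triples (same columns); empty with a warning when no
#'   module is significant at the focal stage.
#' @export
prioritizeTriples <- function(triples, coexprResult, focalStage,
                              pThreshold = 0.05) {
  tp <- traitAssociation(coexprResult)$p
  if (!focalStage %in% colnames(tp))
    stop("focal stage not among the traits: ", focalStage)
  sig <- rownames(tp)[!is.na(tp[, focalStage]) & tp[, focalStage] < pThreshold]
  if (!length(sig)) {
    warning("no module significantly associated with ", focalStage)
    return(triples[integer(0), , drop = FALSE])
  }
  hubs <- unique(unlist(hubSets(coexprResult)[sig]))
  triples[triples$mRNA %in% hubs, , drop = FALSE]
}
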