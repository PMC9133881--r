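#' Run the ceRNA nomination pipeline end to end
#'
#' Executes the integration workflow on a [PlacodeSim] (or any object with
#' the same structure): per-tissue differential expression at the focal
#' stage, tissue-specificity filtering, lncRNA candidate selection, cis /
#' trans / seed target assignment, trend-model triple assembly, stage-series
#' co-expression with module-trait association, and hub-based
#' prioritization. When the object carries planted truth, recovery scores
#' and a per-stage attrition table are added.
#'
#' @param sim a [PlacodeSim].
#' @param focalTissue,focalStage defaults taken from the simulation
#'   parameters.
#' @param fdrThreshold,lfcThreshold DE call thresholds (defaults 0.05, 1).
#' @param cisWindow cis window in bp (default 100,000).
#' @param rThreshold trans correlation threshold (default 0.95).
#' @param requireLncMrnaEdge require a direct lncRNA-mRNA cis/trans edge in
#'   each triple (default `TRUE`; the assembled networks then rest on
#'   co-location or co-expression support in addition to shared seed sites).
#' @param minSumCounts,powers,r2Target,minModuleSize,cutHeight,kmeThreshold
#'   co-expression parameters, see [runCoexpression()].
#' @param modulePThreshold module-trait significance threshold (default
#'   0.05).
#' @param outDir optional directory; when given, all intermediate tables are
#'   written as TSV plus a JSON report.
#' @param verbose log stage progress and counts to stderr.
#' @return A list with elements `deTables`, `deSets`, `specific`,
#'   `lncFilter`, `candidates`, `edges`, `overlap`, `triples`, `coexpr`,
#'   `finalTriples`, and (with truth) `recovery` and `attrition`.
#' @export
runPlacodePipeline <- function(sim,
                               focalTissue = NULL, focalStage = NULL,
                               fdrThreshold = 0.05, lfcThreshold = 1,
                               cisWindow = 100000, rThreshold = 0.95,
                               requireLncMrnaEdge = TRUE,
                               minSumCounts = 10, powers = 1:20,
                               r2Target = 0.8, minModuleSize = 30,
                               cutHeight = NULL, kmeThreshold = 0.8,
                               modulePThreshold = 0.05,
                               outDir = NULL, verbose = FALSE) {
  p <- generatorParams(sim)
  if (is.null(focalTissue)) focalTissue <- p$focalTissue
  if (is.null(focalStage)) focalStage <- p$focalStage
  counts <- SummarizedExperiment::assay(sim, "counts")
  cd <- as.data.frame(SummarizedExperiment::colData(sim))
  rd <- SummarizedExperiment::rowData(sim)
  gr <- SummarizedExperiment::rowRanges(sim)
  biotype <- stats::setNames(rd$biotype, rownames(sim))
  lengths <- stats::setNames(rd$tx_length, rownames(sim))
  mrnaIds <- names(biotype)[biotype == "mRNA"]
  lncIds <- names(biotype)[biotype == "lncRNA_candidate"]
  mirIds <- names(biotype)[biotype == "miRNA"]
  ref <- if (!is.null(p$conditions)) p$conditions[1] else
    sort(unique(cd$condition))[1]
  say <- function(...) if (verbose) message("[placodeCeRNA] ", ...)

  ## 1. differential expression per tissue at the focal stage
  tissues <- unique(cd$tissue)
  deTables <- list(); deSets <- list()
  for (t in tissues) {
    sel <- cd$tissue == t & cd$stage == focalStage
    deTables[[t]] <- runDE(counts[, sel, drop = FALSE], cd$condition[sel],
                           reference = ref, fdrThreshold = fdrThreshold,
                           lfcThreshold = lfcThreshold)
    deSets[[t]] <- deSet(deTables[[t]])
    say("DE ", t, "/", focalStage, ": ", nrow(deSets[[t]]), " features")
  }

  ## 2. tissue-specific sets (direction-agnostic exclusion)
  specific <- tissueSpecificSets(deSets, focalTissue)
  spec <- split(specific, biotype[specific$feature])
  specM <- spec[["mRNA"]]; if (is.null(specM)) specM <- specific[0, ]
  specL <- spec[["lncRNA_candidate"]]; if (is.null(specL)) specL <- specific[0, ]
  specR <- spec[["miRNA"]]; if (is.null(specR)) specR <- specific[0, ]
  say("focal-specific DE: ", nrow(specM), " mRNA, ", nrow(specL),
      " lncRNA, ", nrow(specR), " miRNA")

  ## 3. lncRNA candidate filtering
  libSizes <- colSums(counts)
  fpkm <- computeFPKM(counts[lncIds, , drop = FALSE], lengths[lncIds],
                      libSizes)
  cov <- readCoverage(counts[lncIds, , drop = FALSE], lengths[lncIds],
                      readLength = if (!is.null(p$readLength)) p$readLength
                      else 150)
  scores <- orfCodingScore(txSequences(sim)[lncIds])
  votes <- matrix(scores$coding, ncol = 1,
                  dimnames = list(lncIds, "orf"))
  txInfo <- data.frame(id = lncIds, length = unname(lengths[lncIds]),
                       n_exons = rd[lncIds, "n_exons"],
                       annotated_biotype = unname(biotype[lncIds]),
                       stringsAsFactors = FALSE)
  lncFilter <- filterLncRNACandidates(txInfo, fpkm, cov, votes)
  candidates <- lncFilter$id[lncFilter$pass]
  specL <- specL[specL$feature %in% candidates, , drop = FALSE]
  say("lncRNA candidates: ", length(candidates), " of ", length(lncIds))

  ## 4. target edges
  ssSel <- cd$tissue == focalTissue & cd$condition == ref
  ssCounts <- counts[, ssSel, drop = FALSE]
  ssExpr <- vstTransform(ssCounts, sizeFactorsMoR(ssCounts))
  cis <- cisTargets(gr[intersect(candidates, names(gr))], gr[mrnaIds],
                    window = cisWindow)
  trans <- suppressWarnings(
    transTargets(ssExpr[candidates, , drop = FALSE],
                 ssExpr[mrnaIds, , drop = FALSE], rThreshold))
  seedLnc <- seedTargets(mirSequences(sim),
                         txSequences(sim)[candidates])
  seedMrna <- seedTargets(mirSequences(sim), txSequences(sim)[mrnaIds])
  lncMrna <- rbind(cis[, c("regulator", "target")],
                   trans[, c("regulator", "target")])
  say("edges: ", nrow(cis), " cis, ", nrow(trans), " trans, ",
      nrow(seedLnc), " miRNA-lncRNA seed, ", nrow(seedMrna),
      " miRNA-mRNA seed")

  ## 5. DE/target overlap (focal-specific DE regulators only)
  lncEdgesDE <- lncMrna[lncMrna$regulator %in% specL$feature, , drop = FALSE]
  mirEdgesDE <- seedMrna[seedMrna$regulator %in% specR$feature, ,
                         drop = FALSE]
  overlap <- overlapTargets(specM$feature, lncEdgesDE, mirEdgesDE)

  ## 6. trend-model triple assembly
  triples <- assembleTriples(specL, specR, specM, seedLnc, seedMrna,
                             lncMrnaEdges = lncMrna,
                             requireLncMrnaEdge = requireLncMrnaEdge)
  say("assembled triples: ", nrow(triples))

  ## 7. stage-series co-expression on focal-tissue reference samples
  coexpr <- runCoexpression(counts[mrnaIds, ssSel, drop = FALSE],
                            stages = cd$stage[ssSel],
                            minSumCounts = minSumCounts, powers = powers,
                            r2Target = r2Target,
                            minModuleSize = minModuleSize,
                            cutHeight = cutHeight,
                            kmeThreshold = kmeThreshold)

  ## 8. prioritization by significant focal-stage modules
  finalTriples <- prioritizeTriples(triples, coexpr, focalStage,
                                    pThreshold = modulePThreshold)
  say("final triples: ", nrow(finalTriples))

  report <- list(focalTissue = focalTissue, focalStage = focalStage,
                 reference = ref,
                 deTables = deTables, deSets = deSets,
                 specific = list(mRNA = specM, lncRNA = specL, miRNA = specR),
                 lncFilter = lncFilter, candidates = candidates,
                 edges = list(cis = cis, trans = trans, seedLnc = seedLnc,
                              seedMrna = seedMrna),
                 overlap = overlap, triples = triples, coexpr = coexpr,
                 finalTriples = finalTriples)

  truth <- tryCatch(plantedTruth(sim), error = function(e) NULL)
  if (!is.null(truth) && length(truth)) {
    report$recovery <- scoreRecovery(finalTriples, truth$triples)
    report$attrition <- .tripleAttrition(truth, report, requireLncMrnaEdge)
  }
  if (!is.null(outDir)) .writeReport(report, outDir)
  report
}

## first pipeline stage at which each planted triple was lost
.tripleAttrition <- function(truth, report, strict) {
  stages <- c("DE call", "tissue specificity", "lncRNA filter",
              "target edges", "assembly", "prioritization")
  dirs <- stats::setNames(report$deSets[[report$focalTissue]]$direction,
                          report$deSets[[report$focalTissue]]$feature)
  specAll <- c(report$specific$mRNA$feature, report$specific$lncRNA$feature,
               report$specific$miRNA$feature)
  edgeKey <- function(e) paste(e$regulator, e$target, sep = "\r")
  sLnc <- edgeKey(report$edges$seedLnc)
  sMrna <- edgeKey(report$edges$seedMrna)
  lg <- c(edgeKey(report$edges$cis), edgeKey(report$edges$trans))
  asmKey <- paste(report$triples$lncRNA, report$triples$miRNA,
                  report$triples$mRNA)
  finKey <- paste(report$finalTriples$lncRNA, report$finalTriples$miRNA,
                  report$finalTriples$mRNA)
  lostAt <- character(nrow(truth$triples))
  for (i in seq_len(nrow(truth$triples))) {
    L <- truth$triples$lncRNA[i]; M <- truth$triples$miRNA[i]
    G <- truth$triples$mRNA[i]
    md <- .trendModels[[truth$triples$model[i]]]
    lostAt[i] <-
      if (!(identical(unname(dirs[L]), unname(md[["lncRNA"]])) &&
            identical(unname(dirs[M]), unname(md[["miRNA"]])) &&
            identical(unname(dirs[G]), unname(md[["mRNA"]]))))
        "DE call"
      else if (!all(c(L, M, G) %in% specAll)) "tissue specificity"
      else if (!L %in% report$candidates) "lncRNA filter"
      else if (!(paste(M, L, sep = "\r") %in% sLnc &&
                 paste(M, G, sep = "\r") %in% sMrna &&
                 (!strict || paste(L, G, sep = "\r") %in% lg)))
        "target edges"
      else if (!paste(L, M, G) %in% asmKey) "assembly"
      else if (!paste(L, M, G) %in% finKey) "prioritization"
      else "recovered"
  }
  tab <- table(factor(lostAt, levels = c(stages, "recovered")))
  list(perTriple = data.frame(truth$triples, lostAt = lostAt,
                              stringsAsFactors = FALSE),
       counts = tab)
}

#' Score triple recovery against planted truth
#'
#' Exact-match comparison of candidate triples with the planted truth set.
#'
#' @param candidates DataFrame/data.frame with `lncRNA`, `miRNA`, `mRNA`.
#' @param truthTriples the planted triples (same columns).
#' @return list with `precision` (`NA` when there are no candidates),
#'   `recall`, `nCandidates`, `nTruth`, `truePositives`, `falsePositives`
#'   and `falseNegatives` (data.frames).
#' @export
#' @examples
#' tr <- data.frame(lncRNA = "L1", miRNA = "M1", mRNA = "G1")
#' scoreRecovery(tr, tr)  # precision = recall = 1
scoreRecovery <- function(candidates, truthTriples) {
  key <- function(d) paste(d$lncRNA, d$miRNA, d$mRNA)
  ck <- key(candidates); tk <- key(truthTriples)
  tp <- candidates[ck %in% tk, , drop = FALSE]
  fp <- candidates[!ck %in% tk, , drop = FALSE]
  fn <- truthTriples[!tk %in% ck, , drop = FALSE]
  list(precision = if (nrow(candidates)) nrow(tp) / nrow(candidates)
       else NA_real_,
       recall = if (nrow(truthTriples)) nrow(tp) / nrow(truthTriples)
       else NA_real_,
       nCandidates = nrow(candidates), nTruth = nrow(truthTriples),
       truePositives = as.data.frame(tp), falsePositives = as.data.frame(fp),
       falseNegatives = as.data.frame(fn))
}

.writeTsv <- function(d, path) {
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (t in names(report$deTables))
    .writeTsv(report$deTables[[t]],
              file.path(outDir, sprintf("de_%s.tsv", t)))
  .writeTsv(report$lncFilter, file.path(outDir, "lncrna_filter.tsv"))
  for (e in names(report$edges)) {
    ed <- report$edges[[e]]
    ed$siteStarts <- NULL
    .writeTsv(ed, file.path(outDir, sprintf("edges_%s.tsv", e)))
  }
  .writeTsv(report$triples, file.path(outDir, "triples.tsv"))
  .writeTsv(report$finalTriples, file.path(outDir, "final_triples.tsv"))
  cx <- report$coexpr
  .writeTsv(data.frame(gene = names(moduleLabels(cx)),
                       module = moduleLabels(cx)),
            file.path(outDir, "modules.tsv"))
  .writeTsv(data.frame(module = rownames(eigengenes(cx)), eigengenes(cx),
                       check.names = FALSE),
            file.path(outDir, "eigengenes.tsv"))
  ta <- traitAssociation(cx)
  .writeTsv(data.frame(module = rownames(ta$r), r = ta$r, p = ta$p,
                       check.names = FALSE),
            file.path(outDir, "module_trait.tsv"))
  summaryJson <- list(
    focalTissue = report$focalTissue, focalStage = report$focalStage,
    softPower = softPower(cx),
    nCandidateLnc = length(report$candidates),
    nAssembledTriples = nrow(report$triples),
    finalTriples = as.data.frame(report$finalTriples))
  if (!is.null(report$recovery))
    summaryJson$recovery <- report$recovery[c("precision", "recall",
                                              "nCandidates", "nTruth")]
  jsonlite::write_json(summaryJson, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
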