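#' Simulation parameters for a synthetic placode experiment
#'
#' Builds and validates the parameter list consumed by
#' [simulatePlacodeData()]. Defaults describe the study design the pipeline is
#' meant to exercise: two phenotypes (normal, hairless) with three replicate
#' embryos each, five tissues and five embryonic stages, with hair-placode
#' signal focused on skin at E41.
#'
#' @param nMrna,nLnc,nMir numbers of mRNAs, lncRNA candidates and miRNAs.
#' @param tissues,stages design labels.
#' @param focalTissue,focalStage where differential expression and the
#'   stage-associated module are planted.
#' @param conditions two phenotype labels; the first is the reference.
#' @param nReps replicates per condition x tissue x stage cell (>= 2).
#' @param nbMeanLog2Range log2-scale interval for per-feature base means
#'   (drawn log-uniformly).
#' @param dispersion per-gene negative-binomial dispersion (> 0).
#' @param deFraction fraction of mRNAs planted differentially expressed per
#'   tissue.
#' @param deLfc planted absolute log2 fold change (> 0).
#' @param nTriples number of planted true ceRNA triples.
#' @param nDecoyTriples planted near-triples that must be rejected downstream
#'   (half violate the trend models, half have an mRNA outside the
#'   stage-associated module).
#' @param moduleSizes gene counts of the planted co-expression modules; the
#'   first module is associated with `focalStage` and carries the triple
#'   mRNAs.
#' @param decoyFraction fraction of lncRNA candidates that are decoys, split
#'   over four classes (short, mono-exonic, coding-ORF, low-expression).
#' @param cisGap genomic gap (bp) used for designed lncRNA-mRNA cis pairs.
#' @param minGap minimum genomic gap (bp) between non-paired features; must
#'   exceed the downstream cis window (100 kb).
#' @param readLength sequencing read length (bp), used for the coverage proxy.
#' @param mrnaLength,lncLength,mirLength,utrLength transcript geometry (nt).
#' @param libLog2Spread half-range of log2 library-size factors; the default
#'   0.5 spans a 2-fold spread, exercising normalization.
#' @param moduleStageEffect,moduleFactorSd,loadingRange latent-factor model of
#'   the planted modules: each module shares a per-sample factor
#'   `effect * I(stage == module stage) + N(0, sd)` added on the log2-mean
#'   scale with per-gene loadings drawn uniformly from `loadingRange`.
#' @param nChrom number of chromosomes used for placement.
#' @param seed integer seed; all generator output is a pure function of the
#'   parameter list including this seed.
#'
#' @return A named list of class `SimulationParams`.
#' @export
#' @examples
#' p <- simParams(nMrna = 100, nLnc = 20, nMir = 8, nTriples = 3,
#'                moduleSizes = c(10, 10), seed = 7)
#' p$focalTissue
simParams <- function(nMrna = 2000, nLnc = 100, nMir = 50,
                      tissues = c("skin", "heart", "liver", "lung", "kidney"),
                      stages = c("E39", "E41", "E45", "E52", "E60"),
                      focalTissue = "skin", focalStage = "E41",
                      conditions = c("normal", "hairless"),
                      nReps = 3,
                      nbMeanLog2Range = c(log2(20), log2(2000)),
                      dispersion = 0.05,
                      deFraction = 0.10, deLfc = 2.0,
                      nTriples = 10, nDecoyTriples = 4,
                      moduleSizes = c(50, 50, 50),
                      decoyFraction = 0.2,
                      cisGap = 50000L, minGap = 150000L,
                      readLength = 150L,
                      mrnaLength = 1200L, lncLength = 600L, mirLength = 22L,
                      utrLength = 250L,
                      libLog2Spread = 0.5,
                      moduleStageEffect = 1.5, moduleFactorSd = 0.5,
                      loadingRange = c(0.9, 1.1),
                      nChrom = 20L, seed = 42L) {
  p <- list(nMrna = as.integer(nMrna), nLnc = as.integer(nLnc),
            nMir = as.integer(nMir), tissues = tissues, stages = stages,
            focalTissue = focalTissue, focalStage = focalStage,
            conditions = conditions, nReps = as.integer(nReps),
            nbMeanLog2Range = nbMeanLog2Range, dispersion = dispersion,
            deFraction = deFraction, deLfc = deLfc,
            nTriples = as.integer(nTriples),
            nDecoyTriples = as.integer(nDecoyTriples),
            moduleSizes = as.integer(moduleSizes),
            decoyFraction = decoyFraction,
            cisGap = as.integer(cisGap), minGap = as.integer(minGap),
            readLength = as.integer(readLength),
            mrnaLength = as.integer(mrnaLength),
            lncLength = as.integer(lncLength),
            mirLength = as.integer(mirLength),
            utrLength = as.integer(utrLength),
            libLog2Spread = libLog2Spread,
            moduleStageEffect = moduleStageEffect,
            moduleFactorSd = moduleFactorSd, loadingRange = loadingRange,
            nChrom = as.integer(nChrom), seed = as.integer(seed))
  stopifnot(p$nReps >= 2L, p$deLfc > 0, p$dispersion > 0,
            length(p$conditions) == 2L)
  if (!p$focalTissue %in% p$tissues) stop("focalTissue must be in tissues")
  if (!p$focalStage %in% p$stages) stop("focalStage must be in stages")
  if (p$minGap <= 100000L)
    stop("minGap must exceed the 100 kb cis window so non-pairs stay apart")
  if (p$mirLength < 8L)
    stop("miRNA length must be >= 8 nt so the seed region (nt 2-8) exists")
  nDecoy <- floor(p$decoyFraction * p$nLnc)
  if (p$nLnc - nDecoy < p$nTriples + p$nDecoyTriples)
    stop("not enough non-decoy lncRNAs for the planted triples")
  if (p$nMir < p$nTriples + p$nDecoyTriples)
    stop("not enough miRNAs for the planted triples")
  nonfree <- p$nTriples + p$nDecoyTriples + sum(p$moduleSizes) - p$nTriples
  if (p$nMrna <= nonfree + ceiling(p$deFraction * p$nMrna))
    stop("nMrna too small for the requested modules, triples and DE fraction")
  class(p) <- "SimulationParams"
  p
}

.decoyClasses <- c("short", "monoexonic", "coding", "lowexpr")

## Deterministic design plan: feature ids, lncRNA decoy classes, triple and
## module membership, per-tissue DE sets. Uses the RNG stream seeded from
## params$seed; callers re-seed before each generation stage so that the
## stages are individually reproducible.
.planDesign <- function(p) {
  set.seed(p$seed %% .Machine$integer.max)
  mrna <- sprintf("G%04d", seq_len(p$nMrna))
  lnc <- sprintf("L%03d", seq_len(p$nLnc))
  mir <- sprintf("M%03d", seq_len(p$nMir))

  nDecoy <- floor(p$decoyFraction * p$nLnc)
  lncClass <- rep("true", p$nLnc)
  if (nDecoy > 0)
    lncClass[(p$nLnc - nDecoy + 1L):p$nLnc] <-
      rep(.decoyClasses, length.out = nDecoy)
  names(lncClass) <- lnc
  trueLnc <- lnc[lncClass == "true"]

  nT <- p$nTriples; nD <- p$nDecoyTriples
  tripleLnc <- trueLnc[seq_len(nT)]
  decoyLnc <- trueLnc[nT + seq_len(nD)]
  tripleMir <- mir[seq_len(nT)]
  decoyMir <- mir[nT + seq_len(nD)]
  tripleMrna <- mrna[seq_len(nT)]
  decoyMrna <- mrna[nT + seq_len(nD)]

  models <- rep(c("model1", "model2"), length.out = nT)
  triples <- data.frame(lncRNA = tripleLnc, miRNA = tripleMir,
                        mRNA = tripleMrna, model = models,
                        stringsAsFactors = FALSE)
  decoyType <- rep(c("direction", "module"), length.out = nD)
  decoyTriples <- data.frame(lncRNA = decoyLnc, miRNA = decoyMir,
                             mRNA = decoyMrna, type = decoyType,
                             stringsAsFactors = FALSE)

  ## module membership: module 1 carries the true triple mRNAs and is tied to
  ## the focal stage; further modules are tied to other stages in turn
  cursor <- nT + nD
  modules <- list()
  otherStages <- setdiff(p$stages, p$focalStage)
  for (m in seq_along(p$moduleSizes)) {
    sz <- p$moduleSizes[m]
    if (m == 1L) {
      fill <- mrna[cursor + seq_len(max(0L, sz - nT))]
      genes <- c(tripleMrna, fill)
      cursor <- cursor + max(0L, sz - nT)
      stage <- p$focalStage
    } else {
      genes <- mrna[cursor + seq_len(sz)]
      cursor <- cursor + sz
      stage <- otherStages[(m - 2L) %% length(otherStages) + 1L]
    }
    modules[[paste0("mod", m)]] <- list(id = paste0("mod", m),
                                        genes = genes, stage = stage)
  }
  moduleGenes <- unique(unlist(lapply(modules, `[[`, "genes")))
  freeMrna <- setdiff(mrna, c(tripleMrna, decoyMrna, moduleGenes))
  freeLnc <- setdiff(trueLnc, c(tripleLnc, decoyLnc))
  freeMir <- setdiff(mir, c(tripleMir, decoyMir))

  dirFor <- function(model, slot) {
    ## model1: lncRNA-|miRNA+|mRNA-  model2: lncRNA+|miRNA-|mRNA+
    if (model == "model1") c(lncRNA = "down", miRNA = "up", mRNA = "down")[slot]
    else c(lncRNA = "up", miRNA = "down", mRNA = "up")[slot]
  }

  nDe <- floor(p$deFraction * p$nMrna)
  de <- list()
  for (t in p$tissues) {
    if (t == p$focalTissue) {
      feats <- character(0); dirs <- character(0)
      for (i in seq_len(nT)) {
        feats <- c(feats, triples$lncRNA[i], triples$miRNA[i], triples$mRNA[i])
        dirs <- c(dirs, dirFor(triples$model[i], "lncRNA"),
                  dirFor(triples$model[i], "miRNA"),
                  dirFor(triples$model[i], "mRNA"))
      }
      for (i in seq_len(nD)) {
        if (decoyTriples$type[i] == "direction") {
          ## break the trend signature: all three members up
          feats <- c(feats, decoyTriples$lncRNA[i], decoyTriples$miRNA[i],
                     decoyTriples$mRNA[i])
          dirs <- c(dirs, "up", "up", "up")
        } else {
          mdl <- c("model1", "model2")[i %% 2L + 1L]
          feats <- c(feats, decoyTriples$lncRNA[i], decoyTriples$miRNA[i],
                     decoyTriples$mRNA[i])
          dirs <- c(dirs, dirFor(mdl, "lncRNA"), dirFor(mdl, "miRNA"),
                    dirFor(mdl, "mRNA"))
        }
      }
      extraM <- sample(freeMrna, min(nDe, length(freeMrna)))
      extraL <- sample(freeLnc, min(5L, length(freeLnc)))
      extraR <- sample(freeMir, min(3L, length(freeMir)))
      extra <- c(extraM, extraL, extraR)
      feats <- c(feats, extra)
      dirs <- c(dirs, sample(c("up", "down"), length(extra), replace = TRUE))
    } else {
      feats <- sample(freeMrna, min(nDe, length(freeMrna)))
      dirs <- sample(c("up", "down"), length(feats), replace = TRUE)
      if (length(freeLnc) >= 2L) {
        xl <- sample(freeLnc, 2L)
        feats <- c(feats, xl)
        dirs <- c(dirs, sample(c("up", "down"), 2L, replace = TRUE))
      }
    }
    de[[t]] <- data.frame(feature = feats, direction = dirs,
                          stringsAsFactors = FALSE)
  }

  cis <- data.frame(
    lncRNA = c(triples$lncRNA, decoyTriples$lncRNA),
    gene = c(triples$mRNA, decoyTriples$mRNA),
    gap = p$cisGap, stringsAsFactors = FALSE)

  list(mrna = mrna, lnc = lnc, mir = mir, lncClass = lncClass,
       triples = triples, decoyTriples = decoyTriples, modules = modules,
       de_features = de, cis_pairs = cis)
}

.txLength <- function(p, id, lncClass) {
  if (grepl("^G", id)) return(p$mrnaLength)
  if (grepl("^M", id)) return(p$mirLength)
  switch(lncClass[[id]],
         short = 150L,
         coding = 900L,
         p$lncLength)
}

.nExons <- function(id, lncClass) {
  if (grepl("^G", id)) return(3L)
  if (grepl("^M", id)) return(1L)
  if (lncClass[[id]] == "monoexonic") 1L else 2L
}

#' Generate a synthetic transcript annotation with planted cis pairs
#'
#' Places every transcript on a synthetic genome so that designed lncRNA-mRNA
#' cis pairs sit within the generator's cis gap while all other features are
#' separated by more than the downstream 100 kb cis window. lncRNA candidates
#' are at least 200 nt with at least two exons except for the planted decoy
#' classes (short, mono-exonic, coding-ORF, low-expression), each built to
#' fail the candidate filters.
#'
#' @param params a `SimulationParams` list from [simParams()].
#' @return A list with elements `ranges` (transcript-level
#'   [GenomicRanges::GRanges] with `biotype`, `tx_length`, `n_exons` metadata),
#'   `exons` (a [GenomicRanges::GRangesList]) and `truth` (the planted design:
#'   DE features per tissue, triples, decoy triples, modules, cis pairs and
#'   lncRNA classes).
#' @export
#' @examples
#' ann <- generateAnnotation(simParams(nMrna = 60, nLnc = 12, nMir = 6,
#'                                     nTriples = 2, moduleSizes = c(8, 8),
#'                                     seed = 1))
#' ann$ranges[1:3]
generateAnnotation <- function(params) {
  p <- params
  plan <- .planDesign(p)
  set.seed((p$seed + 1L) %% .Machine$integer.max)

  pairedIds <- c(plan$cis_pairs$lncRNA, plan$cis_pairs$gene)
  singles <- setdiff(c(plan$mrna, plan$lnc, plan$mir), pairedIds)
  units <- c(lapply(seq_len(nrow(plan$cis_pairs)), function(i)
               c(plan$cis_pairs$lncRNA[i], plan$cis_pairs$gene[i])),
             as.list(singles))
  units <- units[sample.int(length(units))]

  chrom <- paste0("chr", seq_len(p$nChrom))
  cursor <- stats::setNames(rep(10001L, p$nChrom), chrom)
  maxTries <- 50L

  exonRows <- list()
  uChr <- rep(chrom, length.out = length(units))

  for (u in seq_along(units)) {
    ids <- units[[u]]
    ch <- uChr[u]
    for (j in seq_along(ids)) {
      id <- ids[j]
      len <- .txLength(p, id, plan$lncClass)
      k <- .nExons(id, plan$lncClass)
      ew <- rep(len %/% k, k)
      ew[1] <- ew[1] + len %% k
      introns <- if (k > 1) sample(200:2000, k - 1, replace = TRUE) else integer(0)
      span <- sum(ew) + sum(introns)
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        start <- cursor[[ch]]
        if (start + span < 5e8) { placed <- TRUE; break }
        ch <- chrom[(match(ch, chrom) %% p$nChrom) + 1L]
      }
      if (!placed)
        stop("placement failure: could not honour the gap constraint for ", id)
      strand <- sample(c("+", "-"), 1L)
      es <- start
      starts <- integer(k); ends <- integer(k)
      for (e in seq_len(k)) {
        starts[e] <- es
        ends[e] <- es + ew[e] - 1L
        es <- ends[e] + if (e < k) introns[e] + 1L else 1L
      }
      exonRows[[id]] <- data.frame(chrom = ch, start = starts, end = ends,
                                   strand = strand, id = id,
                                   stringsAsFactors = FALSE)
      ## gap to the next feature: the designed cis gap inside a pair,
      ## otherwise more than the cis window
      gapNext <- if (j < length(ids)) p$cisGap else
        p$minGap + sample.int(50000L, 1L)
      cursor[[ch]] <- ends[k] + gapNext + 1L
    }
  }

  exAll <- do.call(rbind, exonRows)
  ids <- unique(exAll$id)
  ## transcript-level ranges
  agg <- do.call(rbind, lapply(split(exAll, exAll$id), function(d)
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
               strand = d$strand[1], id = d$id[1], n_exons = nrow(d),
               tx_length = sum(d$end - d$start + 1L),
               stringsAsFactors = FALSE)))
  ord <- c(plan$mrna, plan$lnc, plan$mir)
  agg <- agg[match(ord, agg$id), ]
  biotype <- ifelse(grepl("^G", agg$id), "mRNA",
                    ifelse(grepl("^L", agg$id), "lncRNA_candidate", "miRNA"))
  gr <- GenomicRanges::GRanges(
    seqnames = agg$chrom,
    ranges = IRanges::IRanges(start = agg$start, end = agg$end),
    strand = agg$strand)
  names(gr) <- agg$id
  S4Vectors::mcols(gr)$gene_id <- agg$id
  S4Vectors::mcols(gr)$biotype <- biotype
  S4Vectors::mcols(gr)$tx_length <- agg$tx_length
  S4Vectors::mcols(gr)$n_exons <- agg$n_exons
  sl <- tapply(agg$end, agg$chrom, max) + 10000L
  sl <- stats::setNames(as.integer(sl), names(sl))
  GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]

  exl <- GenomicRanges::GRangesList(lapply(ord, function(id) {
    d <- exonRows[[id]]
    g <- GenomicRanges::GRanges(d$chrom,
                                IRanges::IRanges(d$start, d$end), d$strand)
    g
  }))
  names(exl) <- ord

  truth <- list(de_features = plan$de_features, triples = plan$triples,
                decoy_triples = plan$decoyTriples, modules = plan$modules,
                cis_pairs = plan$cis_pairs,
                lnc_status = data.frame(id = plan$lnc,
                                        class = unname(plan$lncClass[plan$lnc]),
                                        stringsAsFactors = FALSE))
  list(ranges = gr, exons = exl, truth = truth)
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.codingDna <- function(n) {
  ## an ORF spanning ~90% of the transcript, flanked by short random pads
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  codons <- setdiff(codons, stops)
  pad <- 30L
  orfCodons <- (n - 2L * pad) %/% 3L - 2L
  body <- paste(sample(codons, orfCodons, replace = TRUE), collapse = "")
  seqc <- paste0(.randomDna(pad), "ATG", body, "TAA", .randomDna(pad))
  substr(seqc, 1L, n)
}

#' Generate transcript and miRNA sequences with embedded seed sites
#'
#' Background sequence is uniform over A/C/G/T. For every planted (true or
#' decoy) triple the exact reverse complement of the miRNA seed (nucleotides
#' 2-8) is embedded once in the target mRNA's 3' UTR region and once in the
#' sponge lncRNA. True lncRNA candidates are re-drawn until their longest open
#' reading frame stays safely below the coding-potential cutoff; coding-decoy
#' lncRNAs carry a near-full-length ORF.
#'
#' @param annotation output of [generateAnnotation()].
#' @param truth the `truth` element of that output.
#' @param params the `SimulationParams` list.
#' @return A list with `tx` (transcript [Biostrings::DNAStringSet]), `mir`
#'   (miRNA [Biostrings::DNAStringSet], U written as T) and `seed_sites`
#'   (data.frame of embedded site positions, 0-based starts on the target).
#' @export
generateSequences <- function(annotation, truth, params) {
  p <- params
  if (p$mirLength < 8L)
    stop("seed region (miRNA nt 2-8) requires miRNA length >= 8")
  set.seed((p$seed + 2L) %% .Machine$integer.max)
  gr <- annotation$ranges
  ids <- names(gr)
  lens <- stats::setNames(S4Vectors::mcols(gr)$tx_length, ids)
  biotype <- stats::setNames(S4Vectors::mcols(gr)$biotype, ids)
  lncClass <- stats::setNames(truth$lnc_status$class, truth$lnc_status$id)

  mirIds <- ids[biotype == "miRNA"]
  mirSeq <- vapply(mirIds, function(i) .randomDna(lens[[i]]), "")
  seeds <- substr(mirSeq, 2L, 8L)
  sites <- vapply(seeds, function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))), "")
  names(sites) <- mirIds

  txIds <- ids[biotype != "miRNA"]
  txSeq <- stats::setNames(character(length(txIds)), txIds)
  for (i in txIds) {
    if (biotype[[i]] == "lncRNA_candidate" && lncClass[[i]] == "coding")
      txSeq[[i]] <- .codingDna(lens[[i]])
    else
      txSeq[[i]] <- .randomDna(lens[[i]])
  }

  allTriples <- rbind(truth$triples[, c("lncRNA", "miRNA", "mRNA")],
                      truth$decoy_triples[, c("lncRNA", "miRNA", "mRNA")])
  siteRows <- list()
  embed <- function(seqc, site, at) {
    substr(seqc, at, at + nchar(site) - 1L) <- site
    seqc
  }
  for (i in seq_len(nrow(allTriples))) {
    m <- allTriples$miRNA[i]; g <- allTriples$mRNA[i]; l <- allTriples$lncRNA[i]
    site <- sites[[m]]
    ## mRNA: inside the 3' UTR window
    gl <- lens[[g]]
    lo <- max(1L, gl - p$utrLength + 1L)
    at <- sample(lo:(gl - 6L), 1L)
    txSeq[[g]] <- embed(txSeq[[g]], site, at)
    siteRows[[length(siteRows) + 1L]] <-
      data.frame(miRNA = m, target = g, start0 = at - 1L)
    ## lncRNA: anywhere
    ll <- lens[[l]]
    at <- sample(1L:(ll - 6L), 1L)
    txSeq[[l]] <- embed(txSeq[[l]], site, at)
    siteRows[[length(siteRows) + 1L]] <-
      data.frame(miRNA = m, target = l, start0 = at - 1L)
  }

  ## true lncRNAs must survive the ORF-based coding filter
  lncTrue <- names(lncClass)[lncClass %in% c("true", "lowexpr")]
  for (i in lncTrue) {
    tries <- 0L
    while (.longestOrf(txSeq[[i]]) / lens[[i]] >= 0.45) {
      tries <- tries + 1L
      if (tries > 100L)
        stop("could not draw a non-coding sequence for ", i,
             " under the ORF-fraction constraint")
      txSeq[[i]] <- .randomDna(lens[[i]])
      hit <- which(allTriples$lncRNA == i)
      for (h in hit) {
        at <- sample(1L:(lens[[i]] - 6L), 1L)
        txSeq[[i]] <- embed(txSeq[[i]], sites[[allTriples$miRNA[h]]], at)
        sel <- vapply(siteRows, function(r)
          r$target == i && r$miRNA == allTriples$miRNA[h], TRUE)
        siteRows[[which(sel)[1]]]$start0 <- at - 1L
      }
    }
  }

  list(tx = Biostrings::DNAStringSet(txSeq),
       mir = Biostrings::DNAStringSet(mirSeq),
       seed_sites = do.call(rbind, siteRows))
}

#' Simulate negative-binomial counts with planted effects
#'
#' Draws counts `NB(mu, dispersion)` for every feature and sample. Planted DE
#' features have their mean shifted by `2^(+/- deLfc)` in the non-reference
#' condition of the feature's tissue at the focal stage only; module genes
#' share a per-sample latent factor (on the log2-mean scale) tied to the
#' module's stage in the focal tissue; library-size factors span a 2-fold
#' range.
#'
#' @param annotation output of [generateAnnotation()].
#' @param truth the `truth` element of that output.
#' @param params the `SimulationParams` list.
#' @return A list with `counts` (integer matrix features x samples), `design`
#'   (data.frame: sample, condition, tissue, stage, replicate, lib_factor) and
#'   `baseMeans`.
#' @export
simulateCounts <- function(annotation, truth, params) {
  p <- params
  set.seed((p$seed + 3L) %% .Machine$integer.max)
  ids <- names(annotation$ranges)
  nF <- length(ids)

  design <- expand.grid(replicate = seq_len(p$nReps),
                        condition = p$conditions,
                        stage = p$stages, tissue = p$tissues,
                        stringsAsFactors = FALSE)
  design <- design[, c("condition", "tissue", "stage", "replicate")]
  design$sample <- sprintf("%s_%s_%s_r%d", design$tissue, design$stage,
                           design$condition, design$replicate)
  nS <- nrow(design)

  base <- 2^stats::runif(nF, p$nbMeanLog2Range[1], p$nbMeanLog2Range[2])
  names(base) <- ids
  lowexpr <- truth$lnc_status$id[truth$lnc_status$class == "lowexpr"]
  base[lowexpr] <- 0.05

  lib <- 2^seq(-p$libLog2Spread, p$libLog2Spread, length.out = nS)
  lib <- lib[sample.int(nS)]
  design$lib_factor <- lib

  offset <- matrix(0, nF, nS, dimnames = list(ids, design$sample))
  ref <- p$conditions[1]
  for (t in names(truth$de_features)) {
    de <- truth$de_features[[t]]
    cols <- design$tissue == t & design$stage == p$focalStage &
      design$condition != ref
    sgn <- ifelse(de$direction == "up", 1, -1)
    offset[de$feature, cols] <- offset[de$feature, cols] + sgn * p$deLfc
  }
  focalCols <- design$tissue == p$focalTissue
  for (m in truth$modules) {
    z <- p$moduleStageEffect * as.numeric(design$stage[focalCols] == m$stage) +
      stats::rnorm(sum(focalCols), 0, p$moduleFactorSd)
    lam <- stats::runif(length(m$genes), p$loadingRange[1], p$loadingRange[2])
    offset[m$genes, focalCols] <- offset[m$genes, focalCols] +
      outer(lam, z)
  }

  mu <- sweep(2^offset * base, 2, lib, `*`)
  if (any(mu < 0)) stop("negative NB means are not allowed")
  counts <- matrix(stats::rnbinom(nF * nS, mu = mu, size = 1 / p$dispersion),
                   nF, nS, dimnames = list(ids, design$sample))
  storage.mode(counts) <- "integer"
  list(counts = counts, design = design, baseMeans = base)
}

#' Simulate a complete synthetic placode experiment
#'
#' Composes [generateAnnotation()], [generateSequences()] and
#' [simulateCounts()] into a [PlacodeSim] object carrying counts, annotation,
#' sequences and the planted ground truth. Output is a pure function of
#' `params` (including its `seed`).
#'
#' @param params a `SimulationParams` list from [simParams()].
#' @return A [PlacodeSim] object.
#' @export
#' @examples
#' sim <- simulatePlacodeData(simParams(nMrna = 60, nLnc = 12, nMir = 6,
#'                                      nTriples = 2, moduleSizes = c(8, 8),
#'                                      seed = 1))
#' sim
simulatePlacodeData <- function(params) {
  ann <- generateAnnotation(params)
  sq <- generateSequences(ann, ann$truth, params)
  cn <- simulateCounts(ann, ann$truth, params)
  truth <- ann$truth
  truth$seed_sites <- sq$seed_sites
  cd <- S4Vectors::DataFrame(cn$design, row.names = cn$design$sample)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cn$counts),
    rowRanges = ann$ranges, colData = cd)
  methods::new("PlacodeSim", se, exons = ann$exons, txSequences = sq$tx,
               mirSequences = sq$mir, truth = truth,
               params = unclass(params))
}

#' Write a PlacodeSim to standard on-disk formats
#'
#' Writes a GTF (1-based inclusive `exon` features with `transcript_id`,
#' `gene_id`, `gene_biotype`), transcript and miRNA FASTA files, a counts TSV
#' (feature x sample), a design TSV and a truth JSON.
#'
#' @param sim a [PlacodeSim] object.
#' @param dir output directory, created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
writeSimData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gr <- SummarizedExperiment::rowRanges(sim)
  ex <- txExons(sim)
  biotype <- stats::setNames(S4Vectors::mcols(gr)$biotype, names(gr))
  exFlat <- unlist(ex)
  txid <- rep(names(ex), lengths(ex))
  S4Vectors::mcols(exFlat)$type <- "exon"
  S4Vectors::mcols(exFlat)$transcript_id <- txid
  S4Vectors::mcols(exFlat)$gene_id <- txid
  S4Vectors::mcols(exFlat)$gene_biotype <- unname(biotype[txid])
  paths <- c(gtf = file.path(dir, "annotation.gtf"),
             tx_fasta = file.path(dir, "transcripts.fa"),
             mir_fasta = file.path(dir, "mirnas.fa"),
             counts = file.path(dir, "counts.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.json"))
  rtracklayer::export(exFlat, paths[["gtf"]], format = "gtf")
  Biostrings::writeXStringSet(txSequences(sim), paths[["tx_fasta"]])
  Biostrings::writeXStringSet(mirSequences(sim), paths[["mir_fasta"]])
  cts <- SummarizedExperiment::assay(sim, "counts")
  utils::write.table(data.frame(feature = rownames(cts), cts,
                                check.names = FALSE),
                     paths[["counts"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(SummarizedExperiment::colData(sim)),
                     paths[["design"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(plantedTruth(sim), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
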