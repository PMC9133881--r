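test_that("generator output is a pure function of params and seed", {
  p <- smallSimParams(seed = 7)
  sim1 <- simulatePlacodeData(p)
  sim2 <- simulatePlacodeData(p)
  expect_identical(SummarizedExperiment::assay(sim1),
                   SummarizedExperiment::assay(sim2))
  expect_identical(as.character(txSequences(sim1)),
                   as.character(txSequences(sim2)))
  expect_identical(plantedTruth(sim1), plantedTruth(sim2))

  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  writeSimData(sim1, d1); writeSimData(sim2, d2)
  expect_identical(readLines(file.path(d1, "annotation.gtf")),
                   readLines(file.path(d2, "annotation.gtf")))

  sim3 <- simulatePlacodeData(smallSimParams(seed = 8))
  expect_false(identical(SummarizedExperiment::assay(sim1),
                         SummarizedExperiment::assay(sim3)))
})

test_that("parameter validation rejects impossible designs", {
  expect_error(simParams(nReps = 1), "nReps")
  expect_error(simParams(focalTissue = "brain"), "focalTissue")
  expect_error(simParams(focalStage = "E99"), "focalStage")
  expect_error(simParams(mirLength = 7), "seed region")
  expect_error(simParams(minGap = 90000), "100 kb")
})

test_that("annotation places cis pairs inside and non-pairs outside the window", {
  sim <- simulatePlacodeData(smallSimParams())
  gr <- SummarizedExperiment::rowRanges(sim)
  tr <- plantedTruth(sim)
  ## designed pairs sit at the designed gap
  for (i in seq_len(nrow(tr$cis_pairs))) {
    d <- GenomicRanges::distance(gr[tr$cis_pairs$lncRNA[i]],
                                 gr[tr$cis_pairs$gene[i]],
                                 ignore.strand = TRUE)
    expect_equal(unname(d), generatorParams(sim)$cisGap)
  }
  ## all non-designed same-chromosome neighbours are > 100 kb apart
  pairKey <- paste(tr$cis_pairs$lncRNA, tr$cis_pairs$gene)
  hits <- GenomicRanges::findOverlaps(gr, gr, maxgap = 100000,
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  close <- unique(t(apply(cbind(names(gr)[q], names(gr)[s]), 1, sort)))
  close <- close[close[, 1] != close[, 2], , drop = FALSE]
  keys <- c(paste(close[, 1], close[, 2]), paste(close[, 2], close[, 1]))
  expect_true(all(keys %in% c(pairKey, paste(tr$cis_pairs$gene,
                                             tr$cis_pairs$lncRNA))))
})

test_that("lncRNA decoy classes violate their intended candidate rule", {
  sim <- simulatePlacodeData(smallSimParams())
  gr <- SummarizedExperiment::rowRanges(sim)
  rd <- SummarizedExperiment::rowData(sim)
  tr <- plantedTruth(sim)
  st <- tr$lnc_status
  lens <- stats::setNames(rd$tx_length, rownames(sim))
  nex <- stats::setNames(rd$n_exons, rownames(sim))
  expect_true(all(lens[st$id[st$class == "short"]] < 200))
  expect_true(all(nex[st$id[st$class == "monoexonic"]] == 1))
  expect_true(all(lens[st$id[st$class %in% c("true", "monoexonic",
                                             "coding", "lowexpr")]] >= 200))
  expect_true(all(nex[st$id[st$class != "monoexonic"]] >= 2))
  sc <- orfCodingScore(txSequences(sim)[st$id])
  expect_true(all(sc$coding[st$class == "coding"]))
  expect_false(any(sc$coding[st$class %in% c("true", "lowexpr")]))
})

test_that("planted seed sites are embedded; seed is miRNA nt 2-8", {
  sim <- simulatePlacodeData(smallSimParams())
  tr <- plantedTruth(sim)
  mir <- mirSequences(sim)
  tx <- txSequences(sim)
  for (i in seq_len(nrow(tr$triples))) {
    m <- tr$triples$miRNA[i]
    seed <- Biostrings::subseq(mir[[m]], 2, 8)
    expect_equal(length(seed), 7L)
    site <- Biostrings::reverseComplement(seed)
    expect_gte(Biostrings::countPattern(site, tx[[tr$triples$mRNA[i]]]), 1)
    expect_gte(Biostrings::countPattern(site, tx[[tr$triples$lncRNA[i]]]), 1)
  }
})

test_that("chance 7-mer hit rate in random UTRs matches the closed form", {
  set.seed(31)
  len <- 500; nSim <- 1000
  site <- "ATAAGCT"
  hits <- vapply(seq_len(nSim), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    grepl(site, s, fixed = TRUE)
  }, TRUE)
  pExp <- 1 - (1 - 4^-7)^(len - 6)
  ci <- stats::qnorm(0.995) * sqrt(pExp * (1 - pExp) / nSim)
  expect_lt(abs(mean(hits) - pExp), ci + 0.005)
})

test_that("simulated null counts have NB moments", {
  p <- simParams(nMrna = 200, nLnc = 12, nMir = 6, nTriples = 2,
                 nDecoyTriples = 2, moduleSizes = c(10, 10),
                 libLog2Spread = 0, seed = 5)
  sim <- simulatePlacodeData(p)
  tr <- plantedTruth(sim)
  planted <- unique(c(unlist(lapply(tr$de_features, `[[`, "feature")),
                      unlist(lapply(tr$modules, `[[`, "genes"))))
  nullG <- setdiff(rownames(sim)[SummarizedExperiment::rowData(sim)$biotype
                                 == "mRNA"], planted)
  cts <- SummarizedExperiment::assay(sim)[nullG, ]
  ## >= 10,000 iid draws in total across null genes (150 samples each)
  expect_gte(length(cts), 10000)
  m <- rowMeans(cts)
  v <- apply(cts, 1, stats::var)
  alphaHat <- (v - m) / m^2
  expect_lt(abs(stats::median(alphaHat) - p$dispersion), 0.03)
})

test_that("planted DE means shift only in the focal tissue and stage", {
  p <- smallSimParams()
  sim <- simulatePlacodeData(p)
  cd <- as.data.frame(SummarizedExperiment::colData(sim))
  cts <- SummarizedExperiment::assay(sim)
  tr <- plantedTruth(sim)
  g <- tr$triples$mRNA[1]
  dirg <- tr$de_features[[p$focalTissue]]
  sgn <- if (dirg$direction[dirg$feature == g] == "up") 1 else -1
  norm <- cts[g, ] / cd$lib_factor
  focalH <- cd$tissue == p$focalTissue & cd$stage == p$focalStage &
    cd$condition == "hairless"
  focalN <- cd$tissue == p$focalTissue & cd$stage == p$focalStage &
    cd$condition == "normal"
  obs <- log2(mean(norm[focalH]) / mean(norm[focalN]))
  expect_lt(abs(obs - sgn * p$deLfc), 1.0)
  ## another tissue at the focal stage is null for this gene
  otherH <- cd$tissue == "heart" & cd$stage == p$focalStage &
    cd$condition == "hairless"
  otherN <- cd$tissue == "heart" & cd$stage == p$focalStage &
    cd$condition == "normal"
  expect_lt(abs(log2(mean(norm[otherH]) / mean(norm[otherN]))), 1.0)
})

test_that("library size factors span at least a 2-fold range", {
  sim <- simulatePlacodeData(smallSimParams())
  lf <- SummarizedExperiment::colData(sim)$lib_factor
  expect_gte(max(lf) / min(lf), 2)
})
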