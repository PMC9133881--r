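test_that("vst transform hits exact values and normalization shifts", {
  expect_equal(vstTransform(matrix(0), factors = 1)[1], 0)
  expect_equal(vstTransform(matrix(1023), factors = 1)[1], 10)
  expect_error(vstTransform(matrix(-1), factors = 1), "non-negative")
  expect_error(vstTransform(matrix(1), factors = 0), "positive")
  ## doubling a sample's factor shifts large-count values by ~ -1
  cts <- matrix(2^c(10, 12, 14), 3, 1)
  d <- vstTransform(cts, factors = 2) - vstTransform(cts, factors = 1)
  expect_true(all(abs(d + 1) < 0.01))
})

test_that("sum-count gene filter is strictly greater than the threshold", {
  cts <- rbind(at = rep(2, 5), above = c(3, 2, 2, 2, 2),
               zero = rep(0, 5))
  keep <- filterGenesBySum(cts, 10)
  expect_setequal(keep, "above")
})

test_that("an exact discrete power law gives scale-free fit near 1", {
  k <- rep(2^(1:8), times = round(1000 * (2^(1:8))^-1.5))
  expect_gt(scaleFreeFitR2(k), 0.95)
  expect_error(scaleFreeFitR2(rep(3, 50)), "degenerate")
})

test_that("the soft-threshold selection rule picks the smallest admissible power", {
  expect_equal(chooseSoftPower(c(4, 10, 12), c(0.5, 0.82, 0.9)), 10)
  expect_equal(chooseSoftPower(c(4, 10, 12), c(0.5, 0.6, 0.7)), 12)
  expect_equal(chooseSoftPower(1:3, c(0.9, 0.95, 0.99)), 1)
})

test_that("independent noise genes never look scale-free; hub structure does", {
  set.seed(18)
  expr <- matrix(rnorm(200 * 20), 200, 20,
                 dimnames = list(paste0("g", 1:200), NULL))
  sft <- suppressWarnings(pickSoftThreshold(expr, powers = c(1, 4, 8, 12)))
  expect_true(all(sft$fitIndices$r2 < 0.6))
  ## data with modular structure fits a power law far better than noise
  eb <- blockExpr(nBlock = 40, nNoise = 120, nSamples = 20, seed = 4)
  sftB <- suppressWarnings(pickSoftThreshold(eb, powers = c(1, 4, 8, 12)))
  expect_gt(max(sftB$fitIndices$r2), max(sft$fitIndices$r2))
})

test_that("adjacency is |cor|^power with safe zero-variance handling", {
  x <- c(1, 2, 3, 4, 5)
  expr <- rbind(a = x, b = 2 * x + 3, c = rev(x))
  a1 <- adjacencyMatrix(expr, 1)
  expect_equal(a1["a", "b"], 1)
  expect_equal(a1["a", "c"], 1)  # |cor| = 1 for reversed linear profile
  orth <- rbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_equal(adjacencyMatrix(orth, 3)["a", "b"], 0)
  set.seed(19)
  e2 <- matrix(rnorm(40), 4, 10, dimnames = list(letters[1:4], NULL))
  expect_equal(adjacencyMatrix(e2, 2), abs(stats::cor(t(e2)))^2,
               ignore_attr = TRUE)
  ez <- rbind(e2, flat = rep(1, 10))
  expect_warning(az <- adjacencyMatrix(ez, 2), "zero-variance")
  expect_equal(unname(az["flat", letters[1:4]]), rep(0, 4))
  expect_equal(az["flat", "flat"], 1)
})

test_that("TOM matches the hand example and a triple-loop oracle", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  tom <- tomSimilarity(a)
  expect_equal(tom[1, 2], 0.5, tolerance = 1e-12)  # (0.25+0.5)/(1+1-0.5)
  z <- diag(4)
  expect_equal(unname(tomSimilarity(z)[1, 2]), 0)
  bad <- a; bad[1, 2] <- 0.7
  expect_error(tomSimilarity(bad), "symmetric")
  set.seed(20)
  for (i in 1:5) {
    r <- matrix(runif(50 * 50), 50)
    r <- (r + t(r)) / 2
    diag(r) <- 1
    tom <- tomSimilarity(r)
    expect_equal(tom, bruteTOM(r), tolerance = 1e-10, ignore_attr = TRUE)
    expect_lt(max(abs(tom - t(tom))), 1e-10)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("module detection recovers planted blocks and greys out noise", {
  e <- blockExpr(nSamples = 40)
  tom <- tomSimilarity(adjacencyMatrix(e, 6))
  lab <- detectModules(tom, minModuleSize = 20)
  truthLab <- rep(c(1, 2, 0), c(30, 30, 40))
  blocks <- grepl("^b", rownames(e))
  expect_equal(adjustedRand(lab[blocks], truthLab[blocks]), 1)
  ## with 40 samples chance correlations are weak: noise stays grey
  expect_gte(mean(lab[!blocks] == 0), 0.9)
  ## permuting gene order permutes labels consistently
  perm <- sample(nrow(e))
  lab2 <- detectModules(tom[perm, perm], minModuleSize = 20)
  expect_equal(adjustedRand(lab2, lab[perm]), 1)
  ## fewer genes than the minimum size: everything grey, with a warning
  expect_warning(labSmall <- detectModules(tom[1:5, 1:5],
                                           minModuleSize = 20), "fewer")
  expect_true(all(labSmall == 0))
})

test_that("eigengenes are unit-norm first PCs oriented with the module", {
  e <- blockExpr(nNoise = 0)
  tom <- tomSimilarity(adjacencyMatrix(e, 6))
  lab <- detectModules(tom, minModuleSize = 20)
  eg <- moduleEigengenes(e, lab)
  expect_equal(unname(sqrt(rowSums(eg$eigengenes^2))),
               rep(1, nrow(eg$eigengenes)))
  ## power-iteration oracle, up to sign
  for (m in rownames(eg$eigengenes)) {
    genes <- names(lab)[lab == as.integer(sub("ME", "", m))]
    xs <- t(scale(t(e[genes, ])))
    pc <- brutePC1(xs)
    expect_gt(abs(stats::cor(eg$eigengenes[m, ], pc)), 1 - 1e-6)
  }
  ## identical genes: variance explained 1, eigengene follows the profile
  prof <- rnorm(12)
  idMod <- rbind(a = prof, b = prof, c = prof)
  labId <- stats::setNames(rep(1L, 3), rownames(idMod))
  egId <- moduleEigengenes(idMod, labId)
  expect_equal(unname(egId$varExplained), 1, tolerance = 1e-12)
  expect_gt(stats::cor(egId$eigengenes[1, ], prof), 1 - 1e-12)
  ## uniformly negated module is still positively oriented to its mean
  egNeg <- moduleEigengenes(-idMod, labId)
  xs <- t(scale(t(-idMod)))
  expect_gt(stats::cor(egNeg$eigengenes[1, ], colMeans(xs)), 0)
  ## single-gene module
  lab1 <- stats::setNames(c(1L, 0L), c("a", "b"))
  eg1 <- moduleEigengenes(idMod[1:2, ], lab1)
  expect_gt(abs(stats::cor(eg1$eigengenes[1, ], prof)), 1 - 1e-12)
})

test_that("module-trait p-values follow the t distribution exactly", {
  n <- 32
  z1 <- rep(c(1, -1), 16); z2 <- rep(c(1, 1, -1, -1), 8)
  eg <- matrix(z1, 1, n, dimnames = list("ME1", NULL))
  traits <- cbind(t06 = 0.6 * z1 + 0.8 * z2, orth = z2)
  mt <- moduleTraitCor(eg, traits)
  expect_equal(unname(mt$r[1, "t06"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(mt$r[1, "orth"]), 0, tolerance = 1e-12)
  expect_equal(unname(mt$p[1, "orth"]), 1, tolerance = 1e-12)
  ## quadrature oracle for r = 0.6, n = 30
  tt <- 0.6 * sqrt((n - 2) / (1 - 0.36))
  pOracle <- 2 * stats::integrate(function(x) stats::dt(x, df = n - 2),
                                  tt, Inf)$value
  expect_equal(unname(mt$p[1, "t06"]), pOracle, tolerance = 1e-6)
  ## eigengene equal to the trait
  mt2 <- moduleTraitCor(eg, cbind(self = z1))
  expect_equal(unname(mt2$r[1, 1]), 1)
  expect_lt(unname(mt2$p[1, 1]), 1e-12)
  ## constant trait flagged
  expect_warning(mt3 <- moduleTraitCor(eg, cbind(const = rep(1, n))),
                 "constant")
  expect_true(is.na(mt3$p[1, 1]))
})

test_that("hub calling by kME matches a brute-force oracle", {
  e <- blockExpr(nNoise = 10)
  tom <- tomSimilarity(adjacencyMatrix(e, 6))
  lab <- detectModules(tom, minModuleSize = 20)
  eg <- moduleEigengenes(e, lab)
  hubs <- hubGenes(e, lab, eg$eigengenes, kmeThreshold = 0.8)
  expect_identical(hubs, bruteHubs(e, lab, eg$eigengenes, 0.8))
  ## a gene identical to its eigengene is a hub; grey genes never are
  expect_true(all(!grepl("^n", unlist(hubs))))
  eSelf <- rbind(e, self = eg$eigengenes["ME1", ] * 5)
  labSelf <- c(lab, self = 1L)
  hubsSelf <- hubGenes(eSelf, labSelf, eg$eigengenes)
  expect_true("self" %in% hubsSelf$ME1)
})

test_that("runCoexpression ties the stages to the planted module", {
  sim <- simulatePlacodeData(smallSimParams())
  cd <- as.data.frame(SummarizedExperiment::colData(sim))
  rd <- SummarizedExperiment::rowData(sim)
  mrna <- rownames(sim)[rd$biotype == "mRNA"]
  sel <- cd$tissue == "skin" & cd$condition == "normal"
  cx <- suppressWarnings(
    runCoexpression(SummarizedExperiment::assay(sim)[mrna, sel],
                    stages = cd$stage[sel], minModuleSize = 15))
  tr <- plantedTruth(sim)
  lab <- moduleLabels(cx)
  ## each planted module lands coherently in one detected label, and that
  ## label is significantly associated with the module's planted stage
  for (m in tr$modules) {
    tt <- table(lab[m$genes])
    expect_gte(max(tt) / length(m$genes), 0.8)
    modLab <- names(tt)[which.max(tt)]
    expect_true(modLab != "0")
    p <- traitAssociation(cx)$p[paste0("ME", modLab), ]
    expect_lt(p[[m$stage]], 0.05)
  }
})
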