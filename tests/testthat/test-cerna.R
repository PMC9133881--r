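mkDe <- function(...) {
  x <- c(...)
  data.frame(feature = names(x), direction = unname(x),
             stringsAsFactors = FALSE)
}

mkEdges <- function(reg, tgt) {
  S4Vectors::DataFrame(regulator = reg, target = tgt,
                       mode = rep("seed", length(reg)))
}

test_that("tissue-specific sets exclude features DE anywhere else", {
  de <- list(skin = mkDe(A = "up", B = "down", C = "up"),
             heart = mkDe(B = "up"),
             liver = mkDe())
  s <- tissueSpecificSets(de, "skin")
  expect_setequal(s$feature, c("A", "C"))
  ## direction-agnostic: up in skin, down in heart -> excluded
  de2 <- list(skin = mkDe(X = "up"), heart = mkDe(X = "down"))
  expect_equal(nrow(tissueSpecificSets(de2, "skin")), 0)
  expect_error(tissueSpecificSets(list(), "skin"), "empty|not in")
})

test_that("tissue-specific sets equal a brute-force membership scan", {
  set.seed(15)
  tissues <- paste0("t", 1:5)
  for (i in 1:20) {
    de <- lapply(stats::setNames(tissues, tissues), function(t) {
      f <- sample(LETTERS, sample(0:10, 1))
      data.frame(feature = f,
                 direction = sample(c("up", "down"), length(f), TRUE),
                 stringsAsFactors = FALSE)
    })
    s <- tissueSpecificSets(de, "t3")
    manual <- de$t3$feature[vapply(de$t3$feature, function(f)
      !any(vapply(tissues[tissues != "t3"],
                  function(t) f %in% de[[t]]$feature, TRUE)), TRUE)]
    expect_setequal(s$feature, manual)
  }
})

test_that("overlapped genes need lncRNA, miRNA and specific-DE support", {
  lncE <- mkEdges(c("L1", "L1"), c("G1", "G2"))
  mirE <- mkEdges(c("M1", "M1"), c("G1", "G3"))
  out <- overlapTargets(c("G1", "G2", "G3"), lncE, mirE)
  expect_equal(out$gene, "G1")
  expect_equal(out$lncRegulators, "L1")
  expect_equal(out$mirRegulators, "M1")
  ## associativity of the triple intersection
  sets <- list(c("G1", "G2", "G3"), unique(lncE$target),
               unique(mirE$target))
  expect_setequal(out$gene,
                  Reduce(intersect, sets))
})

test_that("triples follow the two trend models exactly", {
  lm1 <- mkEdges("M1", "L1")
  mg1 <- mkEdges("M1", "G1")
  ## model1: lncRNA down | miRNA up | mRNA down
  t1 <- assembleTriples(mkDe(L1 = "down"), mkDe(M1 = "up"),
                        mkDe(G1 = "down"), lm1, mg1)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$model, "model1")
  ## model2: lncRNA up | miRNA down | mRNA up
  t2 <- assembleTriples(mkDe(L1 = "up"), mkDe(M1 = "down"),
                        mkDe(G1 = "up"), lm1, mg1)
  expect_equal(t2$model, "model2")
  ## no model matches
  t3 <- assembleTriples(mkDe(L1 = "up"), mkDe(M1 = "up"),
                        mkDe(G1 = "down"), lm1, mg1)
  expect_equal(nrow(t3), 0)
  ## a not-DE member simply yields no triple
  t4 <- assembleTriples(mkDe(), mkDe(M1 = "up"), mkDe(G1 = "down"),
                        lm1, mg1)
  expect_equal(nrow(t4), 0)
  ## missing either seed edge yields no triple
  t5 <- assembleTriples(mkDe(L1 = "down"), mkDe(M1 = "up"),
                        mkDe(G1 = "down"), mkEdges(character(0),
                                                   character(0)), mg1)
  expect_equal(nrow(t5), 0)
})

test_that("assembly equals exhaustive enumeration on random instances", {
  set.seed(16)
  for (i in 1:30) {
    nL <- sample(3:8, 1); nM <- sample(3:8, 1); nG <- sample(3:8, 1)
    lncDE <- data.frame(feature = paste0("L", 1:nL),
                        direction = sample(c("up", "down"), nL, TRUE))
    mirDE <- data.frame(feature = paste0("M", 1:nM),
                        direction = sample(c("up", "down"), nM, TRUE))
    mrnaDE <- data.frame(feature = paste0("G", 1:nG),
                         direction = sample(c("up", "down"), nG, TRUE))
    rndE <- function(from, to) {
      idx <- which(matrix(runif(length(from) * length(to)) < 0.4,
                          length(from)), arr.ind = TRUE)
      S4Vectors::DataFrame(regulator = from[idx[, 1]], target = to[idx[, 2]],
                           mode = "seed")
    }
    lm <- rndE(mirDE$feature, lncDE$feature)
    mg <- rndE(mirDE$feature, mrnaDE$feature)
    lg <- rndE(lncDE$feature, mrnaDE$feature)
    for (strict in c(FALSE, TRUE)) {
      got <- assembleTriples(lncDE, mirDE, mrnaDE, lm, mg, lg,
                             requireLncMrnaEdge = strict)
      exp <- bruteTriples(lncDE, mirDE, mrnaDE, lm, mg, lg, strict)
      expect_equal(as.data.frame(got)[, c("lncRNA", "miRNA", "mRNA",
                                          "model")],
                   exp, ignore_attr = TRUE)
    }
  }
})

test_that("assembly is invariant to input order and duplicate rows", {
  lncDE <- mkDe(L1 = "down", L2 = "up")
  mirDE <- mkDe(M1 = "up", M2 = "down")
  mrnaDE <- mkDe(G1 = "down", G2 = "up")
  lm <- mkEdges(c("M1", "M2"), c("L1", "L2"))
  mg <- mkEdges(c("M1", "M2"), c("G1", "G2"))
  base <- assembleTriples(lncDE, mirDE, mrnaDE, lm, mg)
  shuf <- assembleTriples(lncDE[2:1, ], mirDE[2:1, ], mrnaDE[2:1, ],
                          lm[c(2, 1, 1), ], mg[c(1, 1, 2), ])
  expect_identical(as.data.frame(base), as.data.frame(shuf))
  ## every emitted triple satisfies its model signature (post-hoc check)
  dirs <- c(L1 = "down", L2 = "up", M1 = "up", M2 = "down",
            G1 = "down", G2 = "up")
  models <- list(model1 = c("down", "up", "down"),
                 model2 = c("up", "down", "up"))
  for (i in seq_len(nrow(base)))
    expect_equal(unname(dirs[c(base$lncRNA[i], base$miRNA[i],
                               base$mRNA[i])]),
                 models[[base$model[i]]])
})

mkCoexpr <- function(traitP, hubs) {
  nmod <- nrow(traitP)
  eg <- diag(nmod)
  eg <- eg / sqrt(rowSums(eg^2))
  rownames(eg) <- rownames(traitP)
  new("CoexprResult", power = 6L,
      fitIndices = data.frame(power = 6, r2 = 0.9, meanK = 1),
      labels = stats::setNames(rep(seq_len(nmod), each = 2),
                               paste0("g", seq_len(2 * nmod))),
      eigengenes = eg, varExplained = rep(1, nmod),
      traitCor = traitP * 0, traitP = traitP, hubs = hubs,
      params = list())
}

test_that("prioritization keeps mRNAs that are hubs of significant modules", {
  triples <- S4Vectors::DataFrame(
    lncRNA = c("L1", "L2", "L3"), miRNA = c("M1", "M2", "M3"),
    mRNA = c("G1", "G2", "G3"), model = "model1",
    hasLncMrnaEdge = TRUE)
  traitP <- matrix(c(4e-04, 0.03, 0.2, 0.7, 0.5, 0.5), nrow = 3,
                   dimnames = list(c("ME1", "ME2", "ME3"),
                                   c("E41", "E45")))
  hubs <- list(ME1 = c("G1"), ME2 = c("G2"), ME3 = c("G3"))
  cx <- mkCoexpr(traitP, hubs)
  kept <- prioritizeTriples(triples, cx, "E41")
  expect_setequal(kept$mRNA, c("G1", "G2"))  # ME3 p = 0.2 not significant
  ## boundary: p exactly 0.05 is not significant
  traitP2 <- traitP; traitP2["ME1", "E41"] <- 0.05
  kept2 <- prioritizeTriples(triples, mkCoexpr(traitP2, hubs), "E41")
  expect_setequal(kept2$mRNA, "G2")
  ## no significant module: warning and empty result
  traitP3 <- traitP; traitP3[, "E41"] <- 0.5
  expect_warning(none <- prioritizeTriples(triples,
                                           mkCoexpr(traitP3, hubs), "E41"),
                 "no module")
  expect_equal(nrow(none), 0)
})
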