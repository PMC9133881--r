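## Independent brute-force oracles used to cross-check the package
## implementations. These deliberately use the most literal formulation of
## each definition and share no code with the package internals.

## Benjamini-Hochberg step-up, computed literally from the definition
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

## all-pairs cis scan on 1-based inclusive intervals
bruteCis <- function(lncDf, geneDf, window) {
  out <- list()
  for (i in seq_len(nrow(lncDf))) for (j in seq_len(nrow(geneDf))) {
    if (lncDf$chrom[i] != geneDf$chrom[j]) next
    gap <- max(0L, max(lncDf$start[i], geneDf$start[j]) -
                 min(lncDf$end[i], geneDf$end[j]) - 1L)
    if (gap <= window && lncDf$id[i] != geneDf$id[j])
      out[[length(out) + 1L]] <- data.frame(regulator = lncDf$id[i],
                                            target = geneDf$id[j], gap = gap)
  }
  if (!length(out)) return(data.frame(regulator = character(0),
                                      target = character(0), gap = integer(0)))
  do.call(rbind, out)
}

## literal triple-loop TOM
bruteTOM <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- sum(a[i, ] * a[, j]) - a[i, i] * a[i, j] - a[i, j] * a[j, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

## kME hub calling from the definition
bruteHubs <- function(expr, labels, eigengenes, thr) {
  out <- list()
  for (m in sort(unique(labels[labels != 0]))) {
    genes <- names(labels)[labels == m]
    hubs <- character(0)
    for (g in genes) {
      kme <- stats::cor(expr[g, ], eigengenes[paste0("ME", m), ])
      if (!is.na(kme) && abs(kme) >= thr) hubs <- c(hubs, g)
    }
    out[[paste0("ME", m)]] <- hubs
  }
  out
}

## exhaustive trend-model triple enumeration
bruteTriples <- function(lncDE, mirDE, mrnaDE, lncMir, mirMrna,
                         lncMrna = NULL, strict = FALSE) {
  models <- list(model1 = c("down", "up", "down"),
                 model2 = c("up", "down", "up"))
  ek <- function(e) paste(e$regulator, e$target)
  out <- list()
  for (i in seq_len(nrow(lncDE))) for (j in seq_len(nrow(mirDE)))
    for (k in seq_len(nrow(mrnaDE))) {
      L <- lncDE$feature[i]; M <- mirDE$feature[j]; G <- mrnaDE$feature[k]
      if (!paste(M, L) %in% ek(lncMir)) next
      if (!paste(M, G) %in% ek(mirMrna)) next
      sig <- c(lncDE$direction[i], mirDE$direction[j], mrnaDE$direction[k])
      mdl <- names(models)[vapply(models, function(x) all(x == sig), TRUE)]
      if (!length(mdl)) next
      if (strict && !(paste(L, G) %in% ek(lncMrna))) next
      out[[length(out) + 1L]] <- data.frame(lncRNA = L, miRNA = M, mRNA = G,
                                            model = mdl[1])
    }
  if (!length(out)) return(data.frame(lncRNA = character(0),
                                      miRNA = character(0),
                                      mRNA = character(0),
                                      model = character(0)))
  df <- unique(do.call(rbind, out))
  df[order(df$lncRNA, df$miRNA, df$mRNA), , drop = FALSE]
}

## power-iteration first principal component (independent of svd)
brutePC1 <- function(xs, iter = 500) {
  cc <- crossprod(xs) # samples x samples
  v <- rep(1, ncol(cc))
  for (i in seq_len(iter)) {
    v <- cc %*% v
    v <- v / sqrt(sum(v^2))
  }
  as.numeric(v)
}

## small helper: simulate an NB count matrix with per-sample factors
nbCounts <- function(n, mu, disp, sf, nGroups = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cts <- t(sapply(mu, function(m)
    stats::rnbinom(length(sf), mu = m * sf, size = 1 / disp)))
  rownames(cts) <- sprintf("g%05d", seq_len(n))
  colnames(cts) <- sprintf("s%02d", seq_along(sf))
  cts
}

## small simulated experiment shared across tests (built once per run)
smallSimParams <- function(seed = 7) {
  simParams(nMrna = 300, nLnc = 40, nMir = 12, nTriples = 3,
            nDecoyTriples = 2, moduleSizes = c(25, 25), seed = seed)
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

## two latent-factor blocks plus independent noise genes
blockExpr <- function(nBlock = 30, nNoise = 40, nSamples = 20, seed = 1) {
  set.seed(seed)
  z1 <- stats::rnorm(nSamples); z2 <- stats::rnorm(nSamples)
  e <- rbind(
    t(sapply(seq_len(nBlock), function(i)
      2 * z1 + stats::rnorm(nSamples, 0, 0.7))),
    t(sapply(seq_len(nBlock), function(i)
      2 * z2 + stats::rnorm(nSamples, 0, 0.7))))
  if (nNoise > 0)
    e <- rbind(e, matrix(stats::rnorm(nNoise * nSamples), nNoise))
  rownames(e) <- c(paste0("b1_", seq_len(nBlock)),
                   paste0("b2_", seq_len(nBlock)),
                   if (nNoise > 0) paste0("n", seq_len(nNoise)))
  e
}
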