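#' Variance-stabilizing log transform
#'
#' `log2(count / sizeFactor + 1)`: a simplified variance-stabilizing
#' transform, monotone in counts, used as the expression scale for
#' co-expression and trans-target analysis.
#'
#' @param counts genes x samples count matrix (non-negative).
#' @param factors positive size factors.
#' @return Numeric matrix on the log2 scale.
#' @export
#' @examples
#' vstTransform(matrix(c(0, 1023), 1), factors = c(1, 1))  # 0 and 10
vstTransform <- function(counts, factors = rep(1, ncol(counts))) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(factors <= 0)) stop("size factors must be positive")
  log2(sweep(counts, 2, factors, `/`) + 1)
}

#' Sum-count gene filter
#'
#' Keeps genes whose total count across samples is strictly greater than
#' `minSumCounts`.
#'
#' @param counts genes x samples count matrix.
#' @param minSumCounts threshold (default 10, strict).
#' @return Character vector of retained gene ids (or row indices when
#'   unnamed).
#' @export
filterGenesBySum <- function(counts, minSumCounts = 10) {
  keep <- rowSums(as.matrix(counts)) > minSumCounts
  if (!is.null(rownames(counts))) rownames(counts)[keep] else which(keep)
}

#' Scale-free topology fit
#'
#' Bins `log10(k)` of a connectivity vector into `nBins` equal-width bins,
#' and returns the R-squared of the regression of log10 bin frequency on
#' log10 mean bin connectivity — high when the degree distribution follows a
#' power law.
#'
#' @param k non-negative connectivity vector.
#' @param nBins number of bins (default 10).
#' @return R-squared in `[0, 1]`.
#' @export
scaleFreeFitR2 <- function(k, nBins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2L)
    stop("degenerate connectivity: the degree distribution is single-valued")
  lk <- log10(k)
  br <- seq(min(lk), max(lk), length.out = nBins + 1L)
  bin <- cut(lk, br, include.lowest = TRUE)
  freq <- tapply(lk, bin, length)
  meanK <- tapply(k, bin, mean)
  use <- !is.na(freq) & freq > 0
  if (sum(use) < 3L) return(0)
  fit <- stats::lm(log10(freq[use]) ~ log10(meanK[use]))
  summary(fit)$r.squared
}

#' Soft-threshold selection helper
#'
#' Given candidate powers and their scale-free fit R-squared values, returns
#' the smallest power whose fit reaches `r2Target`, or the power with the
#' best fit when none does.
#'
#' @param powers integer vector of candidate powers.
#' @param r2 matching R-squared values.
#' @param r2Target target fit (default 0.8).
#' @return The chosen power.
#' @export
#' @examples
#' chooseSoftPower(c(4, 10, 12), c(0.5, 0.82, 0.9))  # 10
chooseSoftPower <- function(powers, r2, r2Target = 0.8) {
  ok <- which(r2 >= r2Target)
  if (length(ok)) powers[min(ok)] else powers[which.max(r2)]
}

#' Soft-threshold power by scale-free fit
#'
#' For each candidate power, forms the unsigned adjacency
#' `|cor|^power`, computes connectivities, and evaluates the scale-free
#' topology fit; the chosen power is the smallest reaching `r2Target`
#' (otherwise the best-fitting one).
#'
#' @param expr genes x samples expression matrix (log scale).
#' @param powers candidate powers (default 1:20).
#' @param r2Target scale-free fit target (default 0.8).
#' @return list with `power` and `fitIndices` (data.frame: `power`, `r2`,
#'   `meanK`).
#' @export
pickSoftThreshold <- function(expr, powers = 1:20, r2Target = 0.8) {
  stopifnot(all(powers >= 1))
  if (ncol(expr) < 8L)
    warning("fewer than 8 samples: scale-free fit is unstable")
  corAbs <- abs(stats::cor(t(expr)))
  corAbs[is.na(corAbs)] <- 0
  fit <- data.frame(power = powers, r2 = NA_real_, meanK = NA_real_)
  for (i in seq_along(powers)) {
    a <- corAbs^powers[i]
    k <- rowSums(a) - 1
    fit$meanK[i] <- mean(k)
    fit$r2[i] <- scaleFreeFitR2(k)
  }
  list(power = chooseSoftPower(fit$power, fit$r2, r2Target), fitIndices = fit)
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^power` with unit diagonal. Zero-variance genes get
#' zero off-diagonal entries, with a warning.
#'
#' @param expr genes x samples expression matrix.
#' @param power soft-thresholding power (>= 1).
#' @return Symmetric matrix with entries in `[0, 1]`.
#' @export
adjacencyMatrix <- function(expr, power) {
  stopifnot(power >= 1)
  expr <- as.matrix(expr)
  zv <- apply(expr, 1, stats::sd) == 0
  a <- abs(suppressWarnings(stats::cor(t(expr))))^power
  a[is.na(a)] <- 0
  if (any(zv)) {
    warning("zero-variance genes get zero adjacency: ",
            paste(rownames(expr)[zv], collapse = ", "))
    a[zv, ] <- 0
    a[, zv] <- 0
  }
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{u != i} a_iu` (diagonal excluded from all sums) and
#' `TOM_ii = 1`.
#'
#' @param adjacency symmetric adjacency matrix in `[0, 1]`.
#' @param tol asymmetry tolerance (default 1e-8).
#' @return Symmetric TOM matrix with values in `[0, 1]`.
#' @export
tomSimilarity <- function(adjacency, tol = 1e-8) {
  a <- as.matrix(adjacency)
  if (max(abs(a - t(a))) > tol) stop("adjacency must be symmetric")
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Module detection by static tree cut
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a fixed
#' height (default: 0.98 of the highest merge, just below the
#' dendrogram top; average-linkage TOM merge heights pile up near the
#' maximum, so a cut slightly below it separates coherent modules from the
#' background chaining). Clusters
#' smaller than `minModuleSize` are assigned label 0 (grey); remaining
#' modules are renumbered by decreasing size. Deterministic given the input.
#'
#' @param tom TOM matrix from [tomSimilarity()].
#' @param minModuleSize minimum module size (default 30).
#' @param cutHeight cut height on the dissimilarity scale; `NULL` for the
#'   default just below the dendrogram top.
#' @return Named integer vector of module labels (0 = unassigned).
#' @export
detectModules <- function(tom, minModuleSize = 30, cutHeight = NULL) {
  n <- nrow(tom)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- as.character(seq_len(n))
  if (n < minModuleSize) {
    warning("fewer genes than minModuleSize: all genes unassigned")
    return(stats::setNames(rep(0L, n), genes))
  }
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  if (is.null(cutHeight))
    cutHeight <- 0.98 * max(h$height)
  cl <- stats::cutree(h, h = cutHeight)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= minModuleSize]
  lab <- ifelse(cl %in% as.integer(keep), cl, 0L)
  ord <- names(sort(table(lab[lab != 0]), decreasing = TRUE))
  relab <- stats::setNames(seq_along(ord), ord)
  out <- ifelse(lab == 0L, 0L, relab[as.character(lab)])
  stats::setNames(as.integer(out), genes)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression (unit norm over samples), sign-oriented to
#' correlate positively with the module's mean expression profile. A
#' single-gene module's eigengene is that gene's standardized profile.
#'
#' @param expr genes x samples expression matrix.
#' @param labels module labels as from [detectModules()] (0 is skipped).
#' @return list with `eigengenes` (modules x samples matrix, rows `ME<k>`)
#'   and `varExplained`.
#' @export
moduleEigengenes <- function(expr, labels) {
  expr <- as.matrix(expr)
  mods <- sort(unique(labels[labels != 0]))
  if (!length(mods)) stop("no non-grey module")
  eg <- matrix(NA_real_, length(mods), ncol(expr),
               dimnames = list(paste0("ME", mods), colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), rownames(eg))
  for (i in seq_along(mods)) {
    genes <- names(labels)[labels == mods[i]]
    x <- expr[genes, , drop = FALSE]
    xs <- t(scale(t(x)))
    xs[!is.finite(xs)] <- 0
    sv <- svd(xs)
    v <- sv$v[, 1]
    v <- v / sqrt(sum(v^2))
    meanProf <- colMeans(xs)
    if (stats::cor(v, meanProf) < 0) v <- -v
    eg[i, ] <- v
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = eg, varExplained = ve)
}

#' Module-trait association
#'
#' Pearson correlation of each module eigengene with each trait column
#' (e.g. binary stage indicators), with a two-sided Student p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Constant traits give `NA` with a warning.
#'
#' @param eigengenes modules x samples matrix from [moduleEigengenes()].
#' @param traits samples x traits numeric matrix (>= 3 samples).
#' @return list with matrices `r` and `p` (modules x traits).
#' @export
moduleTraitCor <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  n <- ncol(eigengenes)
  if (n < 3L) stop("need >= 3 samples")
  if (nrow(traits) != n) stop("traits must have one row per sample")
  const <- apply(traits, 2, stats::sd) == 0
  if (any(const))
    warning("constant traits give undefined correlation: ",
            paste(colnames(traits)[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(t(eigengenes), traits))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  p[, const] <- NA_real_
  r[, const] <- NA_real_
  list(r = r, p = p)
}

#' Hub genes by module membership (kME)
#'
#' A gene is a hub of its module when the absolute correlation of its profile
#' with the module eigengene (kME) is at least `kmeThreshold`. Unassigned
#' (grey) genes are never hubs.
#'
#' @param expr genes x samples expression matrix.
#' @param labels module labels.
#' @param eigengenes modules x samples matrix.
#' @param kmeThreshold kME threshold (default 0.8).
#' @return Named list of character vectors, one per module (`ME<k>`).
#' @export
hubGenes <- function(expr, labels, eigengenes, kmeThreshold = 0.8) {
  mods <- sort(unique(labels[labels != 0]))
  out <- stats::setNames(vector("list", length(mods)),
                         paste0("ME", mods))
  for (m in mods) {
    genes <- names(labels)[labels == m]
    e <- eigengenes[paste0("ME", m), ]
    kme <- suppressWarnings(
      stats::cor(t(expr[genes, , drop = FALSE]), e))[, 1]
    kme[is.na(kme)] <- 0
    out[[paste0("ME", m)]] <- genes[abs(kme) >= kmeThreshold]
  }
  out
}

#' Weighted co-expression analysis
#'
#' The full co-expression core: sum-count gene filter, variance-stabilizing
#' log transform, soft-threshold selection by scale-free fit, unsigned
#' adjacency, topological overlap, static-cut module detection, eigengenes,
#' module-trait association against stage indicators, and kME hub calling.
#'
#' @param counts genes x samples count matrix.
#' @param stages per-sample stage labels (turned into binary indicators).
#' @param factors size factors; computed by [sizeFactorsMoR()] when `NULL`.
#' @param minSumCounts sum-count filter threshold (default 10).
#' @param powers,r2Target soft-threshold candidates and fit target.
#' @param minModuleSize,cutHeight module detection parameters.
#' @param kmeThreshold hub kME threshold (default 0.8).
#' @return A [CoexprResult].
#' @export
runCoexpression <- function(counts, stages, factors = NULL,
                            minSumCounts = 10, powers = 1:20,
                            r2Target = 0.8, minModuleSize = 30,
                            cutHeight = NULL, kmeThreshold = 0.8) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- sizeFactorsMoR(counts)
  keep <- filterGenesBySum(counts, minSumCounts)
  expr <- vstTransform(counts[keep, , drop = FALSE], factors)
  sft <- pickSoftThreshold(expr, powers, r2Target)
  adj <- adjacencyMatrix(expr, sft$power)
  tom <- tomSimilarity(adj)
  labels <- detectModules(tom, minModuleSize, cutHeight)
  eg <- moduleEigengenes(expr, labels)
  traits <- stats::model.matrix(~ 0 + factor(stages))
  colnames(traits) <- levels(factor(stages))
  mt <- moduleTraitCor(eg$eigengenes, traits)
  hubs <- hubGenes(expr, labels, eg$eigengenes, kmeThreshold)
  methods::new("CoexprResult", power = as.integer(sft$power),
               fitIndices = sft$fitIndices, labels = labels,
               eigengenes = eg$eigengenes, varExplained = eg$varExplained,
               traitCor = mt$r, traitP = mt$p, hubs = hubs,
               params = list(minSumCounts = minSumCounts,
                             r2Target = r2Target,
                             minModuleSize = minModuleSize,
                             cutHeight = cutHeight,
                             kmeThreshold = kmeThreshold))
}
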