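#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: each sample's factor is the median,
#' over genes with a positive geometric mean across samples, of the ratio of
#' the sample's count to that gene's geometric-mean pseudo-reference.
#'
#' @param counts non-negative numeric matrix, genes x samples.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
#' @examples
#' m <- rbind(g1 = c(100, 200), g2 = c(10, 20))
#' colnames(m) <- c("s1", "s2")
#' sizeFactorsMoR(m)  # 0.7071 1.4142
sizeFactorsMoR <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use))
    stop("no gene has nonzero counts in every sample; ",
         "a pseudo-reference fallback is not applied silently")
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt)
    exp(stats::median(log(cnt) - logGeo[use])))
  if (is.null(names(sf)) && !is.null(colnames(counts)))
    names(sf) <- colnames(counts)
  sf
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments dispersions from normalized counts, shrunk 50/50 toward a
#' mean-dispersion trend `alpha(mu) = a0 + a1/mu` fitted across genes by least
#' squares on the natural scale, with a floor of `1e-8`. The moment estimator
#' uses `Var(q) = mu * E(1/s) + alpha * mu^2` on counts normalized by size
#' factors `s`, with a pooled within-group variance. The trend is fitted on
#' the untruncated moment estimates (negative values included) so it is
#' centred on the true dispersion rather than on a selection- or log-scale-
#' biased value; gene-wise estimates are truncated at zero before shrinkage,
#' so variance-below-mean genes (Poisson-like or constant) inherit half the
#' trend value, and a fully Poisson-like matrix drives the trend itself to
#' the floor.
#'
#' @param counts genes x samples count matrix.
#' @param factors size factors from [sizeFactorsMoR()].
#' @param groups two-level factor or character vector over samples.
#' @param floor minimum dispersion.
#' @param shrink weight on the gene-wise moment estimate (the trend gets
#'   `1 - shrink`).
#' @return Named numeric vector of dispersions (>= `floor`).
#' @export
estimateDispersionsMoM <- function(counts, factors, groups,
                                   floor = 1e-8, shrink = 0.5) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab < 2L))
    stop("each group needs >= 2 replicates to estimate dispersion")
  q <- sweep(counts, 2, factors, `/`)
  baseMean <- rowMeans(q)
  grpIdx <- split(seq_along(groups), groups)
  ss <- rowSums(do.call(cbind, lapply(grpIdx, function(j) {
    m <- rowMeans(q[, j, drop = FALSE])
    rowSums((q[, j, drop = FALSE] - m)^2)
  })))
  v <- ss / (length(groups) - length(grpIdx))
  c1 <- mean(1 / factors)
  alphaRaw <- ifelse(baseMean > 0, (v - baseMean * c1) / baseMean^2, 0)
  use <- is.finite(alphaRaw) & baseMean > 0
  if (sum(use) >= 5L) {
    fit <- stats::lm(alphaRaw[use] ~ I(1 / baseMean[use]))
    trend <- (cbind(1, 1 / pmax(baseMean, 1e-8)) %*% stats::coef(fit))[, 1]
    trend <- pmin(pmax(trend, floor), 10)
  } else {
    trend <- rep(floor, length(alphaRaw))
  }
  disp <- pmax(floor, shrink * pmax(alphaRaw, 0) + (1 - shrink) * trend)
  stats::setNames(disp, rownames(counts))
}

#' Negative-binomial Wald test for a two-group comparison
#'
#' For each gene, the log2 fold change of normalized group means (pseudocount
#' 0.5), a delta-method standard error from the NB variance
#' `mu/s + alpha * mu^2`, the Wald statistic and a two-sided normal p-value.
#' The first level of `condition` (or `reference`) is the baseline, so
#' positive log2 fold changes mean higher expression in the other group.
#' All-zero genes are flagged degenerate with `log2FC = 0`, `p = 1`.
#'
#' @param counts genes x samples count matrix.
#' @param factors size factors.
#' @param dispersions per-gene dispersions.
#' @param condition two-level factor/character vector over samples.
#' @param reference baseline level; default the first level.
#' @param pseudocount added to group means before the log-ratio (default 0.5).
#' @return A [S4Vectors::DataFrame] with columns `feature`, `baseMean`,
#'   `log2FC`, `SE`, `stat`, `p`, `degenerate`.
#' @export
waldTestNB <- function(counts, factors, dispersions, condition,
                       reference = NULL, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  lev <- unique(condition)
  if (length(lev) != 2L) stop("condition must have exactly two levels")
  if (is.null(reference)) reference <- lev[1]
  other <- setdiff(lev, reference)
  if (any(table(condition) < 2L)) stop("each group needs >= 2 samples")
  q <- sweep(counts, 2, factors, `/`)
  j0 <- condition == reference
  j1 <- !j0
  m0 <- rowMeans(q[, j0, drop = FALSE])
  m1 <- rowMeans(q[, j1, drop = FALSE])
  n0 <- sum(j0); n1 <- sum(j1)
  lfc <- log2((m1 + pseudocount) / (m0 + pseudocount))
  v0 <- (m0 * sum(1 / factors[j0])) / n0^2 + dispersions * m0^2 / n0
  v1 <- (m1 * sum(1 / factors[j1])) / n1^2 + dispersions * m1^2 / n1
  se <- sqrt(v0 / (m0 + pseudocount)^2 + v1 / (m1 + pseudocount)^2) / log(2)
  degenerate <- m0 == 0 & m1 == 0
  stat <- ifelse(degenerate | se == 0, 0, lfc / se)
  p <- 2 * stats::pnorm(-abs(stat))
  lfc[degenerate] <- 0
  p[degenerate] <- 1
  S4Vectors::DataFrame(feature = rownames(counts),
                       baseMean = unname(rowMeans(q)), log2FC = unname(lfc),
                       SE = unname(se), stat = unname(stat), p = unname(p),
                       degenerate = unname(degenerate))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rates: monotone in p-rank, at least as large as the
#' raw p-value, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NA`/`NaN` are an error.
#' @return Numeric vector of FDR values.
#' @export
#' @examples
#' adjustBH(c(0.002, 0.01, 0.03, 0.04))  # 0.008 0.020 0.040 0.040
adjustBH <- function(p) {
  if (any(!is.finite(p))) stop("p-values must be finite (no NA/NaN)")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Threshold DE calls
#'
#' Applies the strict thresholds FDR < `fdrThreshold` and
#' |log2FC| > `lfcThreshold`: a feature is `up` when both hold with a positive
#' log2 fold change, `down` with a negative one, otherwise `not-DE`.
#'
#' @param results a DataFrame/data.frame with columns `log2FC` and `fdr` (an
#'   `fdr` column is added from `p` via [adjustBH()] if missing).
#' @param fdrThreshold,lfcThreshold strictly positive thresholds
#'   (defaults 0.05 and 1).
#' @return The input with `fdr` and `call` columns; calls are `up`, `down` or
#'   `not-DE`.
#' @export
callDE <- function(results, fdrThreshold = 0.05, lfcThreshold = 1) {
  stopifnot(fdrThreshold > 0, lfcThreshold > 0)
  if (!"fdr" %in% colnames(results)) results$fdr <- adjustBH(results$p)
  results$call <- ifelse(results$fdr < fdrThreshold &
                           results$log2FC > lfcThreshold, "up",
                  ifelse(results$fdr < fdrThreshold &
                           results$log2FC < -lfcThreshold, "down", "not-DE"))
  results
}

#' One-call differential expression pipeline
#'
#' Size factors, dispersion estimation, NB Wald test, BH-FDR and threshold
#' calls in one step.
#'
#' @inheritParams waldTestNB
#' @inheritParams callDE
#' @return A [S4Vectors::DataFrame] as from [waldTestNB()] with `fdr` and
#'   `call` columns.
#' @export
runDE <- function(counts, condition, reference = NULL,
                  fdrThreshold = 0.05, lfcThreshold = 1) {
  sf <- sizeFactorsMoR(counts)
  disp <- estimateDispersionsMoM(counts, sf, condition)
  res <- waldTestNB(counts, sf, disp, condition, reference = reference)
  callDE(res, fdrThreshold = fdrThreshold, lfcThreshold = lfcThreshold)
}

#' Directed DE feature sets
#'
#' @param results output of [callDE()] or [runDE()].
#' @return data.frame with columns `feature`, `direction` (`up`/`down`) for
#'   called features only.
#' @export
deSet <- function(results) {
  keep <- results$call != "not-DE"
  data.frame(feature = results$feature[keep],
             direction = results$call[keep], stringsAsFactors = FALSE)
}
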