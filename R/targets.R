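#' Cis lncRNA targets within a genomic window
#'
#' A lncRNA is a cis regulator of a gene when both lie on the same chromosome
#' and the gap between their closest transcript boundaries (0 when they
#' overlap) is at most `window`. Strand is ignored.
#'
#' @param lnc,genes named [GenomicRanges::GRanges] of lncRNA and gene loci.
#' @param window maximum gap in bp (default 100,000).
#' @return A [S4Vectors::DataFrame] with columns `regulator`, `target`,
#'   `mode = "cis"`, `gap`.
#' @export
cisTargets <- function(lnc, genes, window = 100000) {
  stopifnot(window > 0)
  if (is.null(names(lnc)) || is.null(names(genes)))
    stop("lnc and genes must be named GRanges")
  hits <- GenomicRanges::findOverlaps(lnc, genes, maxgap = window,
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  gap <- GenomicRanges::distance(lnc[q], genes[s], ignore.strand = TRUE)
  keep <- !is.na(gap) & gap <= window & names(lnc)[q] != names(genes)[s]
  S4Vectors::DataFrame(regulator = names(lnc)[q][keep],
                       target = names(genes)[s][keep],
                       mode = if (any(keep)) "cis" else character(0),
                       gap = gap[keep])
}

#' Trans lncRNA targets by expression correlation
#'
#' A lncRNA is a trans regulator of a gene when the Pearson correlation of
#' their expression profiles satisfies `|r| >= rThreshold` (both the positive
#' and the negative branch qualify). Zero-variance profiles yield no edges,
#' with a warning.
#'
#' @param lncExpr,geneExpr numeric matrices (features x samples) on the
#'   variance-stabilized/log scale, with matching sample columns (>= 3).
#' @param rThreshold correlation threshold in `(0, 1]` (default 0.95).
#' @return A [S4Vectors::DataFrame] with columns `regulator`, `target`,
#'   `mode = "trans"`, `r` (signed).
#' @export
transTargets <- function(lncExpr, geneExpr, rThreshold = 0.95) {
  stopifnot(rThreshold > 0, rThreshold <= 1)
  lncExpr <- as.matrix(lncExpr); geneExpr <- as.matrix(geneExpr)
  if (ncol(lncExpr) < 3L) stop("need >= 3 paired samples")
  v1 <- apply(lncExpr, 1, stats::sd) == 0
  v2 <- apply(geneExpr, 1, stats::sd) == 0
  if (any(v1) || any(v2))
    warning("zero-variance profiles excluded (correlation undefined): ",
            paste(c(rownames(lncExpr)[v1], rownames(geneExpr)[v2]),
                  collapse = ", "))
  lncExpr <- lncExpr[!v1, , drop = FALSE]
  geneExpr <- geneExpr[!v2, , drop = FALSE]
  if (!nrow(lncExpr) || !nrow(geneExpr))
    return(S4Vectors::DataFrame(regulator = character(0),
                                target = character(0),
                                mode = character(0), r = numeric(0)))
  r <- stats::cor(t(lncExpr), t(geneExpr))
  idx <- which(abs(r) >= rThreshold, arr.ind = TRUE)
  idx <- idx[rownames(lncExpr)[idx[, 1]] != rownames(geneExpr)[idx[, 2]], ,
             drop = FALSE]
  S4Vectors::DataFrame(regulator = rownames(lncExpr)[idx[, 1]],
                       target = rownames(geneExpr)[idx[, 2]],
                       mode = if (nrow(idx)) "trans" else character(0),
                       r = r[idx])
}

#' miRNA seed-match targets
#'
#' A miRNA targets a transcript when the exact reverse complement of its seed
#' (miRNA positions `seedStart`-`seedEnd`, default nucleotides 2-8) occurs at
#' least once in the transcript sequence. All site positions are reported as
#' 0-based starts on the target.
#'
#' @param mirSeqs named [Biostrings::DNAStringSet]/[Biostrings::RNAStringSet]
#'   or character vector of mature miRNA sequences (U/T interchangeable).
#' @param targetSeqs named set/vector of target transcript sequences.
#' @param seedStart,seedEnd seed span on the miRNA, 1-based inclusive
#'   (defaults 2 and 8).
#' @return A [S4Vectors::DataFrame] with columns `regulator`, `target`,
#'   `mode = "seed"`, `nSites` and `siteStarts` (an
#'   [IRanges::IntegerList] of 0-based site starts).
#' @export
seedTargets <- function(mirSeqs, targetSeqs, seedStart = 2, seedEnd = 8) {
  stopifnot(seedStart >= 1, seedEnd > seedStart)
  if (seedEnd - seedStart + 1 < 7)
    stop("seed region shorter than 7 nt")
  toDNA <- function(x) {
    if (methods::is(x, "XStringSet")) x <- as.character(x)
    Biostrings::DNAStringSet(chartr("Uu", "Tt", toupper(x)))
  }
  mir <- toDNA(mirSeqs)
  tg <- toDNA(targetSeqs)
  if (any(Biostrings::width(tg) == 0)) stop("empty target sequence")
  if (any(Biostrings::width(mir) < seedEnd))
    stop("miRNA shorter than the seed span")
  if (is.null(names(mir)) || is.null(names(tg)))
    stop("sequences must be named")
  rows <- list()
  for (m in names(mir)) {
    seed <- Biostrings::subseq(mir[[m]], seedStart, seedEnd)
    site <- Biostrings::reverseComplement(seed)
    hits <- Biostrings::vmatchPattern(site, tg)
    n <- S4Vectors::elementNROWS(hits)
    hit <- which(n > 0)
    if (!length(hit)) next
    starts <- IRanges::IntegerList(lapply(hit, function(i)
      BiocGenerics::start(hits[[i]]) - 1L))
    rows[[m]] <- S4Vectors::DataFrame(regulator = m,
                                      target = names(tg)[hit],
                                      mode = "seed", nSites = n[hit],
                                      siteStarts = starts)
  }
  if (!length(rows))
    return(S4Vectors::DataFrame(regulator = character(0),
                                target = character(0), mode = character(0),
                                nSites = integer(0),
                                siteStarts = IRanges::IntegerList()))
  do.call(rbind, unname(rows))
}

#' Intersect edge sets across predictors
#'
#' Keeps only (regulator, target) pairs present in every input set, mirroring
#' the multi-tool overlap used for target prediction. Evidence columns of all
#' sets are merged; on a name clash later sets get a positional suffix.
#'
#' @param edgeSets a non-empty list of edge DataFrames (each with `regulator`
#'   and `target` columns).
#' @return A [S4Vectors::DataFrame] of the common edges.
#' @export
intersectEdges <- function(edgeSets) {
  if (!length(edgeSets)) stop("need at least one edge set")
  keyOf <- function(e) paste(e$regulator, e$target, sep = "\r")
  keys <- Reduce(intersect, lapply(edgeSets, keyOf))
  out <- edgeSets[[1]][match(keys, keyOf(edgeSets[[1]])), , drop = FALSE]
  if (length(edgeSets) > 1) {
    for (i in 2:length(edgeSets)) {
      e <- edgeSets[[i]][match(keys, keyOf(edgeSets[[i]])), , drop = FALSE]
      extra <- setdiff(colnames(e), c("regulator", "target"))
      for (cn in extra) {
        nm <- if (cn %in% colnames(out)) paste0(cn, ".", i) else cn
        out[[nm]] <- e[[cn]]
      }
    }
  }
  rownames(out) <- NULL
  out
}
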