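#' FPKM matrix
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `count / (length/1e3) / (libSize/1e6)`.
#'
#' @param counts features x samples count matrix.
#' @param lengths per-feature transcript lengths (nt, > 0), recycled by row.
#' @param libSizes per-sample library sizes (reads, > 0); default column sums.
#' @return Numeric matrix of FPKM values, same shape as `counts`.
#' @export
#' @examples
#' computeFPKM(matrix(100), lengths = 1000, libSizes = 1e6)  # 100
computeFPKM <- function(counts, lengths, libSizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("transcript lengths must be > 0")
  if (any(libSizes <= 0)) stop("library sizes must be > 0")
  fpkm <- sweep(counts / (lengths / 1e3), 2, libSizes / 1e6, `/`)
  dimnames(fpkm) <- dimnames(counts)
  fpkm
}

#' Per-base read coverage proxy
#'
#' Mean per-base depth approximated as `count * readLength / length`.
#'
#' @inheritParams computeFPKM
#' @param readLength sequencing read length in bp (default 150).
#' @return Numeric matrix of coverage values.
#' @export
readCoverage <- function(counts, lengths, readLength = 150) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("transcript lengths must be > 0")
  counts * readLength / lengths
}

## Longest ATG -> stop open reading frame (nt, including the stop codon) over
## the three forward frames; 0 when no complete ORF exists.
.longestOrf <- function(seq) {
  seq <- chartr("u", "t", chartr("U", "T", toupper(seq)))
  n <- nchar(seq)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (f in 0:2) {
    last <- n - ((n - f) %% 3L)
    if (last - f < 3L) next
    st <- seq.int(1L + f, last - 2L, by = 3L)
    cod <- substring(seq, st, st + 2L)
    atg <- which(cod == "ATG")
    stp <- which(cod %in% stops)
    if (!length(atg) || !length(stp)) next
    nxt <- stp[findInterval(atg, stp) + 1L]
    ok <- !is.na(nxt)
    if (any(ok)) best <- max(best, 3L * (nxt[ok] - atg[ok] + 1L))
  }
  best
}

#' ORF-based coding-potential score
#'
#' A built-in coding-potential scorer satisfying the pluggable scorer
#' contract: the score is a logistic function of the longest-ORF fraction
#' (longest ATG-to-stop ORF length over transcript length, scanning the three
#' forward frames), monotone in that fraction. Transcripts with score >= 0.5
#' (ORF fraction >= 0.5) are classified coding.
#'
#' @param sequences character vector or [Biostrings::DNAStringSet]; U is
#'   normalized to T. More than 10 percent ambiguous bases is an error.
#' @param steepness logistic steepness (default 10).
#' @param midpoint ORF fraction at which the score crosses 0.5 (default 0.5).
#' @return data.frame with columns `score` (in `[0, 1]`), `orf_length` (nt)
#'   and `coding` (logical).
#' @export
#' @examples
#' orfCodingScore("ATGAAACCCGGGTAA")  # one end-to-end ORF: coding
orfCodingScore <- function(sequences, steepness = 10, midpoint = 0.5) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- as.character(sequences)
  seqs <- chartr("Uu", "Tt", toupper(sequences))
  bad <- vapply(seqs, function(s) {
    n <- nchar(s)
    amb <- n - sum(vapply(c("A", "C", "G", "T"), function(b)
      lengths(regmatches(s, gregexpr(b, s, fixed = TRUE))), 0L))
    amb / n
  }, 0)
  if (any(bad > 0.1))
    stop("sequences with more than 10% ambiguous bases are not scored")
  orf <- vapply(seqs, .longestOrf, 0L)
  frac <- orf / nchar(seqs)
  score <- stats::plogis(steepness * (frac - midpoint))
  data.frame(score = unname(score), orf_length = unname(orf),
             coding = unname(score >= 0.5),
             row.names = names(sequences))
}

#' lncRNA candidate filtering
#'
#' Applies the candidate-selection rules in their printed order: transcript
#' length >= `minLength`; exon number >= `minExons`; FPKM > `minFpkm` in at
#' least one sample; read coverage >= `minCoverage` in at least one sample;
#' not annotated protein-coding; consensus non-coding (a transcript is
#' non-coding only when *all* registered coding-potential scorers vote
#' non-coding). The rejection reason records the first failing rule.
#'
#' @param txInfo data.frame with columns `id`, `length`, `n_exons`,
#'   `annotated_biotype` for the transcripts to assess.
#' @param fpkm FPKM matrix (rows must include all `txInfo$id`).
#' @param coverage coverage matrix, same keying.
#' @param codingVotes logical matrix (transcripts x scorers), `TRUE` = votes
#'   coding; rows must include all `txInfo$id`.
#' @param minLength,minExons,minFpkm,minCoverage thresholds (defaults 200, 2,
#'   0.5, 3; all strictly positive).
#' @return A [S4Vectors::DataFrame] with columns `id`, `pass`, `reason`
#'   (`NA` for passing transcripts).
#' @export
filterLncRNACandidates <- function(txInfo, fpkm, coverage, codingVotes,
                                   minLength = 200, minExons = 2,
                                   minFpkm = 0.5, minCoverage = 3) {
  stopifnot(minLength > 0, minExons > 0, minFpkm > 0, minCoverage > 0)
  ids <- txInfo$id
  codingVotes <- as.matrix(codingVotes)
  for (nm in list(rownames(fpkm), rownames(coverage), rownames(codingVotes)))
    if (!all(ids %in% nm))
      stop("transcripts missing from an input: ",
           paste(setdiff(ids, nm), collapse = ", "))
  fpkmMax <- apply(fpkm[ids, , drop = FALSE], 1, max)
  covMax <- apply(coverage[ids, , drop = FALSE], 1, max)
  votedCoding <- apply(codingVotes[ids, , drop = FALSE], 1, any)
  rules <- cbind(
    length = txInfo$length >= minLength,
    `exon number` = txInfo$n_exons >= minExons,
    FPKM = fpkmMax > minFpkm,
    coverage = covMax >= minCoverage,
    `known annotation` = txInfo$annotated_biotype != "mRNA",
    `coding potential` = !votedCoding)
  pass <- apply(rules, 1, all)
  reason <- apply(rules, 1, function(r)
    if (all(r)) NA_character_ else colnames(rules)[which(!r)[1]])
  S4Vectors::DataFrame(id = ids, pass = unname(pass), reason = unname(reason))
}
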