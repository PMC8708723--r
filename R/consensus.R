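#' @importFrom stats cor
NULL

#' Match peaks one-to-one across two replicates
#'
#' Candidate pairs must overlap reciprocally: the shared bases must cover at
#' least `minReciprocalOverlap` of *each* member's length. Among candidates a
#' greedy matching by descending combined score (mean of member scores) is
#' taken, tie-broken by genomic order, with each peak matched at most once.
#'
#' @param repA,repB ranked peak `GRanges` as returned by [readPeaks()].
#' @param params a [consensusParams()].
#' @return data.frame with one row per matched pair: `idxA`, `idxB`,
#'   `rankA`, `rankB`, `scoreA`, `scoreB`, `combinedScore`, `overlapBp`.
#' @export
pairReplicates <- function(repA, repB, params = consensusParams()) {
  stopifnot(is(params, "ConsensusParams"))
  empty <- data.frame(idxA = integer(), idxB = integer(),
                      rankA = integer(), rankB = integer(),
                      scoreA = numeric(), scoreB = numeric(),
                      combinedScore = numeric(), overlapBp = integer())
  if (!length(repA) || !length(repB)) return(empty)
  ov <- overlapQuery(repA, repB)
  if (!nrow(ov)) return(empty)
  ro <- params@minReciprocalOverlap
  keep <- ov$overlapBp >= ro * width(repA)[ov$queryIdx] &
    ov$overlapBp >= ro * width(repB)[ov$subjectIdx]
  ov <- ov[keep, , drop = FALSE]
  if (!nrow(ov)) return(empty)
  combined <- (repA$score[ov$queryIdx] + repB$score[ov$subjectIdx]) / 2
  o <- order(-combined,
             as.character(seqnames(repA))[ov$queryIdx],
             start(repA)[ov$queryIdx],
             start(repB)[ov$subjectIdx])
  ov <- ov[o, , drop = FALSE]
  combined <- combined[o]
  usedA <- logical(length(repA))
  usedB <- logical(length(repB))
  take <- logical(nrow(ov))
  for (k in seq_len(nrow(ov))) {
    a <- ov$queryIdx[k]; b <- ov$subjectIdx[k]
    if (!usedA[a] && !usedB[b]) {
      take[k] <- TRUE
      usedA[a] <- TRUE
      usedB[b] <- TRUE
    }
  }
  ov <- ov[take, , drop = FALSE]
  res <- data.frame(idxA = ov$queryIdx, idxB = ov$subjectIdx,
                    rankA = repA$rank[ov$queryIdx],
                    rankB = repB$rank[ov$subjectIdx],
                    scoreA = repA$score[ov$queryIdx],
                    scoreB = repB$score[ov$subjectIdx],
                    combinedScore = combined[take],
                    overlapBp = ov$overlapBp)
  res[order(res$idxA), , drop = FALSE]
}

#' Build the consensus peak set from a replicate matching
#'
#' Retains matched pairs whose members both lie within the top
#' `maxRankFraction` of their replicate's ranking. The Spearman correlation
#' of member ranks across all matched pairs is reported; a concordance
#' warning is raised when it falls below `rankCorrelationMin`. Each retained
#' pair becomes one consensus peak spanning both members, scored by the mean
#' member score, with reproducibility `min(1 - rank/n)` over the members.
#'
#' @inheritParams pairReplicates
#' @param matching optionally a precomputed [pairReplicates()] result.
#' @return a [ConsensusPeaks-class] object.
#' @export
consensusPeaks <- function(repA, repB, params = consensusParams(),
                           matching = NULL) {
  if (is.null(matching)) matching <- pairReplicates(repA, repB, params)
  rho <- if (nrow(matching) >= 2L) {
    suppressWarnings(cor(matching$rankA, matching$rankB, method = "spearman"))
  } else {
    NA_real_
  }
  if (!is.na(rho) && rho < params@rankCorrelationMin) {
    warning(sprintf(
      "replicate concordance low: rank correlation %.3f < %.3f",
      rho, params@rankCorrelationMin))
  }
  nA <- length(repA); nB <- length(repB)
  cutA <- floor(params@maxRankFraction * nA + 1e-9)
  cutB <- floor(params@maxRankFraction * nB + 1e-9)
  keep <- matching$rankA <= cutA & matching$rankB <= cutB
  kept <- matching[keep, , drop = FALSE]
  if (nrow(kept)) {
    a <- repA[kept$idxA]
    b <- repB[kept$idxB]
    merged <- GRanges(seqnames(a),
                      IRanges(pmin(start(a), start(b)), pmax(end(a), end(b))),
                      seqinfo = seqinfo(a))
    merged$name <- paste0("consensus_", seq_along(merged))
    merged$score <- kept$combinedScore
    merged$reproducibility <- pmin(1 - kept$rankA / nA, 1 - kept$rankB / nB)
    merged$rankA <- kept$rankA
    merged$rankB <- kept$rankB
    merged$memberA <- a$name
    merged$memberB <- b$name
    o <- order(as.character(seqnames(merged)), start(merged))
    merged <- merged[o]
    merged$name <- paste0("consensus_", seq_along(merged))
  } else {
    merged <- GRanges(seqinfo = seqinfo(repA))
    mcols(merged) <- DataFrame(name = character(), score = numeric(),
                               reproducibility = numeric(),
                               rankA = integer(), rankB = integer(),
                               memberA = character(), memberB = character())
  }
  new("ConsensusPeaks", peaks = merged, pairs = matching,
      rankCorrelation = as.numeric(rho), params = params,
      nRepA = nA, nRepB = nB)
}

#' Write the consensus peak TSV report
#'
#' Per-pair member ranks and scores plus the global rank correlation, as a
#' companion to the consensus narrowPeak.
#'
#' @param x a `ConsensusPeaks`.
#' @param path output path.
#' @export
writeConsensusReport <- function(x, path) {
  pk <- x@peaks
  df <- data.frame(name = pk$name,
                   chrom = as.character(seqnames(pk)),
                   start = start(pk) - 1L, end = end(pk),
                   score = pk$score,
                   reproducibility = pk$reproducibility,
                   rankA = pk$rankA, rankB = pk$rankB,
                   memberA = pk$memberA, memberB = pk$memberB,
                   rankCorrelation = rep(x@rankCorrelation,
                                         length.out = length(pk)))
  writeTsv(df, path)
}
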