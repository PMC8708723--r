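#' @importFrom GenomicRanges reduce findOverlaps pintersect
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Peak centers
#'
#' The center of a peak is its summit position when a `summitOffset` metadata
#' column is present (and not `NA`), otherwise the midpoint
#' `start + floor(length/2)` in 0-based coordinates. Returned positions are
#' 1-based.
#'
#' @param peaks a `GRanges`, optionally with `summitOffset`.
#' @return integer vector of center positions (1-based).
#' @export
peakCenters <- function(peaks) {
  centers <- start(peaks) + width(peaks) %/% 2L
  if (!is.null(peaks$summitOffset)) {
    hasSummit <- !is.na(peaks$summitOffset)
    centers[hasSummit] <- start(peaks)[hasSummit] +
      as.integer(peaks$summitOffset[hasSummit])
  }
  centers
}

## Width-1 GRanges at the peak centers (strand dropped).
centerRanges <- function(peaks) {
  c0 <- peakCenters(peaks)
  GRanges(seqnames(peaks), IRanges(c0, c0), seqinfo = seqinfo(peaks))
}

#' Merge intervals into a disjoint sorted set
#'
#' Union of the input coverage; intervals that touch (BED end == next start,
#' i.e. adjacent in 1-based closed coordinates) are merged. Strand is
#' ignored.
#'
#' @param intervals a `GRanges`.
#' @return a disjoint, sorted, unstranded `GRanges`.
#' @export
mergeIntervals <- function(intervals) {
  validateWithinGenome(intervals)
  reduce(granges(intervals), ignore.strand = TRUE, min.gapwidth = 1L)
}

validateWithinGenome <- function(gr) {
  lens <- seqlengths(gr)
  if (all(is.na(lens))) return(invisible(TRUE))
  known <- lens[as.character(seqnames(gr))]
  bad <- which(!is.na(known) & end(gr) > known)
  if (length(bad))
    stop("interval beyond chromosome length: ",
         as.character(seqnames(gr))[bad[1L]], ":", start(gr)[bad[1L]] - 1L,
         "-", end(gr)[bad[1L]], call. = FALSE)
  invisible(TRUE)
}

#' Overlap query with overlap widths
#'
#' Returns every (query, subject) pair sharing at least one base under
#' half-open BED semantics (adjacent intervals do not overlap), with the
#' number of shared bases.
#'
#' @param query,subject `GRanges`.
#' @return data.frame with columns `queryIdx`, `subjectIdx`, `overlapBp`.
#' @export
overlapQuery <- function(query, subject) {
  hits <- findOverlaps(query, subject, ignore.strand = TRUE)
  if (!length(hits)) {
    return(data.frame(queryIdx = integer(), subjectIdx = integer(),
                      overlapBp = integer()))
  }
  inter <- pintersect(granges(query)[queryHits(hits)],
                      granges(subject)[subjectHits(hits)],
                      ignore.strand = TRUE)
  data.frame(queryIdx = queryHits(hits), subjectIdx = subjectHits(hits),
             overlapBp = width(inter))
}

#' Distance from each peak center to the nearest TSS
#'
#' Distance is the center-to-center distance `|peak center - TSS position|`
#' minimized over all TSS on the peak's chromosome. The signed distance is
#' negative when the peak lies upstream of the gene (relative to the gene's
#' strand; unstranded TSS are treated as + strand). Ties are broken by the
#' lexicographically smaller `gene_id`.
#'
#' @param peaks a `GRanges` (centers per [peakCenters()]).
#' @param tss width-1 `GRanges` with `gene_id` as returned by [readTssBed()].
#' @return data.frame with columns `gene_id`, `distance` (signed) and
#'   `absDistance`, one row per peak.
#' @export
distanceToNearestTss <- function(peaks, tss) {
  if (!length(tss)) stop("TSS set is empty", call. = FALSE)
  pc <- as.character(seqnames(peaks))
  missing <- setdiff(unique(pc), unique(as.character(seqnames(tss))))
  if (length(missing))
    stop("peak chromosome(s) absent from the TSS annotation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  centers <- peakCenters(peaks)
  tc <- as.character(seqnames(tss))
  tpos <- start(tss)
  tstr <- as.character(strand(tss))
  tstr[tstr == "*"] <- "+"
  tgene <- tss$gene_id
  ## deterministic tie-break: within equal distance prefer smaller gene_id
  gene <- character(length(peaks))
  dist <- integer(length(peaks))
  for (chr in unique(pc)) {
    pi <- which(pc == chr)
    ti <- which(tc == chr)
    ## order TSS so that, among equal distances, the first found has the
    ## smallest gene_id
    ti <- ti[order(tgene[ti])]
    pos <- tpos[ti]
    for (i in pi) {
      d <- abs(centers[i] - pos)
      j <- ti[which.min(d)]
      gene[i] <- tgene[j]
      s <- centers[i] - tpos[j]
      dist[i] <- if (tstr[j] == "-") -s else s
    }
  }
  data.frame(gene_id = gene, distance = dist, absDistance = abs(dist))
}
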