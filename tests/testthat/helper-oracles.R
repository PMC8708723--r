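## Brute-force oracles and small builders shared across tests. These are
## deliberately naive (per-base, all-pairs, exhaustive) so they cannot share
## failure modes with the interval-tree / Rle implementations under test.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(GenomeInfoDb)
})

## GRanges from 1-based closed coordinate vectors.
mkGR <- function(chrom, start, end, ..., seqinfo = NULL) {
  ## pin seqlevels to sorted order so sorted output is input-order-invariant
  gr <- GRanges(factor(chrom, levels = sort(unique(chrom))),
                IRanges(start, end))
  extras <- list(...)
  for (nm in names(extras)) mcols(gr)[[nm]] <- extras[[nm]]
  if (!is.null(seqinfo)) seqinfo(gr) <- seqinfo
  gr
}

## Per-base merge oracle: mark covered bases, read off maximal runs.
oracleMerge <- function(chrom, start, end, maxPos) {
  out <- list()
  for (chr in sort(unique(chrom))) {
    covered <- logical(maxPos)
    sel <- which(chrom == chr)
    for (i in sel) covered[start[i]:end[i]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      out[[chr]] <- data.frame(chrom = chr, start = starts[keep],
                               end = ends[keep])
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

## All-pairs overlap oracle (1-based closed): shared bases per (i, j) pair.
oracleOverlap <- function(qChrom, qStart, qEnd, sChrom, sStart, sEnd) {
  rows <- list()
  for (i in seq_along(qChrom)) {
    for (j in seq_along(sChrom)) {
      if (qChrom[i] != sChrom[j]) next
      ov <- min(qEnd[i], sEnd[j]) - max(qStart[i], sStart[j]) + 1L
      if (ov > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(queryIdx = i, subjectIdx = j,
                                                overlapBp = ov)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(queryIdx = integer(), subjectIdx = integer(),
                      overlapBp = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$queryIdx, out$subjectIdx), , drop = FALSE]
}

## Exhaustive nearest-TSS oracle with the smaller-gene_id tie-break.
oracleNearestTss <- function(pChrom, pCenter, tChrom, tPos, tStrand, tGene) {
  n <- length(pChrom)
  gene <- character(n); dist <- integer(n)
  for (i in seq_len(n)) {
    sel <- which(tChrom == pChrom[i])
    d <- abs(pCenter[i] - tPos[sel])
    best <- sel[d == min(d)]
    best <- best[order(tGene[best])][1L]
    gene[i] <- tGene[best]
    s <- pCenter[i] - tPos[best]
    dist[i] <- if (tStrand[best] == "-") -s else s
  }
  data.frame(gene_id = gene, distance = dist, absDistance = abs(dist))
}

## Random peak-like GRanges on a small genome.
randGR <- function(n, chroms = c("chr1", "chr2"), maxPos = 5000,
                   maxWidth = 100) {
  start <- sample.int(maxPos - maxWidth, n, replace = TRUE)
  width <- sample.int(maxWidth, n, replace = TRUE)
  mkGR(sample(chroms, n, replace = TRUE), start, start + width - 1L)
}
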