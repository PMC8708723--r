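NULL

#' Build basal-plus-extension regulatory domains
#'
#' One canonical TSS per gene (the first in genomic order when several). The
#' basal domain runs from `upstreamBp` before to `downstreamBp` after the TSS
#' (strand-aware; unstranded genes are treated as + strand). Each side is
#' then extended outward up to `maxExtensionBp`, stopping at the nearest
#' other gene's basal domain, and clipped to the chromosome.
#'
#' @param tss width-1 `GRanges` with `gene_id` (strand used).
#' @param params a [domainParams()].
#' @param seqinfo optional `Seqinfo` for chromosome clipping (falls back to
#'   the `tss` seqinfo).
#' @return a `GRanges` of extended domains with metadata `gene_id`, `tss`,
#'   `basalStart`, `basalEnd` (1-based closed).
#' @export
buildRegulatoryDomains <- function(tss, params = domainParams(),
                                   seqinfo = NULL) {
  stopifnot(is(params, "DomainParams"))
  if (is.null(seqinfo)) seqinfo <- seqinfo(tss)
  tss <- sort(tss, ignore.strand = TRUE)
  canon <- tss[!duplicated(tss$gene_id)]
  chrom <- as.character(seqnames(canon))
  pos <- start(canon)
  str <- as.character(strand(canon))
  str[str == "*"] <- "+"
  lens <- seqlengths(seqinfo)[chrom]
  if (any(!is.na(lens) & pos > lens))
    stop("gene TSS beyond chromosome bounds: ",
         canon$gene_id[which(pos > lens)[1L]], call. = FALSE)
  up <- params@upstreamBp
  down <- params@downstreamBp
  basalStart <- ifelse(str == "+", pos - up, pos - down)
  basalEnd <- ifelse(str == "+", pos + down, pos + up)
  basalStart <- pmax(basalStart, 1)
  basalEnd <- ifelse(is.na(lens), basalEnd, pmin(basalEnd, lens))
  extStart <- numeric(length(canon))
  extEnd <- numeric(length(canon))
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    for (i in idx) {
      others <- setdiff(idx, i)
      leftLimit <- basalEnd[others][basalEnd[others] < basalStart[i]]
      leftLimit <- if (length(leftLimit)) max(leftLimit) + 1 else 1
      rightLimit <- basalStart[others][basalStart[others] > basalEnd[i]]
      rightLimit <- if (length(rightLimit)) min(rightLimit) - 1 else Inf
      extStart[i] <- max(1, basalStart[i] - params@maxExtensionBp, leftLimit)
      extEnd[i] <- min(basalEnd[i] + params@maxExtensionBp, rightLimit,
                       if (is.na(lens[i])) Inf else lens[i])
    }
  }
  gr <- GRanges(chrom, IRanges(as.integer(extStart), as.integer(extEnd)),
                strand = str, seqinfo = seqinfo)
  gr$gene_id <- canon$gene_id
  gr$tss <- pos
  gr$basalStart <- as.integer(basalStart)
  gr$basalEnd <- as.integer(basalEnd)
  sort(gr, ignore.strand = TRUE)
}

#' Associate peaks with genes through regulatory domains
#'
#' A peak maps to every gene whose extended domain contains the peak center
#' (GREAT-style; `mode = "overlap"` instead requires any peak-domain
#' overlap). The empty set is a valid result.
#'
#' @param peaks a `GRanges`.
#' @param domains output of [buildRegulatoryDomains()].
#' @param mode `"center"` (default) or `"overlap"`.
#' @return data.frame with one row per (peak, gene) pair: `peakIdx`,
#'   `peak` (name), `gene_id`, `distanceToTss` (signed,
#'   center minus TSS on the gene strand).
#' @export
associatePeaks <- function(peaks, domains, mode = c("center", "overlap")) {
  mode <- match.arg(mode)
  q <- if (mode == "center") centerRanges(peaks) else granges(peaks)
  hits <- findOverlaps(q, domains, ignore.strand = TRUE)
  pk <- queryHits(hits)
  dm <- subjectHits(hits)
  centers <- peakCenters(peaks)
  s <- centers[pk] - domains$tss[dm]
  sgn <- ifelse(as.character(strand(domains))[dm] == "-", -s, s)
  nm <- if (!is.null(peaks$name)) peaks$name else paste0("peak", seq_along(peaks))
  out <- data.frame(peakIdx = pk, peak = nm[pk], gene_id = domains$gene_id[dm],
                    distanceToTss = sgn)
  out[order(out$peakIdx, out$gene_id), , drop = FALSE]
}
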