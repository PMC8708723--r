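#' @importFrom GenomicRanges coverage
#' @importFrom IRanges Views viewMeans viewMaxs
NULL

## Coverage Rle of a piecewise-constant track, one Rle per chromosome in
## `levels`, each padded with zeros to the chromosome length (or the track's
## own maximum when lengths are unknown).
trackCoverage <- function(track, levels, lengths = NULL) {
  if (is.null(lengths)) {
    lengths <- seqlengths(track)[levels]
    byChrom <- split(end(track), factor(as.character(seqnames(track)), levels))
    fallback <- vapply(byChrom, function(e) if (length(e)) max(e) else 1L, 1L)
    lengths[is.na(lengths)] <- fallback[is.na(lengths)]
  }
  out <- vector("list", length(levels))
  names(out) <- levels
  tc <- as.character(seqnames(track))
  for (chr in levels) {
    sel <- tc == chr
    cvg <- coverage(IRanges(start(track)[sel], end(track)[sel]),
                    weight = track$score[sel], width = lengths[[chr]])
    out[[chr]] <- cvg
  }
  out
}

#' Per-element max-Z scores of a signal track
#'
#' For each element the maximum track value inside it is taken (bases without
#' track coverage count as signal 0), then the maxima are standardized across
#' elements: `z = (max - mean) / sd` with the population (n-denominator)
#' standard deviation, so the scores have mean 0 and sd 1.
#'
#' @param elements a `GRanges` (at least 2 elements).
#' @param track a signal `GRanges` with a `score` column.
#' @return numeric vector of z-scores, one per element.
#' @export
computeMaxZ <- function(elements, track) {
  if (length(elements) < 2L)
    stop("need at least 2 elements to standardize", call. = FALSE)
  levels <- unique(as.character(seqnames(elements)))
  lens <- pmax(vapply(split(end(elements),
                            factor(as.character(seqnames(elements)), levels)),
                      max, 1L),
               vapply(levels, function(chr) {
                 sel <- as.character(seqnames(track)) == chr
                 if (any(sel)) max(end(track)[sel]) else 1L
               }, 1L))
  cvg <- trackCoverage(track, levels, as.list(lens))
  mx <- numeric(length(elements))
  ec <- as.character(seqnames(elements))
  for (chr in levels) {
    sel <- which(ec == chr)
    v <- Views(cvg[[chr]], start(elements)[sel], end(elements)[sel])
    mx[sel] <- viewMaxs(v)
  }
  s <- sdPop(mx)
  if (s == 0)
    stop("zero variance of element max signals; check the signal track",
         call. = FALSE)
  (mx - mean(mx)) / s
}

## Center-to-TSS distance with Inf for chromosomes lacking any TSS.
distToTssOrInf <- function(elements, tss) {
  d <- rep(Inf, length(elements))
  if (!length(tss) || !length(elements)) return(d)
  ec <- as.character(seqnames(elements))
  covered <- ec %in% unique(as.character(seqnames(tss)))
  if (any(covered)) {
    d[covered] <- distanceToNearestTss(elements[covered], tss)$absDistance
  }
  d
}

#' Classify elements into SCREEN-style cCRE classes
#'
#' Applies the classification rules with precedence
#' PLS > pELS > dELS > DNase-H3K4me3 > DNase-only > unclassified:
#' * PLS: center within `tssProximalBp` of a TSS, DNase high, H3K4me3 high;
#' * pELS / dELS: DNase high and H3K27ac high (and not PLS), split at
#'   `elsProximalBp` center-to-TSS distance;
#' * DNase-H3K4me3: DNase high, H3K4me3 high, H3K27ac low, center farther
#'   than `tssProximalBp` from any TSS;
#' * DNase-only: DNase high, H3K4me3 and H3K27ac low.
#'
#' @param elements a `GRanges`; when `signals` is `NULL` the metadata columns
#'   `dnaseZ`, `h3k4me3Z`, `h3k27acZ` are used.
#' @param tss TSS `GRanges` (may be empty: all elements are then distal).
#' @param params a [ccreParams()].
#' @param signals optional data.frame/matrix with columns `dnaseZ`,
#'   `h3k4me3Z`, `h3k27acZ`.
#' @return character vector of classes (one per element).
#' @export
classifyElements <- function(elements, tss, params = ccreParams(),
                             signals = NULL) {
  if (is.null(signals)) signals <- as.data.frame(mcols(elements))
  for (assay in c("dnaseZ", "h3k4me3Z", "h3k27acZ")) {
    if (is.null(signals[[assay]]) || anyNA(signals[[assay]]))
      stop("missing assay signal: ", assay, call. = FALSE)
  }
  dn <- signals$dnaseZ; k4 <- signals$h3k4me3Z; k27 <- signals$h3k27acZ
  high <- function(z) z >= params@highZ
  low <- function(z) z < params@lowZ
  d <- distToTssOrInf(elements, tss)
  cls <- rep("unclassified", length(elements))
  isPLS <- d <= params@tssProximalBp & high(dn) & high(k4)
  isELS <- !isPLS & high(dn) & high(k27)
  ispELS <- isELS & d <= params@elsProximalBp
  isdELS <- isELS & d > params@elsProximalBp
  isDnaseK4 <- !isPLS & !isELS & high(dn) & high(k4) & low(k27) &
    d > params@tssProximalBp
  isDnaseOnly <- !isPLS & !isELS & !isDnaseK4 & high(dn) & low(k4) & low(k27)
  cls[isDnaseOnly] <- "DNase-only"
  cls[isDnaseK4] <- "DNase-H3K4me3"
  cls[isdELS] <- "dELS"
  cls[ispELS] <- "pELS"
  cls[isPLS] <- "PLS"
  cls
}

#' Assign each peak the class of the cCRE element it overlaps
#'
#' The catalog element sharing the most bases with the peak wins; ties are
#' broken by genomic order of the catalog. Peaks overlapping no element are
#' `"unclassified"`.
#'
#' @param peaks a `GRanges`.
#' @param catalog a classified cCRE `GRanges` (metadata column `class`).
#' @return character vector of classes, one per peak.
#' @export
assignPeakClasses <- function(peaks, catalog) {
  if (is.null(catalog$class))
    stop("catalog has no 'class' column", call. = FALSE)
  catalog <- sort(catalog, ignore.strand = TRUE)
  cls <- rep("unclassified", length(peaks))
  ov <- overlapQuery(peaks, catalog)
  if (nrow(ov)) {
    ## stable order: by peak, descending overlap, catalog genomic order
    o <- order(ov$queryIdx, -ov$overlapBp, ov$subjectIdx)
    ov <- ov[o, , drop = FALSE]
    first <- !duplicated(ov$queryIdx)
    cls[ov$queryIdx[first]] <- catalog$class[ov$subjectIdx[first]]
  }
  cls
}

#' Class distribution of a peak set over a cCRE catalog
#'
#' @inheritParams assignPeakClasses
#' @return named numeric vector of fractions over all cCRE classes
#'   (summing to 1).
#' @export
classDistribution <- function(peaks, catalog) {
  cls <- factor(assignPeakClasses(peaks, catalog), levels = ccreClassLevels())
  tab <- table(cls)
  as.numeric(tab) / length(peaks) -> frac
  names(frac) <- names(tab)
  frac
}

#' Signal matrix around peak centers
#'
#' Bins the `+/- flankBp` window around each peak center into `binBp` bins
#' and records the mean track value per bin (track gaps count as 0). Bins
#' extending beyond the chromosome are clipped; bins entirely outside are
#' `NA`. Rows are sorted by descending row mean.
#'
#' @param peaks a `GRanges` (row names taken from `name` when present).
#' @param track signal `GRanges` with `score`.
#' @param flankBp half-window in bp (default 2500).
#' @param binBp bin width in bp (must divide `flankBp`; default 50).
#' @return numeric matrix, peaks x `2*flankBp/binBp` bins; column names are
#'   bin start offsets relative to the center.
#' @export
signalMatrix <- function(peaks, track, flankBp = 2500, binBp = 50) {
  if (flankBp %% binBp != 0)
    stop("flankBp must be divisible by binBp", call. = FALSE)
  nbin <- as.integer(2 * flankBp / binBp)
  centers <- peakCenters(peaks)
  levels <- unique(as.character(seqnames(peaks)))
  lens <- seqlengths(peaks)[levels]
  fallback <- vapply(levels, function(chr) {
    sel <- as.character(seqnames(track)) == chr
    m1 <- if (any(sel)) max(end(track)[sel]) else 1L
    max(m1, max(centers[as.character(seqnames(peaks)) == chr]) + flankBp)
  }, 1)
  lens[is.na(lens)] <- fallback[is.na(lens)]
  cvg <- trackCoverage(track, levels, as.list(lens))
  mat <- matrix(NA_real_, length(peaks), nbin)
  off <- seq(-flankBp, flankBp - binBp, by = binBp)
  colnames(mat) <- off
  pc <- as.character(seqnames(peaks))
  for (chr in levels) {
    sel <- which(pc == chr)
    if (!length(sel)) next
    len <- lens[[chr]]
    for (j in seq_len(nbin)) {
      s <- centers[sel] + off[j]
      e <- s + binBp - 1L
      cs <- pmax(s, 1L)
      ce <- pmin(e, len)
      ok <- which(cs <= ce)
      if (length(ok)) {
        v <- Views(cvg[[chr]], cs[ok], ce[ok])
        mat[sel[ok], j] <- viewMeans(v)
      }
    }
  }
  rn <- if (!is.null(peaks$name)) peaks$name else paste0("peak", seq_along(peaks))
  rownames(mat) <- rn
  mat[order(-rowMeans(mat, na.rm = TRUE)), , drop = FALSE]
}
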