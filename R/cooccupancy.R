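#' @importFrom IRanges viewSums
#' @importFrom stats hclust as.dist cutree
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges assay
#' @importFrom S4Vectors metadata metadata<-
NULL

#' Merge per-factor peak sets into a common region universe
#'
#' The merged (disjoint, sorted) union of all factors' binding sites, with a
#' provenance matrix recording which factors contributed at least one peak
#' per region.
#'
#' @param peakSets named list of per-factor peak `GRanges` (>= 2 factors).
#' @return list with `regions` (`GRanges`) and `provenance`
#'   (regions x factors logical matrix).
#' @export
buildMergedRegions <- function(peakSets) {
  if (length(peakSets) < 2L)
    stop("need at least 2 factors", call. = FALSE)
  if (is.null(names(peakSets)) || anyDuplicated(names(peakSets)))
    stop("peakSets must be uniquely named by factor", call. = FALSE)
  empty <- vapply(peakSets, length, 1L) == 0L
  if (any(empty))
    warning("factor(s) with empty peak set retained with zero contribution: ",
            paste(names(peakSets)[empty], collapse = ", "))
  all <- unlist(GenomicRanges::GRangesList(lapply(peakSets, granges)),
                use.names = FALSE)
  regions <- mergeIntervals(all)
  prov <- vapply(peakSets, function(p) {
    hits <- rep(FALSE, length(regions))
    if (length(p)) {
      ov <- findOverlaps(regions, granges(p), ignore.strand = TRUE)
      hits[unique(queryHits(ov))] <- TRUE
    }
    hits
  }, logical(length(regions)))
  if (length(regions) == 1L) prov <- matrix(prov, nrow = 1L,
                                            dimnames = list(NULL, names(peakSets)))
  list(regions = regions, provenance = prov)
}

#' Co-occupancy score matrix
#'
#' Entry (factor, region) is the length-weighted mean of the factor's signal
#' track over the region; bases without track coverage count as 0. Tracks are
#' expected to be input-normalized fold enrichments (the caller's
#' responsibility, recorded in the result metadata).
#'
#' @param regions merged region `GRanges` (e.g. from [buildMergedRegions()]).
#' @param tracks named list of signal `GRanges` (with `score`), one per
#'   factor.
#' @return a `SummarizedExperiment` with `rowRanges = regions`, one column
#'   per factor, assay `"score"`.
#' @export
scoreMatrix <- function(regions, tracks) {
  levels <- unique(as.character(seqnames(regions)))
  rc <- as.character(seqnames(regions))
  lens <- lapply(levels, function(chr) {
    m <- max(end(regions)[rc == chr])
    for (tr in tracks) {
      sel <- as.character(seqnames(tr)) == chr
      if (any(sel)) m <- max(m, max(end(tr)[sel]))
    }
    m
  })
  names(lens) <- levels
  scores <- vapply(tracks, function(tr) {
    cvg <- trackCoverage(tr, levels, lens)
    out <- numeric(length(regions))
    for (chr in levels) {
      sel <- which(rc == chr)
      v <- Views(cvg[[chr]], start(regions)[sel], end(regions)[sel])
      out[sel] <- viewSums(v) / width(regions)[sel]
    }
    out
  }, numeric(length(regions)))
  if (length(regions) == 1L)
    scores <- matrix(scores, nrow = 1L, dimnames = list(NULL, names(tracks)))
  se <- SummarizedExperiment(assays = list(score = scores),
                             rowRanges = regions)
  metadata(se)$signal <- "length-weighted mean; assumed input-normalized fold enrichment"
  se
}

#' Spearman correlation and hierarchical clustering of factor scores
#'
#' Pairwise Spearman correlation between factors over the merged regions
#' (regions with zero signal in every factor are dropped first, as they carry
#' no rank information), distance `1 - rho`, and agglomerative clustering
#' (average linkage by default). Factors are ordered alphabetically before
#' clustering so leaf order is deterministic.
#'
#' @param scores factors-in-columns numeric matrix, or the
#'   `SummarizedExperiment` from [scoreMatrix()].
#' @param linkage `"average"` (default) or `"complete"`.
#' @return list with `correlation` (factor x factor matrix), `dist`,
#'   `hclust`, `leafOrder` (factor names in dendrogram order), and
#'   `droppedRegions` (count of all-zero regions removed).
#' @export
spearmanCluster <- function(scores, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  if (is(scores, "SummarizedExperiment")) scores <- assay(scores, "score")
  if (ncol(scores) < 2L) stop("need at least 2 factors", call. = FALSE)
  scores <- scores[, order(colnames(scores)), drop = FALSE]
  allZero <- rowSums(scores != 0) == 0L
  dropped <- sum(allZero)
  scores <- scores[!allZero, , drop = FALSE]
  if (nrow(scores) < 3L) stop("need at least 3 informative regions",
                              call. = FALSE)
  rho <- suppressWarnings(cor(scores, method = "spearman"))
  degenerate <- apply(scores, 2L, function(x) length(unique(x)) == 1L)
  if (any(degenerate)) {
    warning("factor(s) with zero variance across regions; correlations set to 0: ",
            paste(colnames(scores)[degenerate], collapse = ", "))
    rho[degenerate, ] <- 0
    rho[, degenerate] <- 0
  }
  diag(rho) <- 1
  d <- as.dist(1 - rho)
  hc <- hclust(d, method = linkage)
  list(correlation = rho, dist = d, hclust = hc,
       leafOrder = colnames(rho)[hc$order], droppedRegions = dropped)
}

#' Jaccard peak-overlap matrix between factors
#'
#' Secondary co-binding statistic: for each factor pair, the base-level
#' Jaccard index of their merged peak footprints
#' (intersection bp / union bp).
#'
#' @param peakSets named list of peak `GRanges`.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
jaccardMatrix <- function(peakSets) {
  n <- length(peakSets)
  merged <- lapply(peakSets, mergeIntervals)
  ## put every set on the union of seqlevels so sets confined to different
  ## chromosomes compare cleanly (Jaccard 0) instead of warning
  lvls <- unique(unlist(lapply(merged, GenomeInfoDb::seqlevels)))
  merged <- lapply(merged, function(g) {
    GenomeInfoDb::seqlevels(g) <- lvls
    g
  })
  out <- matrix(1, n, n, dimnames = list(names(peakSets), names(peakSets)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      inter <- sum(width(GenomicRanges::intersect(merged[[i]], merged[[j]],
                                                  ignore.strand = TRUE)))
      uni <- sum(width(GenomicRanges::union(merged[[i]], merged[[j]],
                                            ignore.strand = TRUE)))
      out[i, j] <- out[j, i] <- if (uni > 0) inter / uni else 0
    }
  }
  out
}

#' Write a dendrogram in Newick format
#'
#' @param hc an `hclust`.
#' @param path output path.
#' @export
writeNewick <- function(hc, path) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}
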