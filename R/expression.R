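#' @importFrom stats quantile dist phyper p.adjust sd
NULL

#' Counts per million
#'
#' `cpm = count / (librarySize * normFactor) * 1e6`, with library sizes taken
#' as column sums unless supplied.
#'
#' @param counts genes x samples nonnegative matrix.
#' @param normFactors per-sample normalization factors (default 1). These are
#'   composition factors multiplying the library size (edgeR convention).
#' @param libSizes per-sample library sizes (default `colSums(counts)`).
#' @return genes x samples numeric matrix.
#' @export
cpmMatrix <- function(counts, normFactors = rep(1, ncol(counts)),
                      libSizes = colSums(counts)) {
  if (any(libSizes <= 0)) stop("zero library size", call. = FALSE)
  if (any(normFactors <= 0)) stop("normalization factors must be positive",
                                  call. = FALSE)
  t(t(counts) / (libSizes * normFactors)) * 1e6
}

#' Filter lowly expressed genes
#'
#' A gene is retained when its CPM is at least `cpmMin` in at least
#' `minSamples` samples.
#'
#' @param cpm genes x samples CPM matrix (rownames = genes).
#' @param params a [deParams()].
#' @return character vector of retained gene names.
#' @export
filterLowExpression <- function(cpm, params = deParams()) {
  keep <- rowSums(cpm >= params@cpmMin) >= params@minSamples
  if (!any(keep)) warning("all genes fall below the expression filter")
  rownames(cpm)[keep]
}

#' Trimmed mean of M-values scaling factors
#'
#' Per-sample relative abundance factors by the TMM procedure: against a
#' reference sample (the one whose upper-quartile scaled count is closest to
#' the mean upper quartile), per-gene log2 count ratios M and mean log2
#' abundances A are computed on genes expressed in both samples; the upper
#' and lower 30% of M and 5% of A are trimmed; the factor is 2 to the
#' precision-weighted mean of the remaining M values. Factors are rescaled to
#' geometric mean 1, so they capture each sample's total-abundance scale
#' relative to the panel.
#'
#' @param counts genes x samples nonnegative integer matrix (>= 2 samples).
#' @param trimM,trimA two-sided trim fractions (published defaults 0.3 and
#'   0.05).
#' @return named numeric vector of factors, geometric mean 1.
#' @export
tmmFactors <- function(counts, trimM = 0.30, trimA = 0.05) {
  if (ncol(counts) < 2L) stop("need at least 2 samples", call. = FALSE)
  N <- colSums(counts)
  if (any(N <= 0)) stop("zero library size", call. = FALSE)
  f75 <- apply(counts, 2L, function(y) quantile(y / sum(y), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    yj <- counts[, j]; yr <- counts[, ref]
    both <- yj > 0 & yr > 0
    if (!any(both))
      stop("sample ", colnames(counts)[j] %||% j,
           " shares no expressed genes with the reference", call. = FALSE)
    yj <- yj[both]; yr <- yr[both]
    M <- log2(yj / yr)
    A <- (log2(yj) + log2(yr)) / 2
    w <- 1 / ((N[j] - yj) / (N[j] * yj) + (N[ref] - yr) / (N[ref] * yr))
    n <- length(M)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) keep <- rep(TRUE, n)
    2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }, 1)
  f <- f / geomean(f)
  names(f) <- colnames(counts)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Z-score scaling and hierarchical clustering of expression profiles
#'
#' CPM values of the selected (differentially expressed) genes are scaled to
#' Z-scores across samples; genes and samples are then clustered with
#' Euclidean distance and complete linkage. Zero-variance genes are dropped
#' with a warning. Genes are ordered by name before clustering for
#' deterministic leaf order.
#'
#' @param cpm genes x samples CPM matrix.
#' @param genes genes to cluster (>= 2 after the zero-variance drop).
#' @return list with `z` (scaled matrix), `geneHclust`, `sampleHclust`.
#' @export
zscoreCluster <- function(cpm, genes = rownames(cpm)) {
  if (ncol(cpm) < 2L)
    stop("Z-scores across samples are undefined for a single sample",
         call. = FALSE)
  genes <- sort(intersect(genes, rownames(cpm)))
  x <- cpm[genes, , drop = FALSE]
  v <- apply(x, 1L, sd)
  if (any(v == 0)) {
    warning("dropping zero-variance gene(s): ",
            paste(utils::head(genes[v == 0], 5L), collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("need at least 2 variable genes", call. = FALSE)
  z <- t(scale(t(x)))
  list(z = z,
       geneHclust = hclust(dist(z), method = "complete"),
       sampleHclust = hclust(dist(t(z)), method = "complete"))
}

#' Threshold a differential-expression table into up/down sets
#'
#' Significance requires `FDR < fdrMax` and `|log2FC| > minAbsLog2fc`; the
#' sign of the fold change splits up from down, so the sets are disjoint.
#'
#' @param deTable data.frame with columns `gene`, `log2FC`, `FDR`.
#' @param params a [deParams()].
#' @return list with character vectors `up` and `down` and the annotated
#'   table (`direction` column added).
#' @export
callDE <- function(deTable, params = deParams()) {
  need <- c("gene", "log2FC", "FDR")
  if (!all(need %in% names(deTable)))
    stop("DE table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(deTable$FDR < 0 | deTable$FDR > 1, na.rm = TRUE))
    stop("FDR values must lie in [0, 1]", call. = FALSE)
  sig <- !is.na(deTable$FDR) & deTable$FDR < params@fdrMax
  up <- sig & deTable$log2FC > params@minAbsLog2fc
  down <- sig & deTable$log2FC < -params@minAbsLog2fc
  deTable$direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  list(up = deTable$gene[up], down = deTable$gene[down], table = deTable)
}

#' Two-group negative-binomial exact test
#'
#' Simple DE route for fully synthetic runs: edgeR's exact negative-binomial
#' test with TMM library normalization and a common dispersion, followed by
#' Benjamini-Hochberg adjustment. Real analyses are expected to supply an
#' externally produced DE table to [callDE()] instead.
#'
#' @param counts genes x samples integer matrix.
#' @param group two-level factor/character of sample conditions; fold changes
#'   are level 2 versus level 1.
#' @return data.frame with columns `gene`, `log2FC`, `PValue`, `FDR`.
#' @export
nbExactTest <- function(counts, group) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required", call. = FALSE)
  y <- edgeR::DGEList(counts = counts, group = group)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  y <- edgeR::estimateCommonDisp(y)
  et <- edgeR::exactTest(y)
  tab <- et$table
  data.frame(gene = rownames(tab), log2FC = tab$logFC, PValue = tab$PValue,
             FDR = p.adjust(tab$PValue, method = "BH"), row.names = NULL)
}

#' Overlap of bound genes with differential-expression sets
#'
#' Reports the fraction of bound genes that are down- (and up-) regulated,
#' 2x2 contingency tables against the gene universe, and one-sided
#' hypergeometric enrichment p-values.
#'
#' @param boundGenes character vector of bound genes (nonempty).
#' @param deSets list with character vectors `up` and `down`.
#' @param universe character vector of all genes under consideration.
#' @return list with `downFraction`, `upFraction`, `tables` (list of 2x2
#'   matrices), `pDown`, `pUp`, and the counts used.
#' @export
boundDeOverlap <- function(boundGenes, deSets, universe) {
  boundGenes <- unique(boundGenes)
  universe <- unique(universe)
  if (!length(boundGenes))
    stop("bound gene set is empty; overlap fractions are undefined",
         call. = FALSE)
  boundGenes <- intersect(boundGenes, universe)
  if (!length(boundGenes))
    stop("no bound gene lies in the supplied universe", call. = FALSE)
  one <- function(set) {
    set <- intersect(unique(set), universe)
    k <- length(intersect(boundGenes, set))
    tab <- matrix(c(k, length(boundGenes) - k,
                    length(set) - k,
                    length(universe) - length(set) - length(boundGenes) + k),
                  nrow = 2L,
                  dimnames = list(c("de", "notDe"), c("bound", "notBound")))
    p <- phyper(k - 1L, length(set), length(universe) - length(set),
                length(boundGenes), lower.tail = FALSE)
    list(fraction = k / length(boundGenes), table = tab, p = p, overlap = k)
  }
  dn <- one(deSets$down)
  up <- one(deSets$up)
  list(downFraction = dn$fraction, upFraction = up$fraction,
       tables = list(down = dn$table, up = up$table),
       pDown = dn$p, pUp = up$p,
       nBound = length(boundGenes), nUniverse = length(universe),
       nDown = length(intersect(deSets$down, universe)),
       nUp = length(intersect(deSets$up, universe)),
       downOverlap = dn$overlap, upOverlap = up$overlap)
}
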