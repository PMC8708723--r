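#' @importFrom stats rnorm runif rnbinom rexp
NULL

#' Simulation configuration
#'
#' Holds every knob of the synthetic-data generators and fixes all
#' randomness through a single seed. Defaults describe a desk-scale study:
#' two 5 Mb chromosomes, 300 genes on the first (the second hosts the
#' co-binding landscape), a 13-factor TF panel in two co-binding groups, a
#' 928-peak target-factor landscape with class proportions mirroring a
#' promoter-dominated binding profile (PLS 0.48, pELS 0.134, dELS 0.097),
#' a 500-shared / 250-private replicate design, four-vs-four NB counts at
#' dispersion 0.1, and an NCGGAAMM target motif planted in 30% of target
#' peaks.
#'
#' @slot seed integer; fixes all randomness end to end.
#' @slot chromLengths named chromosome lengths (bp).
#' @slot nGenes,nTfs,nGroups annotation and panel sizes.
#' @slot peakWidth peak width in bp.
#' @slot nCcrePeaks target-factor peak count for the class landscape.
#' @slot classProportions named fractions for PLS, pELS, dELS,
#'   DNase-H3K4me3, DNase-only (remainder is unclassified).
#' @slot nSharedPeaks,nPrivatePeaks replicate-consensus design.
#' @slot replicateJitterBp uniform summit jitter between replicate calls.
#' @slot dropoutRate per-peak replicate dropout probability.
#' @slot nCobindRegions,regionWidth co-binding landscape.
#' @slot withinGroupShare fraction of the group pool each factor binds.
#' @slot withinGroupCor latent log-signal correlation within a group
#'   (between groups it is 0).
#' @slot targetsPerTf planted regulatory targets per factor.
#' @slot edgeJitterBp jitter of planted-edge peak positions.
#' @slot countGenes,nSamplesPerGroup,nbDispersion,deFraction,deLog2fc,
#'   libFactors count-matrix design (`libFactors` recycles over samples).
#' @slot motifConsensus,motifRateFg,motifRateBg,seqLength,nSeqPerArm
#'   motif-enrichment design.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    seed = "numeric",
    chromLengths = "numeric",
    nGenes = "numeric", nTfs = "numeric", nGroups = "numeric",
    peakWidth = "numeric",
    nCcrePeaks = "numeric", classProportions = "numeric",
    nSharedPeaks = "numeric", nPrivatePeaks = "numeric",
    replicateJitterBp = "numeric", dropoutRate = "numeric",
    nCobindRegions = "numeric", regionWidth = "numeric",
    withinGroupShare = "numeric", withinGroupCor = "numeric",
    targetsPerTf = "numeric", edgeJitterBp = "numeric",
    countGenes = "numeric", nSamplesPerGroup = "numeric",
    nbDispersion = "numeric", deFraction = "numeric", deLog2fc = "numeric",
    libFactors = "numeric",
    motifConsensus = "character", motifRateFg = "numeric",
    motifRateBg = "numeric", seqLength = "numeric", nSeqPerArm = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  p <- object@classProportions
  if (any(p < 0 | p > 1) || sum(p) > 1 + 1e-9)
    msg <- c(msg, "class proportions must lie in [0,1] and sum to <= 1")
  if (!all(c("PLS", "pELS", "dELS") %in% names(p)))
    msg <- c(msg, "classProportions must name PLS, pELS and dELS")
  if (any(object@chromLengths <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (object@withinGroupCor < 0 || object@withinGroupCor > 1)
    msg <- c(msg, "withinGroupCor must lie in [0,1]")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in [0,1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed", object@seed, "|", length(object@chromLengths),
      "chromosomes |", object@nGenes, "genes |", object@nTfs, "TFs in",
      object@nGroups, "groups |", object@nCcrePeaks, "target peaks\n")
})

#' @param ... slot overrides, see the class slots.
#' @rdname SimConfig-class
#' @export
simConfig <- function(...) {
  defaults <- list(
    seed = 1,
    chromLengths = c(chr1 = 5e6, chr2 = 5e6),
    nGenes = 300, nTfs = 13, nGroups = 2,
    peakWidth = 200,
    nCcrePeaks = 928,
    classProportions = c(PLS = 0.48, pELS = 0.134, dELS = 0.097,
                         `DNase-H3K4me3` = 0.12, `DNase-only` = 0.08),
    nSharedPeaks = 500, nPrivatePeaks = 250,
    replicateJitterBp = 50, dropoutRate = 0,
    nCobindRegions = 600, regionWidth = 300,
    withinGroupShare = 0.8, withinGroupCor = 0.8,
    targetsPerTf = 30, edgeJitterBp = 0,
    countGenes = 2000, nSamplesPerGroup = 4,
    nbDispersion = 0.1, deFraction = 0.15, deLog2fc = 2,
    libFactors = 1,
    motifConsensus = "NCGGAAMM", motifRateFg = 0.3, motifRateBg = 0.05,
    seqLength = 200, nSeqPerArm = 200
  )
  args <- list(...)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("unknown SimConfig field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vals <- utils::modifyList(defaults, args)
  do.call(new, c(list("SimConfig"), vals))
}

## Per-gene anchor layout on chr1; all element offsets are relative to the
## TSS and chosen so elements are disjoint and classes geometrically valid.
geneSpacing <- function(config) {
  floor(config@chromLengths[[1L]] / (config@nGenes + 1L))
}

#' Simulate the annotation landscape
#'
#' Places `nGenes` TSS on the first chromosome on a regular grid with small
#' jitter (no collisions), and builds a cCRE catalog around them: a 600 bp
#' promoter (PLS) element at each TSS, a proximal enhancer (pELS) 1.2 kb
#' downstream, a DNase-H3K4me3 element 1 kb upstream, a DNase-only element
#' 4 kb upstream, and a distal enhancer (dELS) 8 kb downstream (beyond the
#' 2 kb proximal cutoff of every TSS). Planted max-Z scores are +3 for
#' "high" and -1 for "low" assays, outside the classification ambiguity
#' band, so [classifyElements()] recovers every planted class.
#'
#' @param config a [simConfig()].
#' @return list with `seqinfo`, `tss` (`GRanges` with `gene_id`), and
#'   `ccre` (`GRanges` with `class`, z-score columns, and `gene_id`).
#' @export
simulateAnnotation <- function(config) {
  withSeed(config@seed, {
    si <- Seqinfo(names(config@chromLengths),
                  as.integer(config@chromLengths))
    nG <- as.integer(config@nGenes)
    if (nG == 0L) {
      tss <- GRanges(seqinfo = si)
      mcols(tss) <- DataFrame(gene_id = character())
      ccre <- GRanges(seqinfo = si)
      mcols(ccre) <- DataFrame(class = character())
      return(list(seqinfo = si, tss = tss, ccre = ccre))
    }
    spacing <- geneSpacing(config)
    if (spacing < 15000)
      stop("genome too small for the requested gene density; need at least ",
           15000 * (nG + 1L), " bp on the first chromosome", call. = FALSE)
    pos <- as.integer(seq_len(nG) * spacing +
                        round(runif(nG, -500, 500)))
    strand <- sample(c("+", "-"), nG, replace = TRUE)
    gene <- sprintf("g%03d", seq_len(nG))
    chr <- names(config@chromLengths)[1L]
    tss <- GRanges(chr, IRanges(pos, pos), strand = strand, seqinfo = si)
    tss$gene_id <- gene
    mk <- function(center, halfWidth, class, dn, k4, k27) {
      gr <- GRanges(chr, IRanges(center - halfWidth, center + halfWidth),
                    seqinfo = si)
      gr$class <- class
      gr$dnaseZ <- dn; gr$h3k4me3Z <- k4; gr$h3k27acZ <- k27
      gr$gene_id <- gene
      gr
    }
    hi <- 3; lo <- -1
    ccre <- c(
      mk(pos, 300L, "PLS", hi, hi, lo),
      mk(pos + 1200L, 150L, "pELS", hi, lo, hi),
      mk(pos - 1000L, 100L, "DNase-H3K4me3", hi, hi, lo),
      mk(pos - 4000L, 100L, "DNase-only", hi, lo, lo),
      mk(pos + 8000L, 150L, "dELS", hi, lo, hi)
    )
    ccre <- sort(ccre, ignore.strand = TRUE)
    list(seqinfo = si, tss = tss, ccre = ccre)
  })
}

## Deterministic per-class peak counts for the class landscape.
classPeakCounts <- function(config) {
  n <- as.integer(config@nCcrePeaks)
  p <- config@classProportions
  counts <- round(p * n)
  counts <- c(counts, unclassified = n - sum(counts))
  counts
}

#' Simulate the target-factor peak landscape over the cCRE catalog
#'
#' Plants exactly `round(proportion * n)` peaks per class (deterministic
#' counts; random element choice and sub-element jitter), centering each
#' peak on an element of the planted class; the unclassified remainder is
#' placed midway between gene neighborhoods, clear of every catalog
#' element.
#'
#' @param config a [simConfig()].
#' @param annotation result of [simulateAnnotation()].
#' @return `GRanges` of peaks with `name`, `score`, `summitOffset`, `rank`
#'   and the planted `trueClass`.
#' @export
simulateCcrePeaks <- function(config, annotation) {
  withSeed(config@seed + 1, {
    counts <- classPeakCounts(config)
    ccre <- annotation$ccre
    w <- as.integer(config@peakWidth)
    half <- w %/% 2L
    centers <- integer(); classes <- character()
    for (cls in names(counts)) {
      k <- counts[[cls]]
      if (k == 0L) next
      if (cls == "unclassified") {
        anchors <- start(annotation$tss) + 10500L
        cc <- sample(anchors, k, replace = TRUE) +
          as.integer(round(runif(k, -200, 200)))
      } else {
        el <- ccre[ccre$class == cls]
        pick <- sample(length(el), k, replace = TRUE)
        cc <- as.integer((start(el[pick]) + end(el[pick])) %/% 2L +
                           round(runif(k, -30, 30)))
      }
      centers <- c(centers, cc)
      classes <- c(classes, rep(cls, k))
    }
    chr <- names(config@chromLengths)[1L]
    gr <- GRanges(chr, IRanges(centers - half, centers + half - 1L),
                  seqinfo = annotation$seqinfo)
    gr$name <- sprintf("target_%04d", seq_along(gr))
    gr$score <- round(rexp(length(gr), rate = 0.2) + 1, 3)
    gr$summitOffset <- rep(as.integer(half), length(gr))
    gr$trueClass <- classes
    o <- order(as.character(seqnames(gr)), start(gr))
    gr <- gr[o]
    gr$rank <- rankPeaks(gr$score)
    gr
  })
}

#' Simulate a two-replicate peak-call pair with planted shared peaks
#'
#' `nSharedPeaks` true peaks appear in both replicates (positions jittered
#' independently by up to `replicateJitterBp`, scores correlated);
#' `nPrivatePeaks` further peaks are private to each replicate. All peaks
#' occupy distinct slots of a coarse grid, so no private peak reciprocally
#' overlaps anything in the other replicate. Optional dropout removes
#' shared peaks from one replicate at `dropoutRate`.
#'
#' @param config a [simConfig()].
#' @param seed optional seed override.
#' @return list with `repA`, `repB` (peak `GRanges`) and bookkeeping
#'   `nShared`, `sharedNames`.
#' @export
simulateReplicatePair <- function(config, seed = config@seed + 2) {
  withSeed(seed, {
    nS <- as.integer(config@nSharedPeaks)
    nP <- as.integer(config@nPrivatePeaks)
    w <- as.integer(config@peakWidth)
    j <- as.integer(config@replicateJitterBp)
    chr <- names(config@chromLengths)[1L]
    total <- nS + 2L * nP
    spacing <- max(2L * (w + 2L * j), 1000L)
    if (total * spacing > config@chromLengths[[1L]])
      stop("genome too small for the requested peak density; need at least ",
           total * spacing, " bp", call. = FALSE)
    slots <- sample(seq_len(total)) * spacing
    si <- Seqinfo(names(config@chromLengths), as.integer(config@chromLengths))
    mkPeaks <- function(centers, names, scores) {
      gr <- GRanges(chr, IRanges(centers - w %/% 2L,
                                 centers + w %/% 2L - 1L), seqinfo = si)
      gr$name <- names
      gr$score <- scores
      gr$summitOffset <- rep(w %/% 2L, length(gr))
      gr <- sort(gr, ignore.strand = TRUE)
      gr$rank <- rankPeaks(gr$score)
      gr
    }
    base <- rexp(nS, rate = 0.1) + 1
    sharedA <- slots[seq_len(nS)] +
      as.integer(round(runif(nS, -j, j)))
    sharedB <- slots[seq_len(nS)] +
      as.integer(round(runif(nS, -j, j)))
    keepA <- runif(nS) >= config@dropoutRate
    keepB <- runif(nS) >= config@dropoutRate
    privA <- slots[nS + seq_len(nP)]
    privB <- slots[nS + nP + seq_len(nP)]
    scoresA <- c(base[keepA] * (1 + rnorm(sum(keepA), 0, 0.05)),
                 rexp(nP, rate = 0.5) + 0.5)
    scoresB <- c(base[keepB] * (1 + rnorm(sum(keepB), 0, 0.05)),
                 rexp(nP, rate = 0.5) + 0.5)
    sharedNames <- sprintf("shared_%04d", seq_len(nS))
    repA <- mkPeaks(c(sharedA[keepA], privA),
                    c(sharedNames[keepA], sprintf("privA_%04d", seq_len(nP))),
                    round(pmax(scoresA, 0.1), 3))
    repB <- mkPeaks(c(sharedB[keepB], privB),
                    c(sharedNames[keepB], sprintf("privB_%04d", seq_len(nP))),
                    round(pmax(scoresB, 0.1), 3))
    list(repA = repA, repB = repB, nShared = sum(keepA & keepB),
         sharedNames = sharedNames)
  })
}

#' Simulate the co-binding landscape of a TF panel
#'
#' Factors are split round-robin into `nGroups` groups; regions on the
#' second chromosome are divided into disjoint per-group pools. Each factor
#' binds a random `withinGroupShare` fraction of its group pool. Bound
#' log-signals share a latent per-(group, region) component with weight
#' `sqrt(withinGroupCor)`, so within-group signals correlate at about
#' `withinGroupCor` and between-group signals are independent. Signal
#' tracks are rectangular fold-enrichment blocks over the bound regions.
#'
#' @param config a [simConfig()].
#' @param seed optional seed override.
#' @return list with `peakSets` (named list of `GRanges`), `tracks` (named
#'   list of signal `GRanges`), `groups` (named integer vector), and
#'   `regions`.
#' @export
simulateCobinding <- function(config, seed = config@seed + 3) {
  withSeed(seed, {
    nR <- as.integer(config@nCobindRegions)
    nT <- as.integer(config@nTfs)
    nG <- as.integer(config@nGroups)
    w <- as.integer(config@regionWidth)
    chr <- names(config@chromLengths)[min(2L, length(config@chromLengths))]
    len <- config@chromLengths[[chr]]
    spacing <- floor(len / (nR + 1L))
    if (spacing < 2L * w)
      stop("chromosome too small for the requested region count",
           call. = FALSE)
    si <- Seqinfo(names(config@chromLengths), as.integer(config@chromLengths))
    starts <- as.integer(seq_len(nR) * spacing)
    regions <- GRanges(chr, IRanges(starts, starts + w - 1L), seqinfo = si)
    tfs <- sprintf("TF%02d", seq_len(nT))
    groups <- rep(seq_len(nG), length.out = nT)
    names(groups) <- tfs
    pool <- rep(seq_len(nG), length.out = nR)  # region -> group pool
    rho <- config@withinGroupCor
    latent <- matrix(rnorm(nR * nG), nR, nG)
    peakSets <- list(); tracks <- list()
    for (i in seq_len(nT)) {
      g <- groups[i]
      mine <- which(pool == g)
      bound <- sort(sample(mine, round(config@withinGroupShare * length(mine))))
      logsig <- sqrt(rho) * latent[bound, g] +
        sqrt(1 - rho) * rnorm(length(bound))
      sig <- round(exp(0.5 * logsig + 1), 4)
      pk <- regions[bound]
      pk$name <- sprintf("%s_%04d", tfs[i], seq_along(pk))
      pk$score <- sig
      pk$summitOffset <- rep(w %/% 2L, length(pk))
      pk$rank <- rankPeaks(pk$score)
      peakSets[[tfs[i]]] <- pk
      tr <- granges(regions[bound])
      tr$score <- sig
      tracks[[tfs[i]]] <- tr
    }
    list(peakSets = peakSets, tracks = tracks, groups = groups,
         regions = regions)
  })
}

#' Simulate planted regulatory edges and the supporting peaks
#'
#' The first `nTfs` genes encode the TF panel (factor names are their gene
#' ids, so self-regulatory loops arise naturally). Each factor receives
#' `targetsPerTf` planted target genes; each planted edge is realized as a
#' peak centered on the target gene's promoter (PLS) element, jittered by
#' up to `edgeJitterBp`.
#'
#' @param config a [simConfig()].
#' @param annotation result of [simulateAnnotation()].
#' @param jitterBp overrides `config@edgeJitterBp`.
#' @param seed optional seed override.
#' @return list with `peakSets` (named list of `GRanges`), `edges`
#'   (data.frame `source`, `target`), and `tfs`.
#' @export
simulateNetworkData <- function(config, annotation,
                                jitterBp = config@edgeJitterBp,
                                seed = config@seed + 4) {
  withSeed(seed, {
    nT <- as.integer(config@nTfs)
    genes <- annotation$tss$gene_id
    if (length(genes) < nT)
      stop("need at least as many genes as TFs", call. = FALSE)
    tfs <- genes[seq_len(nT)]
    pls <- annotation$ccre[annotation$ccre$class == "PLS"]
    plsCenter <- (start(pls) + end(pls)) %/% 2L
    names(plsCenter) <- pls$gene_id
    w <- as.integer(config@peakWidth)
    half <- w %/% 2L
    chr <- names(config@chromLengths)[1L]
    edges <- list(); peakSets <- list()
    for (tf in tfs) {
      targets <- sort(sample(genes, min(config@targetsPerTf, length(genes))))
      cc <- plsCenter[targets] +
        as.integer(round(runif(length(targets), -jitterBp, jitterBp)))
      pk <- GRanges(chr, IRanges(cc - half, cc + half - 1L),
                    seqinfo = annotation$seqinfo)
      pk$name <- sprintf("%s_pk%03d", tf, seq_along(pk))
      pk$score <- round(rexp(length(pk), 0.2) + 1, 3)
      pk$summitOffset <- rep(half, length(pk))
      pk <- sort(pk, ignore.strand = TRUE)
      pk$rank <- rankPeaks(pk$score)
      peakSets[[tf]] <- pk
      edges[[tf]] <- data.frame(source = tf, target = targets)
    }
    list(peakSets = peakSets,
         edges = do.call(rbind, c(edges, list(make.row.names = FALSE))),
         tfs = tfs)
  })
}

#' Simulate a count matrix with planted DE genes and scaling factors
#'
#' Negative-binomial counts for a two-condition design
#' (`nSamplesPerGroup` control then treated samples). Per-gene baseline
#' means are log-normal; a `deFraction` of genes receives a `+/- deLog2fc`
#' log2 fold change in the treated group (up and down in equal numbers).
#' `libFactors` (recycled over samples) scale every gene's mean in a
#' sample, planting total-abundance factors recoverable by [tmmFactors()].
#'
#' @param config a [simConfig()].
#' @param nGenes,deFraction,libFactors,nSamplesPerGroup overrides of the
#'   config fields.
#' @param geneIds optional gene identifiers (overrides `nGenes`), used to
#'   tie the count matrix to an annotation's gene universe.
#' @param seed optional seed override.
#' @return list with `counts`, `group`, `trueFactors` (geometric mean 1),
#'   `trueDe` (data.frame `gene`, `label` in up/down/ns, `log2fc`).
#' @export
simulateCounts <- function(config, nGenes = config@countGenes,
                           deFraction = config@deFraction,
                           libFactors = config@libFactors,
                           nSamplesPerGroup = config@nSamplesPerGroup,
                           geneIds = NULL,
                           seed = config@seed + 5) {
  withSeed(seed, {
    nGenes <- if (is.null(geneIds)) as.integer(nGenes) else length(geneIds)
    nS <- 2L * as.integer(nSamplesPerGroup)
    s <- rep_len(libFactors, nS)
    group <- rep(c("ctrl", "kd"), each = nSamplesPerGroup)
    mu <- exp(rnorm(nGenes, log(100), 1))
    nDe <- round(deFraction * nGenes)
    lfc <- numeric(nGenes)
    if (nDe > 0) {
      de <- sample(nGenes, nDe)
      half <- length(de) %/% 2L
      lfc[de[seq_len(half)]] <- config@deLog2fc
      if (length(de) > half) lfc[de[(half + 1L):length(de)]] <- -config@deLog2fc
    }
    size <- 1 / config@nbDispersion
    counts <- matrix(0L, nGenes, nS)
    for (j in seq_len(nS)) {
      m <- mu * s[j] * (if (group[j] == "kd") 2^lfc else 1)
      counts[, j] <- rnbinom(nGenes, mu = m, size = size)
    }
    rownames(counts) <- if (is.null(geneIds)) {
      sprintf("gene%05d", seq_len(nGenes))
    } else {
      geneIds
    }
    colnames(counts) <- paste0(group, rep(seq_len(nSamplesPerGroup), 2L))
    label <- ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "ns"))
    list(counts = counts, group = group,
         trueFactors = structure(s / geomean(s), names = colnames(counts)),
         trueDe = data.frame(gene = rownames(counts), label = label,
                             log2fc = lfc))
  })
}

## Draw one concrete instance of an IUPAC consensus.
sampleMotifInstance <- function(motif) {
  sets <- iupacSets()
  codes <- strsplit(if (is(motif, "IupacMotif")) motif@consensus else motif,
                    "")[[1]]
  paste(vapply(codes, function(cd) {
    s <- sets[[cd]]
    s[sample.int(length(s), 1L)]
  }, ""), collapse = "")
}

randomSequences <- function(n, len) {
  if (n == 0L) return(character())
  ch <- sample(c("A", "C", "G", "T"), n * len, replace = TRUE)
  do.call(paste0, asplit(matrix(ch, nrow = n, ncol = len), 2L))
}

#' Simulate foreground/background sequence arms with planted motifs
#'
#' Random ACGT sequences; a motif instance (a concrete realization of the
#' consensus) is planted at a random interior position in `motifRateFg` of
#' foreground and `motifRateBg` of background sequences.
#'
#' @param config a [simConfig()].
#' @param rateFg,rateBg,n,len overrides of the config fields.
#' @param nBg background arm size (defaults to `n`; a larger background
#'   sharpens the estimated background hit fraction).
#' @param seed optional seed override.
#' @return list with character vectors `foreground`, `background` and
#'   logical vectors `plantedFg`, `plantedBg`.
#' @export
simulateMotifSequences <- function(config, rateFg = config@motifRateFg,
                                   rateBg = config@motifRateBg,
                                   n = config@nSeqPerArm,
                                   nBg = n,
                                   len = config@seqLength,
                                   seed = config@seed + 6) {
  withSeed(seed, {
    motif <- iupacMotif(config@motifConsensus)
    L <- nchar(motif@consensus)
    plant <- function(seqs, rate) {
      planted <- runif(length(seqs)) < rate
      for (i in which(planted)) {
        pos <- sample.int(nchar(seqs[i]) - L + 1L, 1L)
        substr(seqs[i], pos, pos + L - 1L) <- sampleMotifInstance(motif)
      }
      list(seqs = seqs, planted = planted)
    }
    fg <- plant(randomSequences(n, len), rateFg)
    bg <- plant(randomSequences(nBg, len), rateBg)
    list(foreground = fg$seqs, background = bg$seqs,
         plantedFg = fg$planted, plantedBg = bg$planted)
  })
}

#' Simulate a genome sequence consistent with an annotation
#'
#' Random ACGT chromosomes, with a motif instance written at the center of
#' each peak selected for planting.
#'
#' @param config a [simConfig()].
#' @param plantAt optional `GRanges` of peaks whose centers receive a motif
#'   instance (a `motifRateFg` fraction, sampled).
#' @param seed optional seed override.
#' @return named character vector of chromosome sequences.
#' @export
simulateGenomeSequence <- function(config, plantAt = NULL,
                                   seed = config@seed + 7) {
  withSeed(seed, {
    seqs <- vapply(config@chromLengths, function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, "")
    names(seqs) <- names(config@chromLengths)
    if (!is.null(plantAt) && length(plantAt)) {
      motif <- iupacMotif(config@motifConsensus)
      L <- nchar(motif@consensus)
      planted <- runif(length(plantAt)) < config@motifRateFg
      centers <- peakCenters(plantAt)
      chrom <- as.character(seqnames(plantAt))
      for (i in which(planted)) {
        pos <- centers[i] - L %/% 2L
        substr(seqs[[chrom[i]]], pos, pos + L - 1L) <-
          sampleMotifInstance(motif)
      }
      attr(seqs, "planted") <- planted
    }
    seqs
  })
}

#' Write a complete synthetic study to disk
#'
#' Emits, under `dir`: `chrom.sizes`, `tss.bed`, `ccre.bed`, a genome
#' `genome.fa` with the target motif planted under target-factor peaks,
#' per-factor replicate narrowPeak pairs and bedGraph tracks (the panel's
#' planted-edge peaks on chromosome 1 plus the co-binding landscape on
#' chromosome 2), the target factor's class-landscape replicate pair,
#' `counts.tsv`, and ground-truth tables under `truth/`. Every file parses
#' with the package's own readers, and identical configs give
#' byte-identical output.
#'
#' @param config a [simConfig()].
#' @param dir output directory (created).
#' @return invisibly, the list of truth objects.
#' @export
simulateStudy <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tfs"), showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  ann <- simulateAnnotation(config)
  writeChromSizes(ann$seqinfo, file.path(dir, "chrom.sizes"))
  writeTssBed(ann$tss, file.path(dir, "tss.bed"))
  writeCcreBed(ann$ccre, file.path(dir, "ccre.bed"))

  target <- simulateCcrePeaks(config, ann)
  net <- simulateNetworkData(config, ann)
  cob <- simulateCobinding(config)
  tfs <- net$tfs
  cobNames <- names(cob$peakSets)

  ## panel peak sets: planted-edge peaks (chr1) + co-binding peaks (chr2);
  ## the first factor additionally carries the class landscape
  manifest <- list()
  for (i in seq_along(tfs)) {
    tf <- tfs[i]
    pk <- c(net$peakSets[[tf]], cob$peakSets[[cobNames[i]]])
    if (i == 1L) {
      tgt <- target
      mcols(tgt) <- mcols(tgt)[, c("name", "score", "summitOffset", "rank")]
      pk <- c(pk, tgt)
    }
    pk <- sort(pk, ignore.strand = TRUE)
    pk$rank <- rankPeaks(pk$score)
    reps <- jitterReplicates(config, pk, seed = config@seed + 100 + i)
    p1 <- file.path("tfs", paste0(tf, "_rep1.narrowPeak"))
    p2 <- file.path("tfs", paste0(tf, "_rep2.narrowPeak"))
    writePeaks(reps$repA, file.path(dir, p1))
    writePeaks(reps$repB, file.path(dir, p2))
    tr <- granges(pk)
    tr$score <- pk$score
    tr <- mergeTrackBlocks(tr)
    tp <- file.path("tracks", paste0(tf, ".bedGraph"))
    writeBedGraph(tr, file.path(dir, tp))
    manifest[[i]] <- data.frame(factor = tf, rep1 = p1, rep2 = p2,
                                track = tp)
  }
  writeTsv(do.call(rbind, manifest), file.path(dir, "manifest.tsv"))

  genome <- simulateGenomeSequence(config, plantAt = target)
  writeFasta(genome, file.path(dir, "genome.fa"))

  cnt <- simulateCounts(config, geneIds = ann$tss$gene_id)
  counts <- data.frame(gene = rownames(cnt$counts), cnt$counts,
                       check.names = FALSE)
  writeTsv(counts, file.path(dir, "counts.tsv"))
  writeTsv(data.frame(sample = colnames(cnt$counts), group = cnt$group),
           file.path(dir, "samples.tsv"))

  writeTsv(data.frame(peak = target$name, class = target$trueClass),
           file.path(dir, "truth", "target_classes.tsv"))
  writeTsv(net$edges, file.path(dir, "truth", "edges.tsv"))
  writeTsv(data.frame(factor = cobNames, tf = tfs,
                      group = as.integer(cob$groups)),
           file.path(dir, "truth", "groups.tsv"))
  writeTsv(data.frame(sample = colnames(cnt$counts),
                      factor = cnt$trueFactors),
           file.path(dir, "truth", "factors.tsv"))
  writeTsv(cnt$trueDe, file.path(dir, "truth", "de_labels.tsv"))
  invisible(list(annotation = ann, target = target, network = net,
                 cobinding = cob, counts = cnt))
}

## Two jittered replicate call sets of one true peak set.
jitterReplicates <- function(config, peaks, seed) {
  withSeed(seed, {
    j <- config@replicateJitterBp
    one <- function(tag) {
      keep <- runif(length(peaks)) >= config@dropoutRate
      pk <- peaks[keep]
      shift <- as.integer(round(runif(length(pk), -j, j)))
      out <- GRanges(seqnames(pk),
                     IRanges(start(pk) + shift, end(pk) + shift),
                     seqinfo = seqinfo(pk))
      out$name <- paste0(pk$name, "_", tag)
      out$score <- round(pk$score * (1 + rnorm(length(pk), 0, 0.05)), 4)
      out$score <- pmax(out$score, 0.01)
      out$summitOffset <- pk$summitOffset
      out <- sort(out, ignore.strand = TRUE)
      out$rank <- rankPeaks(out$score)
      out
    }
    list(repA = one("a"), repB = one("b"))
  })
}

## Flatten possibly overlapping signal blocks into a valid non-overlapping
## bedGraph (overlapping block values add, coverage-style; zero runs drop).
mergeTrackBlocks <- function(track) {
  if (length(track) < 2L) return(track)
  cvgList <- trackCoverage(track, unique(as.character(seqnames(track))))
  res <- list()
  for (chr in names(cvgList)) {
    r <- cvgList[[chr]]
    v <- S4Vectors::runValue(r)
    l <- S4Vectors::runLength(r)
    ends <- cumsum(l)
    starts <- ends - l + 1L
    keep <- v != 0
    if (!any(keep)) next
    gr <- GRanges(chr, IRanges(starts[keep], ends[keep]))
    gr$score <- v[keep]
    res[[chr]] <- gr
  }
  if (!length(res)) return(GRanges(score = numeric()))
  out <- sort(unlist(GenomicRanges::GRangesList(res), use.names = FALSE),
              ignore.strand = TRUE)
  seqinfo(out) <- seqinfo(track)
  out
}
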