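#' @import methods
#' @importFrom GenomicRanges GRanges
NULL

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Parameters for replicate-consensus peak selection
#'
#' Holds the thresholds of the simplified reproducibility rule used in place
#' of the full IDR model: a reciprocal-overlap requirement for matching peaks
#' across replicates, the fraction of top-ranked peaks eligible for the
#' conservative set, and the minimum rank correlation below which the
#' replicate pair is flagged as discordant.
#'
#' @slot minReciprocalOverlap fraction in (0, 1]; a matched pair must share at
#'   least this fraction of *each* member's length.
#' @slot maxRankFraction fraction in (0, 1]; both members of a retained pair
#'   must lie within this top fraction of their replicate's score ranking.
#' @slot rankCorrelationMin value in [-1, 1]; Spearman rank correlation across
#'   matched pairs below which a concordance warning is raised.
#' @exportClass ConsensusParams
setClass("ConsensusParams",
  representation(
    minReciprocalOverlap = "numeric",
    maxRankFraction = "numeric",
    rankCorrelationMin = "numeric"
  )
)

setValidity("ConsensusParams", function(object) {
  msg <- character()
  ro <- object@minReciprocalOverlap
  if (length(ro) != 1L || !is.finite(ro) || ro <= 0 || ro > 1)
    msg <- c(msg, "minReciprocalOverlap must be in (0, 1]")
  rf <- object@maxRankFraction
  if (length(rf) != 1L || !is.finite(rf) || rf <= 0 || rf > 1)
    msg <- c(msg, "maxRankFraction must be in (0, 1]")
  rc <- object@rankCorrelationMin
  if (length(rc) != 1L || !is.finite(rc) || rc < -1 || rc > 1)
    msg <- c(msg, "rankCorrelationMin must be in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @param minReciprocalOverlap,maxRankFraction,rankCorrelationMin see slots.
#' @rdname ConsensusParams-class
#' @export
consensusParams <- function(minReciprocalOverlap = 0.5,
                            maxRankFraction = 1.0,
                            rankCorrelationMin = 0.5) {
  new("ConsensusParams",
    minReciprocalOverlap = minReciprocalOverlap,
    maxRankFraction = maxRankFraction,
    rankCorrelationMin = rankCorrelationMin
  )
}

#' Parameters for cCRE classification
#'
#' Distance and signal thresholds of the SCREEN-style classification rules.
#' Promoter-like signatures (PLS) must fall within `tssProximalBp` of a TSS
#' (center to center); enhancer-like signatures are split into proximal and
#' distal at `elsProximalBp`. A max-Z score is called "high" at or above
#' `highZ` and "low" below `lowZ`.
#'
#' @slot tssProximalBp center-to-center distance (bp) defining promoter
#'   proximity; default 200.
#' @slot elsProximalBp center-to-center distance (bp) splitting proximal from
#'   distal enhancer-like signatures; default 2000.
#' @slot highZ z-score at or above which a signal is "high"; default 1.64.
#' @slot lowZ z-score below which a signal is "low"; default 1.64 (single cut).
#' @exportClass CcreParams
setClass("CcreParams",
  representation(
    tssProximalBp = "numeric",
    elsProximalBp = "numeric",
    highZ = "numeric",
    lowZ = "numeric"
  )
)

setValidity("CcreParams", function(object) {
  msg <- character()
  if (object@tssProximalBp <= 0 || object@elsProximalBp <= 0)
    msg <- c(msg, "distances must be positive")
  if (object@lowZ > object@highZ)
    msg <- c(msg, "lowZ must not exceed highZ")
  if (length(msg)) msg else TRUE
})

#' @param tssProximalBp,elsProximalBp,highZ,lowZ see slots.
#' @rdname CcreParams-class
#' @export
ccreParams <- function(tssProximalBp = 200, elsProximalBp = 2000,
                       highZ = 1.64, lowZ = 1.64) {
  new("CcreParams",
    tssProximalBp = tssProximalBp, elsProximalBp = elsProximalBp,
    highZ = highZ, lowZ = lowZ
  )
}

#' Parameters for basal-plus-extension regulatory domains
#'
#' GREAT-style defaults: a basal domain from 5 kb upstream to 1 kb downstream
#' of the TSS (strand-aware), extended outward up to 1 Mb but stopping at the
#' nearest neighboring gene's basal domain.
#'
#' @slot upstreamBp bp upstream of the TSS in the basal domain.
#' @slot downstreamBp bp downstream of the TSS in the basal domain.
#' @slot maxExtensionBp maximum outward extension in bp.
#' @exportClass DomainParams
setClass("DomainParams",
  representation(
    upstreamBp = "numeric",
    downstreamBp = "numeric",
    maxExtensionBp = "numeric"
  )
)

setValidity("DomainParams", function(object) {
  if (object@upstreamBp <= 0 || object@downstreamBp <= 0) {
    "basal distances must be positive"
  } else if (object@maxExtensionBp < 0) {
    "maximum extension must be nonnegative (0 keeps basal domains only)"
  } else {
    TRUE
  }
})

#' @param upstreamBp,downstreamBp,maxExtensionBp see slots.
#' @rdname DomainParams-class
#' @export
domainParams <- function(upstreamBp = 5000, downstreamBp = 1000,
                         maxExtensionBp = 1e6) {
  new("DomainParams",
    upstreamBp = upstreamBp, downstreamBp = downstreamBp,
    maxExtensionBp = maxExtensionBp
  )
}

#' Parameters for expression filtering and differential-expression calls
#'
#' @slot fdrMax FDR threshold for a significant call; default 0.05.
#' @slot minAbsLog2fc minimum absolute log2 fold change; default 0.2.
#' @slot cpmMin CPM threshold for the low-expression filter; default 1.
#' @slot minSamples minimum number of samples at or above `cpmMin`; default 3.
#' @exportClass DEParams
setClass("DEParams",
  representation(
    fdrMax = "numeric",
    minAbsLog2fc = "numeric",
    cpmMin = "numeric",
    minSamples = "numeric"
  )
)

setValidity("DEParams", function(object) {
  vals <- c(object@fdrMax, object@minAbsLog2fc, object@cpmMin,
            object@minSamples)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    "all DE parameters must be positive and finite"
  } else {
    TRUE
  }
})

#' @param fdrMax,minAbsLog2fc,cpmMin,minSamples see slots.
#' @rdname DEParams-class
#' @export
deParams <- function(fdrMax = 0.05, minAbsLog2fc = 0.2, cpmMin = 1,
                     minSamples = 3) {
  new("DEParams",
    fdrMax = fdrMax, minAbsLog2fc = minAbsLog2fc, cpmMin = cpmMin,
    minSamples = minSamples
  )
}

## ---------------------------------------------------------------------------
## Result classes
## ---------------------------------------------------------------------------

#' High-confidence consensus peaks from a replicate pair
#'
#' Result of the simplified reproducibility procedure: reciprocal-overlap
#' matched peak pairs, filtered to the top rank fraction of both replicates.
#' `peaks` holds one merged interval per retained pair with the mean member
#' score and a reproducibility score `min(1 - rank/n)` over the two members.
#'
#' @slot peaks `GRanges` of consensus peaks (mcols: `name`, `score`,
#'   `reproducibility`, `rankA`, `rankB`).
#' @slot pairs data.frame of all matched pairs before the rank filter.
#' @slot rankCorrelation Spearman correlation of member ranks across matched
#'   pairs (`NA` when fewer than two pairs).
#' @slot params the `ConsensusParams` used.
#' @slot nRepA,nRepB input peak counts per replicate.
#' @exportClass ConsensusPeaks
setClass("ConsensusPeaks",
  representation(
    peaks = "GRanges",
    pairs = "data.frame",
    rankCorrelation = "numeric",
    params = "ConsensusParams",
    nRepA = "integer",
    nRepB = "integer"
  )
)

setValidity("ConsensusPeaks", function(object) {
  n <- length(object@peaks)
  if (n > min(object@nRepA, object@nRepB) && min(object@nRepA, object@nRepB) > 0)
    return("consensus cannot exceed the smaller replicate")
  TRUE
})

setMethod("show", "ConsensusPeaks", function(object) {
  cat("ConsensusPeaks:", length(object@peaks), "consensus peaks from",
      object@nRepA, "x", object@nRepB, "replicate peaks\n")
  cat("  matched pairs:", nrow(object@pairs),
      " rank correlation:", format(object@rankCorrelation, digits = 3), "\n")
})

#' @describeIn ConsensusPeaks-class the consensus `GRanges`.
#' @param x,object a `ConsensusPeaks`.
#' @export
consensusRanges <- function(x) x@peaks

#' @describeIn ConsensusPeaks-class Spearman correlation of member ranks.
#' @export
rankCorrelation <- function(x) x@rankCorrelation

#' Directed TF-to-target regulatory network
#'
#' Edge TF -> gene exists when the factor has at least one binding peak in a
#' promoter- or enhancer-like cCRE whose regulatory-domain association set
#' contains the gene. Edge weight is the number of supporting peaks; evidence
#' records the peak names and element classes.
#'
#' @slot edges data.frame with columns `source`, `target`, `weight` and a
#'   list column `evidence` of data.frames (`peak`, `class`).
#' @slot factors the TF panel (all sources, whether or not they gained edges).
#' @slot genes the target gene universe.
#' @exportClass RegulatoryNetwork
setClass("RegulatoryNetwork",
  representation(
    edges = "data.frame",
    factors = "character",
    genes = "character"
  )
)

setValidity("RegulatoryNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  need <- c("source", "target", "weight")
  if (!all(need %in% names(ed)))
    msg <- c(msg, "edges must have source/target/weight columns")
  else {
    if (nrow(ed) && any(ed$weight < 1))
      msg <- c(msg, "edge weights must be >= 1")
    if (nrow(ed) && !all(ed$source %in% object@factors))
      msg <- c(msg, "all edge sources must be panel factors")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork:", length(object@factors), "factors,",
      length(unique(object@edges$target)), "bound targets,",
      nrow(object@edges), "edges\n")
})

#' @describeIn RegulatoryNetwork-class edge table (without evidence column).
#' @param x a `RegulatoryNetwork`.
#' @export
networkEdges <- function(x) x@edges[, c("source", "target", "weight")]

#' @describeIn RegulatoryNetwork-class the TF panel.
#' @export
networkFactors <- function(x) x@factors

#' IUPAC consensus motif
#'
#' A degenerate nucleotide consensus such as `NCGGAAMM` (N = any base,
#' M = A or C). Matching tests each sequence base for membership in the
#' degeneracy set of the corresponding code.
#'
#' @slot consensus the consensus string, uppercase IUPAC codes.
#' @exportClass IupacMotif
setClass("IupacMotif", representation(consensus = "character"))

setValidity("IupacMotif", function(object) {
  cons <- object@consensus
  if (length(cons) != 1L || nchar(cons) == 0L)
    return("consensus must be a single nonempty string")
  codes <- strsplit(cons, "")[[1]]
  bad <- setdiff(codes, names(iupacSets()))
  if (length(bad))
    return(paste0("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", ")))
  TRUE
})

setMethod("show", "IupacMotif", function(object) {
  cat("IupacMotif:", object@consensus, "(length", nchar(object@consensus), ")\n")
})

#' @param consensus consensus string over IUPAC codes.
#' @rdname IupacMotif-class
#' @export
iupacMotif <- function(consensus) {
  new("IupacMotif", consensus = toupper(as.character(consensus)))
}

#' Motif enrichment result
#'
#' Sequence-level enrichment of a consensus motif in foreground versus
#' background sequences: counts of sequences with at least one hit, fold
#' enrichment of the hit fractions, and a one-sided binomial p-value of the
#' foreground fraction against the background fraction.
#'
#' @slot motif the consensus tested.
#' @slot fgHits,fgN,bgHits,bgN sequence-with-hit counts and totals.
#' @slot fold foreground fraction / background fraction (`Inf` flagged via
#'   `foldInfinite` when the background fraction is zero).
#' @slot pvalue one-sided binomial p-value.
#' @slot foldInfinite logical, `TRUE` when background had no hits but
#'   foreground did.
#' @exportClass MotifEnrichment
setClass("MotifEnrichment",
  representation(
    motif = "character",
    fgHits = "integer", fgN = "integer",
    bgHits = "integer", bgN = "integer",
    fold = "numeric", pvalue = "numeric",
    foldInfinite = "logical"
  )
)

setValidity("MotifEnrichment", function(object) {
  msg <- character()
  if (any(c(object@fgHits, object@fgN, object@bgHits, object@bgN) < 0))
    msg <- c(msg, "counts must be nonnegative")
  if (object@pvalue < 0 || object@pvalue > 1)
    msg <- c(msg, "p-value must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MotifEnrichment", function(object) {
  cat("MotifEnrichment:", object@motif, "\n")
  cat(sprintf("  foreground %d/%d  background %d/%d  fold %s  p = %.3g\n",
              object@fgHits, object@fgN, object@bgHits, object@bgN,
              if (object@foldInfinite) "Inf" else format(object@fold, digits = 3),
              object@pvalue))
})
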