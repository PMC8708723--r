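#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   reverseComplement
#' @importFrom stats binom.test
NULL

#' IUPAC degeneracy sets
#'
#' @return named list mapping each IUPAC code to its set of concrete bases.
#' @export
iupacSets <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
}

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

#' Reverse complement of an IUPAC consensus
#'
#' @param motif an [iupacMotif()] or consensus string.
#' @return an `IupacMotif`.
#' @export
reverseComplementMotif <- function(motif) {
  cons <- if (is(motif, "IupacMotif")) motif@consensus else toupper(motif)
  codes <- rev(strsplit(cons, "")[[1]])
  iupacMotif(paste(IUPAC_COMPLEMENT[codes], collapse = ""))
}

## Allowance matrix: rows = motif positions, columns = sequence-base classes
## A, C, G, T, other. A concrete base matches a code when it lies in the
## code's degeneracy set; any base outside ACGT (including N) matches only
## the code N.
motifAllowMatrix <- function(motif) {
  cons <- if (is(motif, "IupacMotif")) motif@consensus else
    iupacMotif(motif)@consensus
  codes <- strsplit(cons, "")[[1]]
  sets <- iupacSets()
  m <- matrix(FALSE, length(codes), 5L,
              dimnames = list(NULL, c("A", "C", "G", "T", "other")))
  for (k in seq_along(codes)) {
    m[k, sets[[codes[k]]]] <- TRUE
    m[k, "other"] <- codes[k] == "N"
  }
  m
}

## Byte-level class lookup (A/C/G/T/other), case-insensitive.
SEQ_CLASS_MAP <- local({
  map <- rep(5L, 256L)
  for (k in 1:4) {
    base <- c("A", "C", "G", "T")[k]
    map[utf8ToInt(base)] <- k
    map[utf8ToInt(tolower(base))] <- k
  }
  map
})

seqToClasses <- function(sequence) {
  code <- utf8ToInt(sequence)
  code[code < 1L | code > 256L] <- 1L  # non-ASCII -> "other"
  SEQ_CLASS_MAP[code]
}

#' Test a motif match at one position
#'
#' True when every sequence base lies in the degeneracy set of the
#' corresponding IUPAC code. On the reverse strand the reverse complement of
#' the window is tested (equivalently, the reverse-complemented motif is
#' matched forward). Sequence characters outside ACGT match only the code N.
#'
#' @param motif an [iupacMotif()] or consensus string.
#' @param sequence a single character string.
#' @param position 1-based start of the window.
#' @param strand `"+"` or `"-"`.
#' @return logical scalar.
#' @export
matchAt <- function(motif, sequence, position, strand = "+") {
  if (!is(motif, "IupacMotif")) motif <- iupacMotif(motif)
  L <- nchar(motif@consensus)
  if (position < 1L || position + L - 1L > nchar(sequence))
    stop("window [", position, ", ", position + L - 1L,
         "] outside sequence of length ", nchar(sequence), call. = FALSE)
  eff <- if (strand == "-") reverseComplementMotif(motif) else motif
  allow <- motifAllowMatrix(eff)
  idx <- seqToClasses(substr(sequence, position, position + L - 1L))
  all(allow[cbind(seq_len(L), idx)])
}

## Fast scan of one pre-classified sequence with a pre-built allow matrix.
scanClasses <- function(idx, allow) {
  L <- nrow(allow)
  n <- length(idx) - L + 1L
  if (n < 1L) return(integer())
  ok <- allow[1L, idx[seq_len(n)]]
  for (k in seq_len(L)[-1L]) {
    ok <- ok & allow[k, idx[seq.int(k, k + n - 1L)]]
  }
  which(ok)
}

#' Scan sequences for all motif hits
#'
#' Reports every (position, strand) with a match; overlapping hits are all
#' reported. Reverse-strand hit positions refer to the forward coordinate of
#' the window start.
#'
#' @param motif an [iupacMotif()] or consensus string.
#' @param sequences character vector (or `DNAStringSet`).
#' @param bothStrands scan the reverse strand too (default `TRUE`).
#' @return list (one element per sequence) of data.frames with columns
#'   `position`, `strand`.
#' @export
scanMotif <- function(motif, sequences, bothStrands = TRUE) {
  if (!is(motif, "IupacMotif")) motif <- iupacMotif(motif)
  if (is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  allowF <- motifAllowMatrix(motif)
  allowR <- motifAllowMatrix(reverseComplementMotif(motif))
  oddSeen <- FALSE
  out <- lapply(sequences, function(s) {
    idx <- seqToClasses(s)
    if (!oddSeen && any(idx == 5L)) {
      ch <- strsplit(toupper(s), "")[[1]]
      if (any(idx == 5L & ch != "N")) oddSeen <<- TRUE
    }
    posF <- scanClasses(idx, allowF)
    if (bothStrands) {
      posR <- scanClasses(idx, allowR)
      data.frame(position = c(posF, posR),
                 strand = rep(c("+", "-"), c(length(posF), length(posR))))
    } else {
      data.frame(position = posF, strand = rep("+", length(posF)))
    }
  })
  if (oddSeen)
    message("sequence characters outside ACGTN treated as matching only N")
  out
}

#' Count sequences with at least one motif hit
#'
#' Equivalent to counting nonempty [scanMotif()] results, but scans all
#' sequences in one pass: they are joined by a separator that matches no
#' IUPAC code, and hits whose window crosses a sequence boundary are
#' discarded.
#'
#' @inheritParams scanMotif
#' @return integer count.
#' @export
countSequencesWithHit <- function(motif, sequences, bothStrands = TRUE) {
  if (!is(motif, "IupacMotif")) motif <- iupacMotif(motif)
  if (is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  if (!length(sequences)) return(0L)
  L <- nchar(motif@consensus)
  ## "!" classifies as "other", which only the code N allows; windows that
  ## cross into the separator are filtered out below, so even all-N motifs
  ## are counted correctly
  idx <- seqToClasses(paste(sequences, collapse = strrep("!", L)))
  lens <- nchar(sequences)
  starts <- cumsum(c(1L, lens[-length(lens)] + L))
  ends <- starts + lens - 1L
  pos <- scanClasses(idx, motifAllowMatrix(motif))
  if (bothStrands) {
    pos <- c(pos, scanClasses(idx, motifAllowMatrix(
      reverseComplementMotif(motif))))
  }
  if (!length(pos)) return(0L)
  si <- findInterval(pos, starts)
  ok <- pos + L - 1L <= ends[si]
  length(unique(si[ok]))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Eulerian-path shuffle: the output is a uniformly random
#' sequence with exactly the same dinucleotide (and hence mononucleotide)
#' composition, the same first and last characters included. Deterministic
#' under a fixed seed.
#'
#' @param sequence a single string (length >= 2).
#' @param seed optional integer seed (the caller's RNG stream is restored).
#' @return shuffled string.
#' @export
dinucleotideShuffle <- function(sequence, seed = NULL) {
  withSeed(seed, {
    ch <- strsplit(sequence, "")[[1]]
    n <- length(ch)
    if (n < 2L) stop("sequence must have length >= 2", call. = FALSE)
    verts <- unique(ch)
    adj <- split(ch[-1L], factor(ch[-n], levels = verts))
    terminal <- ch[n]
    nonTerminal <- verts[verts != terminal & lengths(adj)[verts] > 0L]
    pickLast <- function() {
      last <- vapply(nonTerminal, function(v) {
        e <- adj[[v]]
        e[sample.int(length(e), 1L)]
      }, "")
      names(last) <- nonTerminal
      ## every non-terminal vertex must reach the terminal via last edges
      for (v in nonTerminal) {
        cur <- v
        for (step in seq_len(length(verts) + 1L)) {
          if (cur == terminal) break
          if (!cur %in% nonTerminal) break  # dead end that is not terminal
          cur <- last[[cur]]
        }
        if (cur != terminal) return(NULL)
      }
      last
    }
    last <- NULL
    for (try in seq_len(1000L)) {
      last <- pickLast()
      if (!is.null(last)) break
    }
    if (is.null(last)) stop("could not sample an Eulerian shuffle")
    ordered <- lapply(verts, function(v) {
      e <- adj[[v]]
      if (!length(e)) return(character())
      if (v %in% nonTerminal) {
        l <- last[[v]]
        i <- match(l, e)
        rest <- e[-i]
        c(if (length(rest)) rest[sample.int(length(rest))] else character(), l)
      } else {
        e[sample.int(length(e))]
      }
    })
    names(ordered) <- verts
    used <- structure(integer(length(verts)), names = verts)
    out <- character(n)
    out[1L] <- ch[1L]
    cur <- ch[1L]
    for (i in seq_len(n - 1L)) {
      used[[cur]] <- used[[cur]] + 1L
      nxt <- ordered[[cur]][used[[cur]]]
      out[i + 1L] <- nxt
      cur <- nxt
    }
    paste(out, collapse = "")
  })
}

#' Dinucleotide counts of a sequence
#'
#' @param sequence a single string.
#' @return named table of adjacent character pairs.
#' @export
dinucleotideCounts <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  if (length(ch) < 2L) return(table(character()))
  table(paste0(ch[-length(ch)], ch[-1L]))
}

#' Motif enrichment of foreground versus background sequences
#'
#' Sequence-level statistic: the fraction of sequences with at least one hit.
#' The foreground count is tested against the background fraction with a
#' one-sided binomial test; fold enrichment is the ratio of fractions. When
#' no background is supplied, each foreground sequence contributes
#' `shufflesPerSequence` dinucleotide-shuffled copies.
#'
#' @param motif an [iupacMotif()] or consensus string.
#' @param foreground,background character vectors of sequences (background
#'   may be `NULL` to use the shuffle model).
#' @param bothStrands scan both strands (default `TRUE`).
#' @param shufflesPerSequence shuffled copies per foreground sequence when
#'   `background` is `NULL`.
#' @param seed seed for the shuffle background.
#' @return a [MotifEnrichment-class].
#' @export
motifEnrichment <- function(motif, foreground, background = NULL,
                            bothStrands = TRUE, shufflesPerSequence = 1L,
                            seed = NULL) {
  if (!is(motif, "IupacMotif")) motif <- iupacMotif(motif)
  if (!length(foreground)) stop("foreground is empty", call. = FALSE)
  if (is.null(background)) {
    background <- withSeed(seed, {
      unlist(lapply(seq_len(shufflesPerSequence), function(k) {
        vapply(foreground, dinucleotideShuffle, "", USE.NAMES = FALSE)
      }))
    })
  }
  if (!length(background)) stop("background is empty", call. = FALSE)
  fgHits <- countSequencesWithHit(motif, foreground, bothStrands)
  bgHits <- countSequencesWithHit(motif, background, bothStrands)
  fgN <- length(foreground)
  bgN <- length(background)
  fgFrac <- fgHits / fgN
  bgFrac <- bgHits / bgN
  foldInf <- bgFrac == 0 && fgHits > 0
  if (foldInf) {
    fold <- Inf
    p <- .Machine$double.xmin
  } else if (bgFrac == 0) {
    fold <- 1
    p <- 1
  } else {
    fold <- fgFrac / bgFrac
    p <- binom.test(fgHits, fgN, p = min(bgFrac, 1), alternative = "greater")$p.value
  }
  new("MotifEnrichment", motif = motif@consensus,
      fgHits = as.integer(fgHits), fgN = as.integer(fgN),
      bgHits = as.integer(bgHits), bgN = as.integer(bgN),
      fold = fold, pvalue = p, foldInfinite = foldInf)
}

#' Extract peak sequences from a genome
#'
#' @param peaks a `GRanges`.
#' @param genomeSeqs named `DNAStringSet` (or named character) of chromosome
#'   sequences, or a FASTA path.
#' @return named character vector of peak sequences.
#' @export
peakSequences <- function(peaks, genomeSeqs) {
  if (is.character(genomeSeqs) && length(genomeSeqs) == 1L &&
      file.exists(genomeSeqs)) {
    genomeSeqs <- readDNAStringSet(genomeSeqs)
  }
  if (is(genomeSeqs, "DNAStringSet")) genomeSeqs <- as.character(genomeSeqs)
  names(genomeSeqs) <- sub("\\s.*", "", names(genomeSeqs))
  chrom <- as.character(seqnames(peaks))
  missing <- setdiff(unique(chrom), names(genomeSeqs))
  if (length(missing))
    stop("chromosome(s) missing from genome FASTA: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- vapply(seq_along(peaks), function(i) {
    substr(genomeSeqs[[chrom[i]]], start(peaks)[i], end(peaks)[i])
  }, "")
  names(out) <- if (!is.null(peaks$name)) peaks$name else
    paste0("peak", seq_along(peaks))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
writeFasta <- function(seqs, path) {
  writeXStringSet(DNAStringSet(seqs), path)
  invisible(path)
}
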