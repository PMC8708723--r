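#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   mcols<- strand<- granges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb Seqinfo seqlevels seqlengths seqinfo seqinfo<-
#'   seqlevels<- seqnames<-
#' @importFrom S4Vectors DataFrame
NULL

## All on-disk coordinates are BED-family 0-based half-open; in memory they
## live in 1-based closed GRanges. Conversion happens only here.

parseError <- function(path, lineno, msg) {
  stop(sprintf("parse error in '%s' line %d: %s", path, lineno, msg),
       call. = FALSE)
}

readLinesNoComment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  list(lines = lines[keep], lineno = which(keep))
}

splitFields <- function(lines) strsplit(lines, "\t| +")

checkNumericField <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    parseError(path, lineno[bad[1L]], paste0("non-numeric ", what, ": '",
                                             x[bad[1L]], "'"))
  v
}

checkIntervals <- function(chrom, start0, end0, path, lineno, seqinfo = NULL) {
  bad <- which(start0 < 0)
  if (length(bad)) parseError(path, lineno[bad[1L]], "negative start")
  bad <- which(end0 <= start0)
  if (length(bad))
    parseError(path, lineno[bad[1L]],
               sprintf("end (%d) <= start (%d)", end0[bad[1L]], start0[bad[1L]]))
  if (!is.null(seqinfo)) {
    known <- chrom %in% seqlevels(seqinfo)
    if (!all(known))
      parseError(path, lineno[which(!known)[1L]],
                 paste0("unknown chromosome '", chrom[!known][1L], "'"))
    lens <- seqlengths(seqinfo)[chrom]
    bad <- which(end0 > lens)
    if (length(bad))
      parseError(path, lineno[bad[1L]], "interval beyond chromosome length")
  }
  invisible(TRUE)
}

## Build a GRanges from 0-based half-open coordinates, with deterministic
## seqlevel ordering (alphabetical unless a Seqinfo dictates otherwise).
grFromBed0 <- function(chrom, start0, end0, strand = "*", seqinfo = NULL) {
  levels <- if (is.null(seqinfo)) sort(unique(chrom)) else seqlevels(seqinfo)
  gr <- GRanges(factor(chrom, levels = levels),
                IRanges(start0 + 1L, end0), strand = strand)
  if (!is.null(seqinfo)) seqinfo(gr) <- seqinfo
  gr
}

#' Read a two-column chrom.sizes file into a Seqinfo
#'
#' @param path path to a tab- or space-separated file of chromosome name and
#'   length.
#' @param genome optional genome identifier recorded on the `Seqinfo`.
#' @return a [GenomeInfoDb::Seqinfo].
#' @export
readChromSizes <- function(path, genome = NA_character_) {
  parsed <- readLinesNoComment(path)
  f <- splitFields(parsed$lines)
  nf <- lengths(f)
  if (any(nf < 2L))
    parseError(path, parsed$lineno[which(nf < 2L)[1L]], "expected 2 columns")
  chrom <- vapply(f, `[`, "", 1L)
  len <- checkNumericField(vapply(f, `[`, "", 2L), path, parsed$lineno, "length")
  if (any(len <= 0))
    parseError(path, parsed$lineno[which(len <= 0)[1L]],
               "chromosome length must be > 0")
  if (anyDuplicated(chrom))
    parseError(path, parsed$lineno[anyDuplicated(chrom)],
               "duplicated chromosome name")
  Seqinfo(seqnames = chrom, seqlengths = as.integer(len), genome = genome)
}

#' Write a Seqinfo as a chrom.sizes file
#'
#' @param seqinfo a `Seqinfo`.
#' @param path output path.
#' @export
writeChromSizes <- function(seqinfo, path) {
  writeLines(paste(seqlevels(seqinfo), seqlengths(seqinfo), sep = "\t"), path)
}

#' Read a peak file (ENCODE narrowPeak or BED6)
#'
#' Peaks are returned sorted by (chromosome, start) with metadata columns
#' `name`, `score` (the narrowPeak signalValue, or the BED score), a
#' `summitOffset` in bp from the peak start (`NA` when absent or -1), and a
#' `rank` assigned by descending score (ties broken by genomic order).
#'
#' @param path input file.
#' @param format `"narrowPeak"` (10 columns) or `"bed6"`.
#' @param seqinfo optional `Seqinfo`; when supplied, intervals beyond their
#'   chromosome raise a validation error.
#' @return a sorted `GRanges`.
#' @export
readPeaks <- function(path, format = c("narrowPeak", "bed6"), seqinfo = NULL) {
  format <- match.arg(format)
  parsed <- readLinesNoComment(path)
  ncolNeed <- if (format == "narrowPeak") 10L else 6L
  if (!length(parsed$lines)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(name = character(), score = numeric(),
                           summitOffset = integer(), rank = integer())
    if (!is.null(seqinfo)) seqinfo(gr) <- seqinfo
    return(gr)
  }
  f <- splitFields(parsed$lines)
  nf <- lengths(f)
  if (any(nf < ncolNeed))
    parseError(path, parsed$lineno[which(nf < ncolNeed)[1L]],
               sprintf("expected %d columns, found %d", ncolNeed,
                       nf[which(nf < ncolNeed)[1L]]))
  chrom <- vapply(f, `[`, "", 1L)
  start0 <- as.integer(checkNumericField(vapply(f, `[`, "", 2L), path,
                                         parsed$lineno, "start"))
  end0 <- as.integer(checkNumericField(vapply(f, `[`, "", 3L), path,
                                       parsed$lineno, "end"))
  checkIntervals(chrom, start0, end0, path, parsed$lineno, seqinfo)
  name <- vapply(f, `[`, "", 4L)
  strandChr <- vapply(f, `[`, "", 6L)
  strandChr[!strandChr %in% c("+", "-")] <- "*"
  if (format == "narrowPeak") {
    score <- checkNumericField(vapply(f, `[`, "", 7L), path, parsed$lineno,
                               "signalValue")
    summit <- as.integer(checkNumericField(vapply(f, `[`, "", 10L), path,
                                           parsed$lineno, "summit"))
    summit[summit < 0L] <- NA_integer_
  } else {
    score <- checkNumericField(vapply(f, `[`, "", 5L), path, parsed$lineno,
                               "score")
    summit <- rep(NA_integer_, length(score))
  }
  width <- end0 - start0
  bad <- which(!is.na(summit) & summit >= width)
  if (length(bad))
    parseError(path, parsed$lineno[bad[1L]], "summit offset outside peak")
  if (any(score < 0))
    parseError(path, parsed$lineno[which(score < 0)[1L]], "negative score")
  gr <- grFromBed0(chrom, start0, end0, strandChr, seqinfo)
  mcols(gr) <- DataFrame(name = name, score = score, summitOffset = summit,
                         rank = NA_integer_)
  gr <- sort(gr, ignore.strand = TRUE)
  gr$rank <- rankPeaks(gr$score)
  gr
}

## Rank by descending score; ties resolved by current (genomic) order.
rankPeaks <- function(score) {
  as.integer(order(order(-score)))
}

#' Write peaks as narrowPeak or BED6
#'
#' Emits deterministic (chromosome, start, name) ordering; narrowPeak columns
#' not carried by the object (p/q value) are written as -1.
#'
#' @param peaks a `GRanges` as returned by [readPeaks()].
#' @param path output path.
#' @param format `"narrowPeak"` or `"bed6"`.
#' @export
writePeaks <- function(peaks, path, format = c("narrowPeak", "bed6")) {
  format <- match.arg(format)
  o <- order(as.character(seqnames(peaks)), start(peaks),
             if (!is.null(peaks$name)) peaks$name else seq_along(peaks))
  peaks <- peaks[o]
  chrom <- as.character(seqnames(peaks))
  start0 <- start(peaks) - 1L
  end0 <- end(peaks)
  name <- if (!is.null(peaks$name)) peaks$name else paste0("peak", seq_along(peaks))
  strandChr <- as.character(strand(peaks))
  strandChr[strandChr == "*"] <- "."
  score <- if (!is.null(peaks$score)) peaks$score else 0
  if (format == "narrowPeak") {
    summit <- if (!is.null(peaks$summitOffset)) peaks$summitOffset else NA_integer_
    summit[is.na(summit)] <- -1L
    lines <- paste(chrom, start0, end0, name, 0L, strandChr,
                   format(score, trim = TRUE, digits = 15), -1, -1, summit,
                   sep = "\t")
  } else {
    lines <- paste(chrom, start0, end0, name,
                   format(score, trim = TRUE, digits = 15), strandChr,
                   sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Returns a piecewise-constant track as a `GRanges` with a `score` column,
#' sorted, and validated to be non-overlapping per chromosome.
#'
#' @inheritParams readPeaks
#' @return a sorted `GRanges` with metadata column `score`.
#' @export
readBedGraph <- function(path, seqinfo = NULL) {
  parsed <- readLinesNoComment(path)
  if (!length(parsed$lines)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(score = numeric())
    if (!is.null(seqinfo)) seqinfo(gr) <- seqinfo
    return(gr)
  }
  f <- splitFields(parsed$lines)
  nf <- lengths(f)
  if (any(nf < 4L))
    parseError(path, parsed$lineno[which(nf < 4L)[1L]], "expected 4 columns")
  chrom <- vapply(f, `[`, "", 1L)
  start0 <- as.integer(checkNumericField(vapply(f, `[`, "", 2L), path,
                                         parsed$lineno, "start"))
  end0 <- as.integer(checkNumericField(vapply(f, `[`, "", 3L), path,
                                       parsed$lineno, "end"))
  value <- checkNumericField(vapply(f, `[`, "", 4L), path, parsed$lineno,
                             "value")
  if (any(!is.finite(value)))
    parseError(path, parsed$lineno[which(!is.finite(value))[1L]],
               "non-finite value")
  checkIntervals(chrom, start0, end0, path, parsed$lineno, seqinfo)
  gr <- grFromBed0(chrom, start0, end0, "*", seqinfo)
  gr$score <- value
  gr <- sort(gr, ignore.strand = TRUE)
  ## non-overlap per chromosome
  same <- as.character(seqnames(gr))[-1] == as.character(seqnames(gr))[-length(gr)]
  if (length(gr) > 1L && any(same & start(gr)[-1] <= end(gr)[-length(gr)]))
    stop("overlapping bedGraph intervals in '", path, "'", call. = FALSE)
  gr
}

#' Write a signal track as bedGraph
#'
#' @param track `GRanges` with a `score` column.
#' @param path output path.
#' @export
writeBedGraph <- function(track, path) {
  track <- sort(track, ignore.strand = TRUE)
  lines <- paste(as.character(seqnames(track)), start(track) - 1L, end(track),
                 format(track$score, trim = TRUE, digits = 15), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read transcription start sites from a BED file
#'
#' Column 4 is the gene identifier; the TSS position is the (0-based) start.
#' Several TSS per gene are allowed.
#'
#' @inheritParams readPeaks
#' @return width-1 `GRanges` with metadata column `gene_id`.
#' @export
readTssBed <- function(path, seqinfo = NULL) {
  parsed <- readLinesNoComment(path)
  if (!length(parsed$lines)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(gene_id = character())
    if (!is.null(seqinfo)) seqinfo(gr) <- seqinfo
    return(gr)
  }
  f <- splitFields(parsed$lines)
  nf <- lengths(f)
  if (any(nf < 4L))
    parseError(path, parsed$lineno[which(nf < 4L)[1L]], "expected >= 4 columns")
  chrom <- vapply(f, `[`, "", 1L)
  start0 <- as.integer(checkNumericField(vapply(f, `[`, "", 2L), path,
                                         parsed$lineno, "start"))
  gene <- vapply(f, `[`, "", 4L)
  strandChr <- ifelse(nf >= 6L, vapply(f, function(x) x[6L], ""), "*")
  strandChr[!strandChr %in% c("+", "-")] <- "*"
  if (any(start0 < 0))
    parseError(path, parsed$lineno[which(start0 < 0)[1L]], "negative position")
  gr <- grFromBed0(chrom, start0, start0 + 1L, strandChr, seqinfo)
  gr$gene_id <- gene
  sort(gr, ignore.strand = TRUE)
}

#' Write TSS records as BED6
#'
#' @param tss width-1 `GRanges` with `gene_id`.
#' @param path output path.
#' @export
writeTssBed <- function(tss, path) {
  o <- order(as.character(seqnames(tss)), start(tss), tss$gene_id)
  tss <- tss[o]
  strandChr <- as.character(strand(tss))
  strandChr[strandChr == "*"] <- "."
  writeLines(paste(as.character(seqnames(tss)), start(tss) - 1L, start(tss),
                   tss$gene_id, 0L, strandChr, sep = "\t"), path)
  invisible(path)
}

#' Extract TSS records from a simplified GTF
#'
#' Only `gene` feature records with a `gene_id` attribute are honored. GTF is
#' 1-based inclusive; the TSS is the record start on the + strand and the
#' record end on the - strand.
#'
#' @inheritParams readPeaks
#' @return width-1 `GRanges` with metadata column `gene_id`.
#' @export
readGtfTss <- function(path, seqinfo = NULL) {
  parsed <- readLinesNoComment(path)
  f <- strsplit(parsed$lines, "\t")
  nf <- lengths(f)
  if (length(nf) && any(nf < 9L))
    parseError(path, parsed$lineno[which(nf < 9L)[1L]], "expected 9 GTF columns")
  keep <- vapply(f, function(x) x[3L] == "gene", TRUE)
  f <- f[keep]
  lineno <- parsed$lineno[keep]
  if (!length(f)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(gene_id = character())
    return(gr)
  }
  chrom <- vapply(f, `[`, "", 1L)
  start1 <- as.integer(checkNumericField(vapply(f, `[`, "", 4L), path, lineno,
                                         "start"))
  end1 <- as.integer(checkNumericField(vapply(f, `[`, "", 5L), path, lineno,
                                       "end"))
  strandChr <- vapply(f, `[`, "", 7L)
  strandChr[!strandChr %in% c("+", "-")] <- "*"
  attrs <- vapply(f, `[`, "", 9L)
  m <- regmatches(attrs, regexec("gene_id[ =]+\"?([^\";]+)\"?", attrs))
  gene <- vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  if (anyNA(gene))
    parseError(path, lineno[which(is.na(gene))[1L]], "missing gene_id attribute")
  tss1 <- ifelse(strandChr == "-", end1, start1)
  gr <- grFromBed0(chrom, tss1 - 1L, tss1, strandChr, seqinfo)
  gr$gene_id <- gene
  sort(gr, ignore.strand = TRUE)
}

#' Read a cCRE catalog BED
#'
#' BED4+ with the cCRE class in column 4; optional columns 5-7 carry max-Z
#' scores for DNase, H3K4me3 and H3K27ac (in that order).
#'
#' @inheritParams readPeaks
#' @return a sorted `GRanges` with metadata `class` and, when present,
#'   `dnaseZ`, `h3k4me3Z`, `h3k27acZ`.
#' @export
readCcreBed <- function(path, seqinfo = NULL) {
  parsed <- readLinesNoComment(path)
  if (!length(parsed$lines)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(class = character())
    if (!is.null(seqinfo)) seqinfo(gr) <- seqinfo
    return(gr)
  }
  f <- splitFields(parsed$lines)
  nf <- lengths(f)
  if (any(nf < 4L))
    parseError(path, parsed$lineno[which(nf < 4L)[1L]], "expected >= 4 columns")
  chrom <- vapply(f, `[`, "", 1L)
  start0 <- as.integer(checkNumericField(vapply(f, `[`, "", 2L), path,
                                         parsed$lineno, "start"))
  end0 <- as.integer(checkNumericField(vapply(f, `[`, "", 3L), path,
                                       parsed$lineno, "end"))
  checkIntervals(chrom, start0, end0, path, parsed$lineno, seqinfo)
  cls <- vapply(f, `[`, "", 4L)
  bad <- !cls %in% ccreClassLevels()
  if (any(bad))
    parseError(path, parsed$lineno[which(bad)[1L]],
               paste0("unknown cCRE class '", cls[bad][1L], "'"))
  gr <- grFromBed0(chrom, start0, end0, "*", seqinfo)
  gr$class <- cls
  if (all(nf >= 7L)) {
    gr$dnaseZ <- checkNumericField(vapply(f, `[`, "", 5L), path,
                                   parsed$lineno, "DNase z")
    gr$h3k4me3Z <- checkNumericField(vapply(f, `[`, "", 6L), path,
                                     parsed$lineno, "H3K4me3 z")
    gr$h3k27acZ <- checkNumericField(vapply(f, `[`, "", 7L), path,
                                     parsed$lineno, "H3K27ac z")
  }
  sort(gr, ignore.strand = TRUE)
}

#' Write a cCRE catalog BED
#'
#' @param ccre `GRanges` with `class` and optional z-score columns.
#' @param path output path.
#' @export
writeCcreBed <- function(ccre, path) {
  ccre <- sort(ccre, ignore.strand = TRUE)
  base <- paste(as.character(seqnames(ccre)), start(ccre) - 1L, end(ccre),
                ccre$class, sep = "\t")
  if (!is.null(ccre$dnaseZ)) {
    base <- paste(base,
                  format(ccre$dnaseZ, trim = TRUE, digits = 15),
                  format(ccre$h3k4me3Z, trim = TRUE, digits = 15),
                  format(ccre$h3k27acZ, trim = TRUE, digits = 15), sep = "\t")
  }
  writeLines(base, path)
  invisible(path)
}

#' Read / write plain TSV tables
#'
#' Thin wrappers fixing the dialect used throughout (tab separator, header,
#' no quoting, no row names).
#'
#' @param path file path.
#' @return `readTsv` returns a data.frame.
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @param x data.frame to write.
#' @rdname readTsv
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
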