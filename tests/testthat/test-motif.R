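test_that("IUPAC motifs validate their consensus", {
  m <- iupacMotif("NCGGAAMM")
  expect_s4_class(m, "IupacMotif")
  expect_error(iupacMotif("ACGX"), "IUPAC")
  expect_equal(reverseComplementMotif("NCGGAAMM")@consensus, "KKTTCCGN")
  ## double reverse complement is the identity
  expect_equal(reverseComplementMotif(reverseComplementMotif(m))@consensus,
               m@consensus)
})

test_that("matchAt follows the degeneracy sets on both strands", {
  expect_true(matchAt("NCGGAAMM", "ACGGAAAA", 1))
  expect_true(matchAt("NCGGAAMM", "TCGGAACC", 1))
  expect_false(matchAt("NCGGAAMM", "ACGGAATT", 1))  # M is A/C, not T
  ## reverse strand: revcomp(TTTTCCGT) = ACGGAAAA matches
  expect_true(matchAt("NCGGAAMM", "TTTTCCGT", 1, strand = "-"))
  expect_false(matchAt("NCGGAAMM", "TTTTCCGT", 1, strand = "+"))
  ## window bounds
  expect_error(matchAt("NCGGAAMM", "ACGT", 1), "outside sequence")
  expect_error(matchAt("ACGT", "ACGTACGT", 6), "outside sequence")
})

test_that("non-ACGT characters match only the code N", {
  expect_true(matchAt("NCGG", "NCGG", 1))   # N in sequence vs code N
  expect_false(matchAt("ACGG", "NCGG", 1))  # N in sequence vs code A
  expect_message(scanMotif("NCGG", "QCGGT"), "outside ACGTN")
})

test_that("an all-N motif matches every window on both strands", {
  set.seed(450)
  s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  hits <- scanMotif("NNNN", s)[[1]]
  expect_equal(sum(hits$strand == "+"), 50 - 4 + 1)
  expect_equal(sum(hits$strand == "-"), 50 - 4 + 1)
})

test_that("scanMotif equals a position-by-position matchAt scan", {
  set.seed(451)
  motifs <- c("NCGGAAMM", "RYSW", "ACGT")
  for (mt in motifs) {
    L <- nchar(mt)
    seqs <- vapply(1:5, function(i) {
      paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    }, "")
    got <- scanMotif(mt, seqs)
    for (k in seq_along(seqs)) {
      fwd <- which(vapply(seq_len(60 - L + 1), function(p) {
        matchAt(mt, seqs[k], p, "+")
      }, TRUE))
      rev <- which(vapply(seq_len(60 - L + 1), function(p) {
        matchAt(mt, seqs[k], p, "-")
      }, TRUE))
      expect_equal(got[[k]]$position[got[[k]]$strand == "+"], fwd)
      expect_equal(got[[k]]$position[got[[k]]$strand == "-"], rev)
    }
  }
})

test_that("scanMotif agrees with Biostrings fixed-pattern matching", {
  set.seed(452)
  seqs <- vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  }, "")
  mt <- "NCGGAAMM"
  got <- scanMotif(mt, seqs)
  for (k in seq_along(seqs)) {
    subj <- Biostrings::DNAString(seqs[k])
    oF <- start(Biostrings::matchPattern(mt, subj, fixed = FALSE))
    ## oracle for the reverse strand: forward-match the reverse complement
    oR2 <- start(Biostrings::matchPattern(
      reverseComplementMotif(mt)@consensus, subj, fixed = FALSE))
    expect_equal(got[[k]]$position[got[[k]]$strand == "+"], as.integer(oF))
    expect_equal(got[[k]]$position[got[[k]]$strand == "-"], as.integer(oR2))
  }
})

test_that("reverse-strand hits mirror the reverse-complemented sequence", {
  set.seed(453)
  s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  mt <- "NCGGAAMM"
  L <- nchar(mt)
  fwdOnRc <- scanMotif(mt, rc, bothStrands = FALSE)[[1]]$position
  hits <- scanMotif(mt, s)[[1]]
  revOnS <- hits$position[hits$strand == "-"]
  ## a - strand hit at forward position p corresponds to a + strand hit at
  ## position n - p - L + 2 on the reverse-complemented sequence
  expect_setequal(100 - revOnS - L + 2, fwdOnRc)
})

test_that("dinucleotide shuffle preserves composition and endpoints", {
  set.seed(454)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
               collapse = "")
    sh <- dinucleotideShuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, 80, 80), substr(s, 80, 80))
    expect_equal(dinucleotideCounts(sh), dinucleotideCounts(s))
  }
})

test_that("dinucleotide shuffle is seed-deterministic and seed-sensitive", {
  s <- strrep("ACGTTGCAAT", 10)
  expect_identical(dinucleotideShuffle(s, seed = 9),
                   dinucleotideShuffle(s, seed = 9))
  shuffles <- vapply(1:20, function(k) dinucleotideShuffle(s, seed = k), "")
  expect_gt(length(unique(shuffles)), 1)
  ## the caller's RNG stream is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(dinucleotideShuffle(s, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("binomial enrichment p equals exact tail enumeration", {
  fg <- c("ACGGAAAA", "TTTTTTTT", "GCGGAACA", "ACGGAACC")  # 3 of 4 hit
  bg <- c(rep("ACGGAAAA", 2), rep("TTTTTTTT", 8))          # bgFrac 0.2
  enr <- motifEnrichment("NCGGAAMM", fg, bg)
  expect_equal(enr@fgHits, 3L)
  expect_equal(enr@bgHits, 2L)
  expect_equal(enr@fold, (3 / 4) / (2 / 10))
  pExact <- sum(vapply(3:4, function(k) {
    choose(4, k) * 0.2^k * 0.8^(4 - k)
  }, 1))
  expect_equal(enr@pvalue, pExact, tolerance = 1e-12)
})

test_that("identical foreground and background give fold 1 and p >= 0.5", {
  set.seed(455)
  seqs <- vapply(1:30, function(i) {
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  }, "")
  enr <- motifEnrichment("RY", seqs, seqs)
  expect_equal(enr@fold, 1)
  expect_gte(enr@pvalue, 0.5)
})

test_that("an empty background with foreground hits flags infinite fold", {
  enr <- motifEnrichment("ACGT", c("AACGTA", "GGGGGG"),
                         c("CCCCCC", "GGGGGG"))
  expect_true(enr@foldInfinite)
  expect_identical(enr@fold, Inf)
  expect_lt(enr@pvalue, 1e-300)
})

test_that("planted motifs are detected against the shuffle background", {
  cfg <- simConfig(seed = 59)
  sim <- simulateMotifSequences(cfg)
  enr <- motifEnrichment(cfg@motifConsensus, sim$foreground,
                         sim$background)
  expect_gt(enr@fold, 2)
  expect_lt(enr@pvalue, 1e-6)
  ## shuffle-model background behaves comparably
  enr2 <- motifEnrichment(cfg@motifConsensus, sim$foreground, seed = 61)
  expect_lt(enr2@pvalue, 1e-6)
})

test_that("peakSequences extracts exact substrings from FASTA and memory", {
  genome <- c(chr1 = "ACGTACGTACGTACGTACGT")
  pk <- mkGR("chr1", c(1, 5), c(4, 12), name = c("p1", "p2"))
  got <- peakSequences(pk, genome)
  expect_equal(unname(got), c("ACGT", "ACGTACGT"))
  expect_equal(names(got), c("p1", "p2"))
  f <- withr::local_tempfile(fileext = ".fa")
  writeFasta(genome, f)
  expect_equal(peakSequences(pk, f), got)
  bad <- mkGR("chrX", 1, 4)
  expect_error(peakSequences(bad, genome), "missing from genome")
})
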