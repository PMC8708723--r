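test_that("simConfig validates proportions and rejects unknown fields", {
  expect_s4_class(simConfig(), "SimConfig")
  expect_error(simConfig(bogusKnob = 1), "unknown SimConfig field")
  expect_error(simConfig(classProportions = c(PLS = 0.9, pELS = 0.3,
                                              dELS = 0.1)),
               "sum to <= 1")
  expect_error(simConfig(dropoutRate = 1), "dropoutRate")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- simConfig(seed = 101)
  a1 <- simulateAnnotation(cfg)
  a2 <- simulateAnnotation(cfg)
  expect_identical(a1$tss, a2$tss)
  expect_identical(a1$ccre, a2$ccre)
  expect_identical(simulateCcrePeaks(cfg, a1), simulateCcrePeaks(cfg, a2))
  expect_identical(simulateCounts(cfg)$counts, simulateCounts(cfg)$counts)
  ## and sensitive to the seed
  a3 <- simulateAnnotation(simConfig(seed = 102))
  expect_false(identical(start(a1$tss), start(a3$tss)))
})

test_that("generators leave the caller's RNG stream untouched", {
  cfg <- simConfig(seed = 103)
  set.seed(7); before <- runif(3)
  set.seed(7); invisible(simulateAnnotation(cfg))
  invisible(simulateReplicatePair(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("planted class counts are deterministic round(p * n)", {
  cfg <- simConfig(seed = 104)
  ann <- simulateAnnotation(cfg)
  pk <- simulateCcrePeaks(cfg, ann)
  expect_equal(length(pk), 928L)
  tab <- table(pk$trueClass)
  expect_equal(unname(tab[["PLS"]]), round(0.48 * 928))
  expect_equal(unname(tab[["pELS"]]), round(0.134 * 928))
  expect_equal(unname(tab[["dELS"]]), round(0.097 * 928))
  expect_equal(sum(tab), 928L)
})

test_that("zero jitter and zero dropout give perfectly matched replicates", {
  cfg <- simConfig(seed = 105, replicateJitterBp = 0, dropoutRate = 0,
                   nSharedPeaks = 100, nPrivatePeaks = 50)
  sim <- simulateReplicatePair(cfg)
  shared <- sim$repA[grepl("^shared_", sim$repA$name)]
  sharedB <- sim$repB[grepl("^shared_", sim$repB$name)]
  expect_equal(length(shared), 100L)
  expect_identical(granges(shared), granges(sharedB))
  cons <- consensusPeaks(sim$repA, sim$repB)
  expect_equal(length(consensusRanges(cons)), 100L)
})

test_that("dropout removes shared peaks at the configured rate", {
  cfg <- simConfig(seed = 106, dropoutRate = 0.3, nSharedPeaks = 400,
                   nPrivatePeaks = 0)
  sim <- simulateReplicatePair(cfg)
  retained <- length(sim$repA) / 400
  expect_gt(retained, 0.55)
  expect_lt(retained, 0.85)
  expect_lte(sim$nShared, min(length(sim$repA), length(sim$repB)))
})

test_that("counts carry the planted DE labels and library factors", {
  cfg <- simConfig(seed = 107, countGenes = 500,
                   libFactors = c(1, 2), nSamplesPerGroup = 2)
  sim <- simulateCounts(cfg)
  expect_equal(dim(sim$counts), c(500L, 4L))
  expect_equal(sum(sim$trueDe$label != "ns"), round(0.15 * 500))
  expect_equal(sum(sim$trueDe$label == "up"),
               sum(sim$trueDe$label == "down"), tolerance = 1)
  expect_equal(exp(mean(log(sim$trueFactors))), 1, tolerance = 1e-12)
  ## a planted up gene really is higher in the kd group
  up <- sim$trueDe$gene[sim$trueDe$label == "up"]
  kd <- sim$group == "kd"
  ratio <- rowMeans(sim$counts[up, kd, drop = FALSE] + 1) /
    rowMeans(sim$counts[up, !kd, drop = FALSE] + 1)
  expect_gt(median(ratio), 2)
})

test_that("simulateStudy writes a parseable, self-consistent bundle", {
  cfg <- simConfig(seed = 108, nGenes = 40, nTfs = 3, nCcrePeaks = 60,
                   nSharedPeaks = 50, nPrivatePeaks = 20,
                   nCobindRegions = 60, targetsPerTf = 8,
                   chromLengths = c(chr1 = 1e6, chr2 = 1e6),
                   nSeqPerArm = 20)
  d <- withr::local_tempdir()
  simulateStudy(cfg, d)
  si <- readChromSizes(file.path(d, "chrom.sizes"))
  expect_equal(unname(seqlengths(si)), c(1e6, 1e6))
  tss <- readTssBed(file.path(d, "tss.bed"), seqinfo = si)
  expect_equal(length(tss), 40L)
  ccre <- readCcreBed(file.path(d, "ccre.bed"), seqinfo = si)
  expect_true(all(c("dnaseZ", "h3k4me3Z", "h3k27acZ") %in%
                    names(mcols(ccre))))
  ## planted element classes are recoverable from the written z-scores
  expect_equal(classifyElements(ccre, tss), ccre$class)
  manifest <- readTsv(file.path(d, "manifest.tsv"))
  expect_equal(nrow(manifest), 3L)
  for (i in seq_len(nrow(manifest))) {
    pk <- readPeaks(file.path(d, manifest$rep1[i]), seqinfo = si)
    expect_gt(length(pk), 0L)
    tr <- readBedGraph(file.path(d, manifest$track[i]), seqinfo = si)
    expect_gt(length(tr), 0L)
  }
  counts <- readTsv(file.path(d, "counts.tsv"))
  expect_equal(nrow(counts), 40L)  # gene universe = annotation genes
  expect_equal(counts$gene, tss$gene_id[order(tss$gene_id)])
  genome <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  expect_equal(unname(Biostrings::width(genome)), c(1e6, 1e6))
})

test_that("simulateStudy output is byte-identical across runs and paths", {
  cfg <- simConfig(seed = 109, nGenes = 30, nTfs = 2, nCcrePeaks = 40,
                   nSharedPeaks = 30, nPrivatePeaks = 10,
                   nCobindRegions = 40, targetsPerTf = 5,
                   chromLengths = c(chr1 = 6e5, chr2 = 6e5))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateStudy(cfg, d1)
  simulateStudy(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(h1, h2)
})
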