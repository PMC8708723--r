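test_that("a lone gene gets basal plus full extension, clipped to the genome", {
  si <- Seqinfo("chr1", 100000)
  tss <- mkGR("chr1", 50000, 50000, gene_id = "g1", seqinfo = si)
  strand(tss) <- "+"
  d <- buildRegulatoryDomains(tss, domainParams(5000, 1000, 10000),
                              seqinfo = si)
  expect_equal(d$basalStart, 45000L)
  expect_equal(d$basalEnd, 51000L)
  expect_equal(start(d), 35000L)
  expect_equal(end(d), 61000L)
  ## clipping: the same gene near the chromosome start
  tss2 <- mkGR("chr1", 3000, 3000, gene_id = "g1", seqinfo = si)
  d2 <- buildRegulatoryDomains(tss2, domainParams(5000, 1000, 10000),
                               seqinfo = si)
  expect_equal(d2$basalStart, 1L)
  expect_equal(start(d2), 1L)
})

test_that("basal windows are strand-aware", {
  si <- Seqinfo("chr1", 100000)
  tss <- mkGR("chr1", 50000, 50000, gene_id = "g1", seqinfo = si)
  strand(tss) <- "-"
  d <- buildRegulatoryDomains(tss, domainParams(5000, 1000, 0), seqinfo = si)
  ## upstream of a minus-strand gene lies at larger coordinates
  expect_equal(d$basalStart, 49000L)
  expect_equal(d$basalEnd, 55000L)
})

test_that("extension stops at the neighbor's basal domain (hand-worked)", {
  si <- Seqinfo("chr1", 1000000)
  tss <- mkGR("chr1", c(100000, 110000), c(100000, 110000),
              gene_id = c("g1", "g2"), seqinfo = si)
  strand(tss) <- "+"
  d <- buildRegulatoryDomains(tss, domainParams(5000, 1000, 1000000),
                              seqinfo = si)
  ## g1 basal [95000,101000]; g2 basal [105000,111000]
  ## g1 extends right only to 105000-1; g2 extends left only to 101000+1
  expect_equal(end(d[d$gene_id == "g1"]), 104999L)
  expect_equal(start(d[d$gene_id == "g2"]), 101001L)
  ## outer edges run to the genome/extension limits
  expect_equal(start(d[d$gene_id == "g1"]), 1L)
  expect_equal(end(d[d$gene_id == "g2"]), 1000000L)
})

test_that("extended domains never invade another gene's basal window", {
  set.seed(430)
  si <- Seqinfo("chr1", 5e6)
  pos <- as.integer(round(seq(1e5, 4.9e6, length.out = 40)) +
                      sample(-2000:2000, 40, replace = TRUE))
  tss <- mkGR("chr1", pos, pos, gene_id = sprintf("g%02d", 1:40),
              seqinfo = si)
  strand(tss) <- sample(c("+", "-"), 40, replace = TRUE)
  d <- buildRegulatoryDomains(tss, seqinfo = si)
  for (i in seq_along(d)) {
    others <- setdiff(seq_along(d), i)
    ## disjoint from every other basal window
    expect_true(all(start(d)[i] > d$basalEnd[others] |
                      end(d)[i] < d$basalStart[others]))
    expect_gte(start(d)[i], 1L)
    expect_lte(end(d)[i], 5e6)
    ## the gene's own basal window is contained in the extended domain
    expect_lte(start(d)[i], d$basalStart[i])
    expect_gte(end(d)[i], d$basalEnd[i])
  }
})

test_that("domain width is monotone in the extension cap", {
  set.seed(431)
  si <- Seqinfo("chr1", 5e6)
  pos <- sort(sample(seq(20000, 4.98e6), 25))
  tss <- mkGR("chr1", pos, pos, gene_id = sprintf("g%02d", 1:25),
              seqinfo = si)
  w <- lapply(c(0, 1e4, 1e5, 1e6), function(ext) {
    width(buildRegulatoryDomains(tss, domainParams(5000, 1000, ext),
                                 seqinfo = si))
  })
  for (k in 2:4) expect_true(all(w[[k]] >= w[[k - 1]]))
})

test_that("domains are invariant to TSS input order and duplicate TSS", {
  set.seed(432)
  si <- Seqinfo("chr1", 5e6)
  pos <- sort(sample(seq(20000, 4.9e6), 15))
  tss <- mkGR("chr1", pos, pos, gene_id = sprintf("g%02d", 1:15),
              seqinfo = si)
  d1 <- buildRegulatoryDomains(tss, seqinfo = si)
  d2 <- buildRegulatoryDomains(tss[sample(15)], seqinfo = si)
  expect_identical(d1, d2)
  ## a second TSS for one gene: the first in genomic order is canonical
  extra <- mkGR("chr1", pos[3] + 500, pos[3] + 500, gene_id = "g03",
                seqinfo = si)
  d3 <- buildRegulatoryDomains(c(tss, extra), seqinfo = si)
  expect_equal(d3$tss[d3$gene_id == "g03"], pos[3])
})

test_that("center-mode association matches brute-force containment", {
  set.seed(433)
  si <- Seqinfo("chr1", 5e6)
  pos <- sort(sample(seq(20000, 4.9e6), 20))
  tss <- mkGR("chr1", pos, pos, gene_id = sprintf("g%02d", 1:20),
              seqinfo = si)
  strand(tss) <- sample(c("+", "-"), 20, replace = TRUE)
  d <- buildRegulatoryDomains(tss, seqinfo = si)
  pk <- randGR(200, chroms = "chr1", maxPos = 5e6 - 200, maxWidth = 200)
  pk$name <- sprintf("p%03d", seq_along(pk))
  got <- associatePeaks(pk, d)
  centers <- peakCenters(pk)
  expected <- 0L
  for (i in seq_along(pk)) {
    inside <- which(centers[i] >= start(d) & centers[i] <= end(d))
    expected <- expected + length(inside)
    for (j in inside) {
      row <- got[got$peakIdx == i & got$gene_id == d$gene_id[j], ]
      expect_equal(nrow(row), 1L)
      s <- centers[i] - d$tss[j]
      expect_equal(row$distanceToTss,
                   if (as.character(strand(d))[j] == "-") -s else s)
    }
  }
  expect_equal(nrow(got), expected)
})

test_that("overlap mode associates strictly more peaks than center mode", {
  set.seed(434)
  si <- Seqinfo("chr1", 5e6)
  pos <- sort(sample(seq(20000, 4.9e6), 20))
  tss <- mkGR("chr1", pos, pos, gene_id = sprintf("g%02d", 1:20),
              seqinfo = si)
  d <- buildRegulatoryDomains(tss, domainParams(5000, 1000, 2e4),
                              seqinfo = si)
  pk <- randGR(300, chroms = "chr1", maxPos = 5e6 - 5000, maxWidth = 5000)
  a1 <- associatePeaks(pk, d, mode = "center")
  a2 <- associatePeaks(pk, d, mode = "overlap")
  expect_gte(nrow(a2), nrow(a1))
  ## every center association is also an overlap association
  expect_true(all(paste(a1$peakIdx, a1$gene_id) %in%
                    paste(a2$peakIdx, a2$gene_id)))
})
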