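test_that("CPM matches the closed form", {
  counts <- matrix(c(100, 900, 300, 700), 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- cpmMatrix(counts)
  expect_equal(unname(cpm[, 1]), c(100, 900) / 1000 * 1e6)
  expect_equal(unname(cpm[, 2]), c(300, 700) / 1000 * 1e6)
  ## normalization factors divide the effective library size
  cpm2 <- cpmMatrix(counts, normFactors = c(2, 1))
  expect_equal(unname(cpm2[, 1]), unname(cpm[, 1]) / 2)
  expect_error(cpmMatrix(counts, normFactors = c(0, 1)), "positive")
})

test_that("expression filter requires cpmMin in at least minSamples samples", {
  cpm <- rbind(g1 = c(1.0, 1.0, 1.0, 0.5),  # >= 1 in exactly 3 -> kept
               g2 = c(1.0, 1.0, 0.9, 0.5),  # >= 1 in 2 -> dropped
               g3 = c(5, 5, 5, 5))
  expect_equal(filterLowExpression(cpm), c("g1", "g3"))
  expect_equal(filterLowExpression(cpm, deParams(minSamples = 2)),
               c("g1", "g2", "g3"))
  expect_warning(filterLowExpression(cpm * 0), "below the expression filter")
})

test_that("TMM factors are exactly 1 for identical columns", {
  set.seed(440)
  y <- matrix(rnbinom(4000, mu = 100, size = 10), 1000, 4)
  y <- y[rowSums(y) > 0, ]
  f <- tmmFactors(cbind(a = y[, 1], b = y[, 1], c = y[, 1]))
  expect_equal(unname(f), rep(1, 3), tolerance = 1e-12)
})

test_that("a doubled library yields a TMM factor ratio of 2", {
  set.seed(441)
  base <- rnbinom(2000, mu = 200, size = 20) + 1L
  counts <- cbind(s1 = base, s2 = 2L * base)
  f <- tmmFactors(counts)
  ## every M value is exactly log2(2), so the trimmed mean is exact
  expect_equal(unname(f["s2"] / f["s1"]), 2, tolerance = 1e-9)
  expect_equal(prod(f), 1, tolerance = 1e-12)
})

test_that("planted abundance factors are recovered within 5%", {
  cfg <- simConfig(seed = 43, libFactors = c(1, 1.5, 0.7),
                   nSamplesPerGroup = 3, deFraction = 0)
  sim <- simulateCounts(cfg)
  f <- tmmFactors(sim$counts)
  expect_equal(unname(f), unname(sim$trueFactors), tolerance = 0.05)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("TMM agrees with edgeR's effective library scaling", {
  ## independent route: edgeR's factors f_e satisfy
  ## effective size = libSize * f_e; ours absorb the library size, so
  ## compare ours to rescaled f_e * libSize (both geometric mean 1).
  cfg <- simConfig(seed = 47, libFactors = c(1, 2, 0.5, 1.2),
                   nSamplesPerGroup = 2, deFraction = 0)
  sim <- simulateCounts(cfg)
  ours <- tmmFactors(sim$counts)
  fe <- edgeR::calcNormFactors(edgeR::DGEList(sim$counts), method = "TMM")
  eff <- fe$samples$norm.factors * fe$samples$lib.size
  eff <- eff / exp(mean(log(eff)))
  expect_equal(unname(ours), unname(eff), tolerance = 0.03)
})

test_that("Z-score clustering standardizes rows and orders deterministically", {
  set.seed(442)
  cpm <- matrix(rexp(60, 0.01), 10, 6,
                dimnames = list(sprintf("g%02d", 10:1), sprintf("s%d", 1:6)))
  cl <- zscoreCluster(cpm)
  expect_equal(unname(rowMeans(cl$z)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(cl$z, 1, sd)), rep(1, 10), tolerance = 1e-12)
  expect_equal(rownames(cl$z), sort(rownames(cpm)))
  flat <- cpm; flat["g05", ] <- 7
  expect_warning(zscoreCluster(flat), "zero-variance")
  expect_error(zscoreCluster(cpm[, 1, drop = FALSE]), "single sample")
})

test_that("callDE applies the FDR and fold-change thresholds exactly", {
  tab <- data.frame(
    gene = sprintf("g%d", 1:6),
    log2FC = c(0.5, -0.5, 0.2, 0.21, -0.21, 3),
    FDR = c(0.01, 0.01, 0.01, 0.01, 0.049, 0.05))
  de <- callDE(tab)
  ## g3: |lfc| not > 0.2; g6: FDR not < 0.05
  expect_equal(de$up, c("g1", "g4"))
  expect_equal(de$down, c("g2", "g5"))
  expect_equal(de$table$direction,
               c("up", "down", "ns", "up", "down", "ns"))
  ## independent recount
  sig <- tab$FDR < 0.05 & abs(tab$log2FC) > 0.2
  expect_setequal(c(de$up, de$down), tab$gene[sig])
  expect_error(callDE(tab[, 1:2]), "must have columns")
  expect_error(callDE(transform(tab, FDR = FDR * 100)), "lie in \\[0, 1\\]")
})

test_that("relaxing thresholds only grows the DE sets", {
  set.seed(443)
  tab <- data.frame(gene = sprintf("g%03d", 1:200),
                    log2FC = rnorm(200), FDR = runif(200))
  strict <- callDE(tab, deParams(fdrMax = 0.01, minAbsLog2fc = 1))
  loose <- callDE(tab, deParams(fdrMax = 0.2, minAbsLog2fc = 0.1))
  expect_true(all(strict$up %in% loose$up))
  expect_true(all(strict$down %in% loose$down))
  expect_length(intersect(loose$up, loose$down), 0)
})

test_that("the NB exact test finds planted DE genes", {
  cfg <- simConfig(seed = 53, countGenes = 600)
  sim <- simulateCounts(cfg)
  de <- callDE(nbExactTest(sim$counts, sim$group))
  truth <- sim$trueDe
  upTrue <- truth$gene[truth$label == "up"]
  downTrue <- truth$gene[truth$label == "down"]
  expect_gte(mean(upTrue %in% de$up), 0.9)
  expect_gte(mean(downTrue %in% de$down), 0.9)
  ## few false positives among null genes
  nullGenes <- truth$gene[truth$label == "ns"]
  expect_lte(mean(nullGenes %in% c(de$up, de$down)), 0.05)
})

test_that("hypergeometric overlap p equals exact enumeration (small universe)", {
  universe <- sprintf("g%02d", 1:25)
  bound <- universe[1:8]
  down <- universe[c(1, 2, 3, 10, 11)]
  ov <- boundDeOverlap(bound, list(down = down, up = character()), universe)
  expect_equal(ov$downFraction, 3 / 8)
  ## exact enumeration over all ways to draw |bound| genes from the universe
  N <- 25; K <- 5; n <- 8; k <- 3
  pExact <- sum(vapply(k:min(K, n), function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, 1))
  expect_equal(ov$pDown, pExact, tolerance = 1e-12)
  ## 2x2 table margins
  expect_equal(sum(ov$tables$down), N)
  expect_equal(sum(ov$tables$down[, "bound"]), n)
  expect_equal(sum(ov$tables$down["de", ]), K)
})

test_that("bound-vs-DE fractions on a planted 6%-overlap fixture", {
  bound <- sprintf("b%03d", 1:50)
  universe <- c(bound, sprintf("u%03d", 1:450))
  down <- c(bound[1:3], sprintf("u%03d", 1:47))  # 3/50 bound = 6%
  ov <- boundDeOverlap(bound, list(down = down, up = character()), universe)
  expect_equal(ov$downFraction, 0.06)
  expect_equal(ov$upFraction, 0)
  expect_error(boundDeOverlap(character(), list(down = down, up = character()),
                              universe), "empty")
})
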