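## Shared toy landscape: two genes with promoter elements, one TF panel.
toyLandscape <- function() {
  si <- Seqinfo("chr1", 1e6)
  tss <- mkGR("chr1", c(100000, 200000), c(100000, 200000),
              gene_id = c("gA", "gB"), seqinfo = si)
  catalog <- mkGR("chr1", c(99800, 199800, 150000), c(100200, 200200, 150400),
                  class = c("PLS", "PLS", "DNase-only"), seqinfo = si)
  domains <- buildRegulatoryDomains(tss, seqinfo = si)
  list(si = si, tss = tss, catalog = catalog, domains = domains)
}

test_that("edges require promoter/enhancer-class peaks", {
  L <- toyLandscape()
  ## one peak on gA's promoter, one on the DNase-only element
  pk <- mkGR("chr1", c(99900, 150100), c(100100, 150300),
             name = c("p1", "p2"), seqinfo = L$si)
  net <- inferNetwork(list(TFX = pk), catalog = L$catalog,
                      domains = L$domains)
  ed <- networkEdges(net)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$source, "TFX")
  expect_equal(ed$target, "gA")
  expect_equal(ed$weight, 1L)
  ## DNase-only evidence alone yields no edges
  net2 <- inferNetwork(list(TFX = pk[2]), catalog = L$catalog,
                       domains = L$domains)
  expect_equal(nrow(networkEdges(net2)), 0L)
})

test_that("edge weight counts supporting peaks and evidence lists them", {
  L <- toyLandscape()
  pk <- mkGR("chr1", c(99850, 100050), c(100050, 100250),
             name = c("p1", "p2"), seqinfo = L$si)
  net <- inferNetwork(list(TFX = pk), catalog = L$catalog,
                      domains = L$domains)
  ed <- net@edges
  expect_equal(ed$weight, 2L)
  expect_setequal(ed$evidence[[1]]$peak, c("p1", "p2"))
  expect_true(all(ed$evidence[[1]]$class == "PLS"))
})

test_that("self-loops are permitted when a TF binds its own promoter", {
  L <- toyLandscape()
  pk <- mkGR("chr1", 99900, 100100, name = "p1", seqinfo = L$si)
  net <- inferNetwork(list(gA = pk), catalog = L$catalog,
                      domains = L$domains)
  ed <- networkEdges(net)
  expect_equal(ed$source, "gA")
  expect_equal(ed$target, "gA")
})

test_that("noiseless planted networks are recovered perfectly", {
  cfg <- simConfig(seed = 17)
  ann <- simulateAnnotation(cfg)
  nd <- simulateNetworkData(cfg, ann)
  domains <- buildRegulatoryDomains(ann$tss, seqinfo = ann$seqinfo)
  net <- inferNetwork(nd$peakSets, catalog = ann$ccre, domains = domains)
  got <- paste(networkEdges(net)$source, networkEdges(net)$target)
  truth <- paste(nd$edges$source, nd$edges$target)
  expect_setequal(got, truth)  # precision = recall = 1
})

test_that("node statistics recount the edge list", {
  cfg <- simConfig(seed = 19, nTfs = 5, nGenes = 60, targetsPerTf = 10)
  ann <- simulateAnnotation(cfg)
  nd <- simulateNetworkData(cfg, ann)
  domains <- buildRegulatoryDomains(ann$tss, seqinfo = ann$seqinfo)
  net <- inferNetwork(nd$peakSets, catalog = ann$ccre, domains = domains)
  stats <- nodeStatistics(net)
  ed <- networkEdges(net)
  for (i in sample(nrow(stats), 10)) {
    n <- stats$node[i]
    expect_equal(stats$outDegree[i], sum(ed$source == n))
    expect_equal(stats$inDegree[i], sum(ed$target == n))
    expect_equal(stats$degree[i], stats$outDegree[i] + stats$inDegree[i])
  }
  ## interconnectivity counts only panel-internal edges
  panel <- networkFactors(net)
  sub <- ed[ed$source %in% panel & ed$target %in% panel, ]
  for (tf in panel) {
    expect_equal(stats$interconnectivity[stats$node == tf],
                 sum(sub$source == tf) + sum(sub$target == tf))
  }
})

test_that("the panel subgraph keeps only TF-to-TF edges", {
  cfg <- simConfig(seed = 23, nTfs = 5, nGenes = 60, targetsPerTf = 10)
  ann <- simulateAnnotation(cfg)
  nd <- simulateNetworkData(cfg, ann)
  domains <- buildRegulatoryDomains(ann$tss, seqinfo = ann$seqinfo)
  net <- inferNetwork(nd$peakSets, catalog = ann$ccre, domains = domains)
  sub <- tfPanelSubgraph(net)
  expect_true(all(networkEdges(sub)$target %in% networkFactors(net)))
  expect_equal(nrow(networkEdges(sub)),
               sum(networkEdges(net)$target %in% networkFactors(net)))
})

test_that("removing a factor never creates new edges", {
  cfg <- simConfig(seed = 29, nTfs = 4, nGenes = 50, targetsPerTf = 8)
  ann <- simulateAnnotation(cfg)
  nd <- simulateNetworkData(cfg, ann)
  domains <- buildRegulatoryDomains(ann$tss, seqinfo = ann$seqinfo)
  full <- inferNetwork(nd$peakSets, catalog = ann$ccre, domains = domains)
  drop1 <- inferNetwork(nd$peakSets[-1], catalog = ann$ccre,
                        domains = domains)
  fullKeys <- paste(networkEdges(full)$source, networkEdges(full)$target)
  dropKeys <- paste(networkEdges(drop1)$source, networkEdges(drop1)$target)
  expect_true(all(dropKeys %in% fullKeys))
  expect_false(names(nd$peakSets)[1] %in% networkEdges(drop1)$source)
})

test_that("TSV export round-trips and GraphML parses in igraph", {
  cfg <- simConfig(seed = 31, nTfs = 4, nGenes = 50, targetsPerTf = 8)
  ann <- simulateAnnotation(cfg)
  nd <- simulateNetworkData(cfg, ann)
  domains <- buildRegulatoryDomains(ann$tss, seqinfo = ann$seqinfo)
  net <- inferNetwork(nd$peakSets, catalog = ann$ccre, domains = domains)
  f <- withr::local_tempfile(fileext = ".tsv")
  exportNetwork(net, f)
  back <- importNetworkTsv(f)
  expect_equal(networkEdges(back), networkEdges(net))
  g <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(net, g, format = "graphml")
  ig <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::ecount(ig), nrow(networkEdges(net)))
  expect_true(igraph::is_directed(ig))
})
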