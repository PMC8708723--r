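#' @importFrom igraph graph_from_data_frame write_graph
NULL

#' Infer the directed TF-to-target network
#'
#' Two-step rule: (i) keep only peaks falling in promoter- or enhancer-like
#' cCRE elements (classes PLS, pELS, dELS); (ii) associate the retained peaks
#' to genes through basal-plus-extension regulatory domains. An edge
#' TF -> gene exists when at least one retained peak of the factor associates
#' with the gene; its weight is the number of supporting peaks and the
#' evidence list records peak names and element classes. Self-loops (a TF
#' bound at its own gene) are permitted.
#'
#' @param peakSets named list of per-factor peak `GRanges`.
#' @param catalog classified cCRE catalog `GRanges` (column `class`), or
#'   `NULL` if `classes` supplies per-factor class vectors directly.
#' @param domains regulatory domains from [buildRegulatoryDomains()].
#' @param classes optional named list of per-peak class character vectors
#'   (same order as `peakSets`); overrides `catalog`.
#' @return a [RegulatoryNetwork-class].
#' @export
inferNetwork <- function(peakSets, catalog = NULL, domains, classes = NULL) {
  if (is.null(names(peakSets)))
    stop("peakSets must be named by factor", call. = FALSE)
  if (is.null(classes)) {
    if (is.null(catalog))
      stop("either a classified catalog or per-peak classes are required",
           call. = FALSE)
    classes <- lapply(peakSets, assignPeakClasses, catalog = catalog)
  }
  edgeList <- list()
  for (tf in names(peakSets)) {
    pk <- peakSets[[tf]]
    cl <- classes[[tf]]
    if (is.null(cl) || length(cl) != length(pk))
      stop("factor missing class annotations: ", tf, call. = FALSE)
    keep <- cl %in% regulatoryClassLevels()
    if (!any(keep)) next
    pk <- pk[keep]
    cl <- cl[keep]
    assoc <- associatePeaks(pk, domains)
    if (!nrow(assoc)) next
    assoc$class <- cl[assoc$peakIdx]
    byGene <- split(assoc, assoc$gene_id)
    for (g in names(byGene)) {
      ev <- byGene[[g]]
      edgeList[[length(edgeList) + 1L]] <- list(
        source = tf, target = g, weight = nrow(ev),
        evidence = data.frame(peak = ev$peak, class = ev$class)
      )
    }
  }
  if (length(edgeList)) {
    edges <- data.frame(
      source = vapply(edgeList, `[[`, "", "source"),
      target = vapply(edgeList, `[[`, "", "target"),
      weight = vapply(edgeList, `[[`, 1L, "weight")
    )
    edges$evidence <- lapply(edgeList, `[[`, "evidence")
    o <- order(edges$source, edges$target)
    edges <- edges[o, , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(), target = character(),
                        weight = integer())
    edges$evidence <- list()
  }
  new("RegulatoryNetwork", edges = edges,
      factors = names(peakSets),
      genes = sort(unique(domains$gene_id)))
}

#' Per-node degree statistics
#'
#' Out-degree, in-degree and total degree per node, plus the
#' interconnectivity degree (in + out counted within the TF panel subgraph
#' only, i.e. edges whose source and target are both panel factors).
#'
#' @param network a `RegulatoryNetwork`.
#' @return data.frame with columns `node`, `outDegree`, `inDegree`, `degree`,
#'   `interconnectivity`.
#' @export
nodeStatistics <- function(network) {
  ed <- network@edges
  nodes <- sort(unique(c(network@factors, ed$source, ed$target)))
  outD <- vapply(nodes, function(n) sum(ed$source == n), 1L)
  inD <- vapply(nodes, function(n) sum(ed$target == n), 1L)
  panel <- network@factors
  sub <- ed[ed$source %in% panel & ed$target %in% panel, , drop = FALSE]
  inter <- vapply(nodes, function(n) {
    sum(sub$source == n) + sum(sub$target == n)
  }, 1L)
  data.frame(node = nodes, outDegree = outD, inDegree = inD,
             degree = outD + inD, interconnectivity = inter,
             row.names = NULL)
}

#' Subgraph restricted to the TF panel
#'
#' @param network a `RegulatoryNetwork`.
#' @return a `RegulatoryNetwork` keeping only edges whose target is itself a
#'   panel factor.
#' @export
tfPanelSubgraph <- function(network) {
  ed <- network@edges
  keep <- ed$target %in% network@factors
  new("RegulatoryNetwork", edges = ed[keep, , drop = FALSE],
      factors = network@factors, genes = network@genes)
}

#' Export a regulatory network
#'
#' `"tsv"` writes the edge list (source, target, weight); the TSV round-trips
#' through [importNetworkTsv()]. `"graphml"` writes GraphML via igraph.
#'
#' @param network a `RegulatoryNetwork`.
#' @param path output path.
#' @param format `"tsv"` or `"graphml"`.
#' @export
exportNetwork <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  ed <- networkEdges(network)
  if (format == "tsv") {
    writeTsv(ed, path)
  } else {
    g <- graph_from_data_frame(ed, directed = TRUE)
    write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge-list TSV back into a RegulatoryNetwork
#'
#' @param path TSV with columns `source`, `target`, `weight`.
#' @param factors optional TF panel (defaults to the sources present).
#' @return a `RegulatoryNetwork` (without evidence lists).
#' @export
importNetworkTsv <- function(path, factors = NULL) {
  ed <- readTsv(path)
  need <- c("source", "target", "weight")
  if (!all(need %in% names(ed)))
    stop("edge TSV must have source/target/weight columns", call. = FALSE)
  ed <- ed[order(ed$source, ed$target), need, drop = FALSE]
  ed$source <- as.character(ed$source)
  ed$target <- as.character(ed$target)
  rownames(ed) <- NULL
  if (is.null(factors)) factors <- sort(unique(ed$source))
  new("RegulatoryNetwork", edges = ed, factors = factors,
      genes = sort(unique(ed$target)))
}
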