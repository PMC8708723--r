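#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
NULL

pipelineSchema <- function() {
  list(
    required = c("outDir", "seed", "chromSizes", "tss", "ccre", "manifest",
                 "targetFactor"),
    optional = c("genomeFasta", "counts", "samples", "deTable", "boundClassUniverse",
                 "consensus", "ccreParams", "domains", "de", "motif",
                 "stages", "linkage")
  )
}

#' Validate a pipeline configuration
#'
#' Schema validation happens before any computation: required keys must be
#' present, unknown keys are rejected, and all referenced input files must
#' exist.
#'
#' @param config a named list, or the path of a YAML file holding one.
#' @return the validated config (invisibly usable downstream).
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_yaml(config)
  }
  schema <- pipelineSchema()
  missing <- setdiff(schema$required, names(config))
  if (length(missing))
    stop("config schema error: missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(config), c(schema$required, schema$optional))
  if (length(unknown))
    stop("config schema error: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (key in c("chromSizes", "tss", "ccre", "manifest", "genomeFasta",
                "counts", "samples", "deTable")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("config schema error: input for '", key, "' not found: ", p,
           call. = FALSE)
  }
  config
}

paramsFromConfig <- function(block, constructor) {
  if (is.null(block)) constructor() else do.call(constructor, block)
}

#' Run the integrative pipeline
#'
#' Stage order: replicate consensus for every factor, cCRE annotation of the
#' target factor's consensus peaks, panel co-occupancy scoring and Spearman
#' clustering, peak-to-gene association, directed network inference,
#' expression integration (consuming a DE table or computing the
#' synthetic-path NB exact test from counts), and consensus-motif
#' enrichment of target peak sequences against a dinucleotide-shuffled
#' background. Stages are individually skippable via `config$stages`.
#' Identical config and inputs give byte-identical outputs; the run report
#' carries no timestamps.
#'
#' @param config named list (or YAML path); see
#'   [validatePipelineConfig()]. Main keys: `outDir`, `seed`, `chromSizes`,
#'   `tss`, `ccre`, `manifest` (TSV with columns factor/rep1/rep2/track),
#'   `targetFactor`, optional `genomeFasta`, `counts`+`samples` or
#'   `deTable`, parameter blocks `consensus`, `ccreParams`, `domains`,
#'   `de`, `motif` (list with `consensus`).
#' @return the run report, invisibly (also written to
#'   `outDir/report.json`).
#' @export
runPipeline <- function(config) {
  config <- validatePipelineConfig(config)
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("consensus", "annotate", "cooccupancy",
                                 "peak2gene", "network", "expression",
                                 "motif")
  report <- list(version = as.character(utils::packageVersion("crenet")),
                 seed = config$seed,
                 parameters = config[setdiff(names(config), "outDir")],
                 stages = list())
  si <- readChromSizes(config$chromSizes)
  tss <- readTssBed(config$tss, seqinfo = si)
  ccre <- readCcreBed(config$ccre, seqinfo = si)
  manifest <- readTsv(config$manifest)
  ## manifest paths may be relative to the manifest's own directory
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p,
           file.path(dirname(config$manifest), p))
  }
  for (col in c("rep1", "rep2", "track"))
    if (col %in% names(manifest)) manifest[[col]] <- resolve(manifest[[col]])
  cparams <- paramsFromConfig(config$consensus, consensusParams)
  ccparams <- paramsFromConfig(config$ccreParams, ccreParams)
  dparams <- paramsFromConfig(config$domains, domainParams)
  deparams <- paramsFromConfig(config$de, deParams)
  target <- config$targetFactor
  if (!target %in% manifest$factor)
    stop("target factor '", target, "' absent from the manifest",
         call. = FALSE)

  consensusSets <- list()
  if ("consensus" %in% stages) {
    dir.create(file.path(outDir, "consensus"), showWarnings = FALSE)
    rows <- list()
    for (i in seq_len(nrow(manifest))) {
      tf <- manifest$factor[i]
      repA <- readPeaks(manifest$rep1[i], seqinfo = si)
      repB <- readPeaks(manifest$rep2[i], seqinfo = si)
      cons <- consensusPeaks(repA, repB, cparams)
      consensusSets[[tf]] <- consensusRanges(cons)
      writePeaks(consensusRanges(cons),
                 file.path(outDir, "consensus", paste0(tf, ".narrowPeak")))
      writeConsensusReport(cons, file.path(outDir, "consensus",
                                           paste0(tf, "_pairs.tsv")))
      rows[[tf]] <- data.frame(factor = tf, peaksIn = length(repA) + length(repB),
                               consensus = length(consensusRanges(cons)),
                               rankCorrelation = rankCorrelation(cons))
    }
    report$stages$consensus <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    writeTsv(report$stages$consensus, file.path(outDir, "consensus",
                                                "summary.tsv"))
  } else {
    for (i in seq_len(nrow(manifest))) {
      consensusSets[[manifest$factor[i]]] <-
        readPeaks(manifest$rep1[i], seqinfo = si)
    }
  }
  targetPeaks <- consensusSets[[target]]

  if ("annotate" %in% stages) {
    dir.create(file.path(outDir, "annotate"), showWarnings = FALSE)
    cls <- assignPeakClasses(targetPeaks, ccre)
    frac <- classDistribution(targetPeaks, ccre)
    writeTsv(data.frame(peak = targetPeaks$name, class = cls),
             file.path(outDir, "annotate", "peak_classes.tsv"))
    writeTsv(data.frame(class = names(frac), fraction = as.numeric(frac)),
             file.path(outDir, "annotate", "class_fractions.tsv"))
    report$stages$annotate <- list(nPeaks = length(targetPeaks),
                                   fractions = as.list(frac))
  }

  if ("cooccupancy" %in% stages) {
    dir.create(file.path(outDir, "cooccupancy"), showWarnings = FALSE)
    tracks <- lapply(seq_len(nrow(manifest)), function(i) {
      readBedGraph(manifest$track[i], seqinfo = si)
    })
    names(tracks) <- manifest$factor
    mr <- buildMergedRegions(consensusSets)
    se <- scoreMatrix(mr$regions, tracks)
    cl <- spearmanCluster(se)
    sc <- SummarizedExperiment::assay(se, "score")
    writeTsv(data.frame(chrom = as.character(seqnames(mr$regions)),
                        start = start(mr$regions) - 1L,
                        end = end(mr$regions), sc, check.names = FALSE),
             file.path(outDir, "cooccupancy", "scores.tsv"))
    writeTsv(data.frame(factor = rownames(cl$correlation), cl$correlation,
                        check.names = FALSE),
             file.path(outDir, "cooccupancy", "correlation.tsv"))
    writeNewick(cl$hclust, file.path(outDir, "cooccupancy", "dendrogram.nwk"))
    writeLines(cl$leafOrder, file.path(outDir, "cooccupancy",
                                       "leaf_order.txt"))
    jac <- jaccardMatrix(consensusSets)
    writeTsv(data.frame(factor = rownames(jac), jac, check.names = FALSE),
             file.path(outDir, "cooccupancy", "jaccard.tsv"))
    report$stages$cooccupancy <- list(nRegions = length(mr$regions),
                                      droppedRegions = cl$droppedRegions,
                                      leafOrder = cl$leafOrder)
  }

  domains <- buildRegulatoryDomains(tss, dparams, seqinfo = si)
  if ("peak2gene" %in% stages) {
    dir.create(file.path(outDir, "peak2gene"), showWarnings = FALSE)
    assoc <- associatePeaks(targetPeaks, domains)
    assoc$class <- assignPeakClasses(targetPeaks, ccre)[assoc$peakIdx]
    writeTsv(assoc[, c("peak", "gene_id", "distanceToTss", "class")],
             file.path(outDir, "peak2gene", "associations.tsv"))
    report$stages$peak2gene <- list(nPeaks = length(targetPeaks),
                                    nAssociations = nrow(assoc),
                                    nGenes = length(unique(assoc$gene_id)))
  }

  network <- NULL
  if ("network" %in% stages) {
    dir.create(file.path(outDir, "network"), showWarnings = FALSE)
    network <- inferNetwork(consensusSets, catalog = ccre, domains = domains)
    exportNetwork(network, file.path(outDir, "network", "edges.tsv"))
    exportNetwork(tfPanelSubgraph(network),
                  file.path(outDir, "network", "panel_edges.tsv"))
    exportNetwork(network, file.path(outDir, "network", "network.graphml"),
                  format = "graphml")
    writeTsv(nodeStatistics(network), file.path(outDir, "network",
                                                "degrees.tsv"))
    report$stages$network <- list(nEdges = nrow(network@edges),
                                  nFactors = length(network@factors))
  }

  if ("expression" %in% stages) {
    dir.create(file.path(outDir, "expression"), showWarnings = FALSE)
    if (!is.null(config$deTable)) {
      de <- callDE(readTsv(config$deTable), deparams)
    } else if (!is.null(config$counts)) {
      ctab <- readTsv(config$counts)
      counts <- as.matrix(ctab[, -1, drop = FALSE])
      rownames(counts) <- ctab[[1L]]
      groups <- readTsv(config$samples)
      cpm0 <- cpmMatrix(counts)
      kept <- filterLowExpression(cpm0, deparams)
      counts <- counts[kept, , drop = FALSE]
      writeLines(kept, file.path(outDir, "expression", "retained_genes.txt"))
      f <- tmmFactors(counts)
      writeTsv(data.frame(sample = names(f), tmmFactor = as.numeric(f)),
               file.path(outDir, "expression", "tmm_factors.tsv"))
      de <- callDE(nbExactTest(counts, groups$group), deparams)
    } else {
      stop("expression stage needs 'deTable' or 'counts'", call. = FALSE)
    }
    writeTsv(de$table, file.path(outDir, "expression", "de_table.tsv"))
    writeLines(de$up, file.path(outDir, "expression", "up_genes.txt"))
    writeLines(de$down, file.path(outDir, "expression", "down_genes.txt"))
    report$stages$expression <- list(nUp = length(de$up),
                                     nDown = length(de$down))
    ## bound-vs-DE overlap when the gene universes are shared
    if (!is.null(network)) {
      promoterBound <- unique(unlist(lapply(
        which(network@edges$source == target),
        function(i) {
          ev <- network@edges$evidence[[i]]
          if (any(ev$class == "PLS")) network@edges$target[i] else NULL
        })))
      universe <- unique(de$table$gene)
      if (length(intersect(promoterBound, universe))) {
        ov <- boundDeOverlap(promoterBound, de, universe)
        writeTsv(data.frame(universe = "promoter-bound",
                            nBound = ov$nBound,
                            downFraction = ov$downFraction,
                            upFraction = ov$upFraction,
                            pDown = ov$pDown, pUp = ov$pUp),
                 file.path(outDir, "expression", "bound_de_overlap.tsv"))
        report$stages$expression$downFraction <- ov$downFraction
      }
    }
  }

  if ("motif" %in% stages && !is.null(config$genomeFasta)) {
    dir.create(file.path(outDir, "motif"), showWarnings = FALSE)
    motifCfg <- config$motif %||% list(consensus = "NCGGAAMM")
    seqs <- peakSequences(targetPeaks, config$genomeFasta)
    enr <- motifEnrichment(motifCfg$consensus, seqs,
                           seed = config$seed)
    writeTsv(data.frame(motif = enr@motif, fgHits = enr@fgHits,
                        fgN = enr@fgN, bgHits = enr@bgHits, bgN = enr@bgN,
                        fold = enr@fold, pvalue = enr@pvalue),
             file.path(outDir, "motif", "enrichment.tsv"))
    report$stages$motif <- list(fold = enr@fold, pvalue = enr@pvalue)
  }

  write_json(report, file.path(outDir, "report.json"), auto_unbox = TRUE,
             digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(report)
}
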