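#' Run the full higher-order theme discovery pipeline
#'
#' Orchestrates the stages end to end: restrict the collection to the
#' measured-gene universe, compute pairwise similarity, threshold into the
#' overlap graph, prune disconnected gene-sets, detect themes with walktrap,
#' order them by the product of ranks, and characterise every theme with
#' TF-IDF term tables and gene-frequency tables (plus induced PPI
#' subnetworks when an interaction list is supplied). Deterministic for
#' fixed inputs and configuration.
#'
#' @param collection a \linkS4class{GeneSetCollection} or path to a GMT file.
#' @param setStats per-gene-set statistics: data.frame
#'   (\code{set_name}, \code{statistic}) or TSV path.
#' @param geneStats optional per-gene statistics: data.frame (\code{gene},
#'   \code{statistic}) or TSV path.
#' @param universe optional measured-gene universe. Default: the genes of
#'   the \code{geneStats} table when one is supplied (the measured genes are
#'   the genes with statistics), otherwise the union of all set members.
#' @param measure similarity measure (default \code{"ari"}).
#' @param threshold similarity threshold (default 0.25).
#' @param strict strict thresholding (default FALSE).
#' @param steps walktrap random-walk length (default 4).
#' @param direction,absolute cluster-ordering options, see [orderThemes()].
#' @param textSource \code{"name"} or \code{"description"} for annotation.
#' @param corpus reference collection for idf (default: \code{collection}).
#' @param exclusions exclusion words for the tokeniser.
#' @param topTerms terms per cluster (default 25).
#' @param ppi optional PPI edge data.frame (or TSV path) for per-cluster
#'   induced subnetworks.
#' @param minConfidence,minDegree,includeInferred PPI filters, see
#'   [induceSubnetwork()].
#' @param outDir optional directory; when given the report bundle is written
#'   there (see [writeReportBundle()]).
#' @param verbose log stage counts (default TRUE).
#' @return a report bundle: list with \code{partition}, \code{clusterTable},
#'   \code{dropped}, \code{graph}, \code{similarity}, \code{termTables},
#'   \code{geneTables}, \code{ppiNetworks}, \code{metadata}.
#' @export
runVisse <- function(collection, setStats, geneStats = NULL, universe = NULL,
                     measure = c("ari", "jaccard", "overlap"),
                     threshold = 0.25, strict = FALSE, steps = 4L,
                     direction = c("larger-better", "smaller-better"),
                     absolute = FALSE,
                     textSource = c("name", "description"), corpus = NULL,
                     exclusions = defaultExclusionWords(), topTerms = 25L,
                     ppi = NULL, minConfidence = 0, minDegree = 0L,
                     includeInferred = TRUE, outDir = NULL, verbose = TRUE) {
  measure <- match.arg(measure)
  direction <- match.arg(direction)
  textSource <- match.arg(textSource)
  log <- function(...) if (verbose) message(sprintf(...))

  if (is.character(collection)) collection <- readGmt(collection)
  if (is.character(setStats)) setStats <- readSetStats(setStats)
  if (is.character(geneStats)) geneStats <- readGeneStats(geneStats)
  if (is.character(ppi)) ppi <- readPpi(ppi)
  if (is.null(universe)) {
    universe <- if (!is.null(geneStats)) unique(geneStats$gene)
                else universe(collection)
  }
  collection <- restrictToUniverse(collection, universe)
  nInput <- length(collection)
  log("input: %d gene-set(s), universe of %d gene(s), %d empty after restriction",
      nInput, length(universe(collection)), length(emptySets(collection)))

  simmat <- pairwiseSimilarity(collection, measure = measure)
  g <- buildOverlapGraph(simmat, threshold = threshold, setStats = setStats,
                         setSizes = setSizes(collection), strict = strict)
  pruned <- pruneIsolated(g)
  emptyDropped <- setdiff(names(collection),
                          c(igraph::V(g)$name))
  dropped <- c(pruned$dropped, emptyDropped)
  g <- pruned$graph
  log("overlap graph (%s >= %g): %d node(s), %d edge(s); dropped %d disconnected set(s)",
      measure, threshold, igraph::vcount(g), igraph::ecount(g),
      length(dropped))

  partition <- detectThemes(g, steps = steps)
  partition <- orderThemes(partition, setStats, direction = direction,
                           absolute = absolute)
  log("walktrap: %d cluster(s)", nThemes(partition))

  termTables <- list(); geneTables <- list(); ppiNetworks <- NULL
  if (nThemes(partition) > 0L) {
    corpusIdf <- buildCorpusIdf(if (is.null(corpus)) collection else corpus,
                                source = textSource, exclusions = exclusions)
    termTables <- themeTermTables(collection, partition,
                                  corpusIdf = corpusIdf, topN = topTerms,
                                  exclusions = exclusions)
    geneTables <- themeGeneTables(collection, partition, geneStats)
    if (!is.null(ppi)) {
      ids <- sort(unique(themeMembership(partition)))
      ppiNetworks <- lapply(ids, function(cid) {
        genes <- unique(unlist(geneSets(collection)[themeMembers(partition, cid)],
                               use.names = FALSE))
        induceSubnetwork(ppi, genes, minConfidence = minConfidence,
                         minDegree = minDegree,
                         includeInferred = includeInferred,
                         geneStats = geneStats)
      })
      names(ppiNetworks) <- as.character(ids)
    }
  } else {
    log("note: no cluster survives the threshold; partition is empty")
  }

  bundle <- list(
    partition = partition,
    clusterTable = themeTable(partition),
    dropped = dropped,
    graph = g,
    similarity = simmat,
    termTables = termTables,
    geneTables = geneTables,
    ppiNetworks = ppiNetworks,
    metadata = list(
      nInputSets = nInput,
      nNodes = igraph::vcount(g),
      nEdges = igraph::ecount(g),
      nDropped = length(dropped),
      nClusters = nThemes(partition),
      nEmptySets = length(emptySets(collection)),
      universeSize = length(universe(collection)),
      parameters = list(measure = measure, threshold = threshold,
                        strict = strict, steps = steps,
                        direction = direction, absolute = absolute,
                        textSource = textSource, topTerms = topTerms,
                        minConfidence = minConfidence,
                        minDegree = minDegree,
                        includeInferred = includeInferred),
      packageVersion = as.character(utils::packageVersion("gsThemes"))
    )
  )
  if (!is.null(outDir)) writeReportBundle(bundle, outDir)
  bundle
}

#' Write a report bundle to a directory
#'
#' Emits the cluster table, the dropped-set list, long-form term and gene
#' tables, the pruned overlap graph (GraphML + TSV edge list), per-cluster
#' induced PPI graphs (GraphML), and a JSON metadata file recording all
#' parameters and stage counts.
#'
#' @param bundle a report bundle from [runVisse()].
#' @param dir output directory (created if missing).
#' @return invisibly, \code{dir}.
#' @export
writeReportBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeThemes(bundle$partition, file.path(dir, "clusters.tsv"))
  writeLines(bundle$dropped, file.path(dir, "dropped_sets.txt"))
  writeTermTables(bundle$termTables, file.path(dir, "term_tables.tsv"))
  geneRows <- lapply(names(bundle$geneTables), function(cid) {
    gt <- bundle$geneTables[[cid]]
    if (nrow(gt) == 0L) return(NULL)
    cbind(cluster = as.integer(cid), gt)
  })
  geneDf <- do.call(rbind, geneRows)
  if (is.null(geneDf))
    geneDf <- data.frame(cluster = integer(0), gene = character(0),
                         frequency = integer(0), statistic = numeric(0),
                         missingStat = logical(0))
  utils::write.table(geneDf, file.path(dir, "gene_tables.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (igraph::vcount(bundle$graph) > 0L) {
    exportGraph(bundle$graph, file.path(dir, "overlap_graph.graphml"),
                "graphml")
    exportGraph(bundle$graph, file.path(dir, "overlap_graph.tsv"), "tsv")
  }
  if (!is.null(bundle$ppiNetworks)) {
    for (cid in names(bundle$ppiNetworks)) {
      gg <- bundle$ppiNetworks[[cid]]
      if (igraph::vcount(gg) > 0L)
        exportGraph(gg, file.path(dir, sprintf("ppi_cluster_%s.graphml", cid)),
                    "graphml")
    }
  }
  jsonlite::write_json(bundle$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
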