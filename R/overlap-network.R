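#' Build the gene-set overlap graph by thresholding a similarity matrix
#'
#' Nodes are gene-sets; an edge joins X and Y when sim(X, Y) passes the
#' threshold (weak inequality \code{>=} by default, configurable to strict).
#' Edge weights carry the similarity value; nodes carry the set size and the
#' caller-supplied gene-set statistic (and optional direction). Empirically
#' useful adjusted-Rand thresholds sit in the 0.2-0.4 range; the default is
#' 0.25.
#'
#' @param simmat a \linkS4class{SimilarityMatrix}.
#' @param threshold similarity threshold (default 0.25).
#' @param setStats optional data.frame with columns \code{set_name},
#'   \code{statistic} and optionally \code{direction}; sets present in the
#'   matrix but absent here get an NA statistic with a warning.
#' @param setSizes optional named integer vector of set sizes to attach.
#' @param strict use strict \code{>} instead of \code{>=} at the threshold.
#' @return an undirected, simple, weighted \pkg{igraph} graph with vertex
#'   attributes \code{size}, \code{statistic}, \code{direction}.
#' @export
buildOverlapGraph <- function(simmat, threshold = 0.25, setStats = NULL,
                              setSizes = NULL, strict = FALSE) {
  stopifnot(is(simmat, "SimilarityMatrix"))
  v <- simmat@values
  adj <- if (strict) (v > threshold) else (v >= threshold)
  adj[!adj] <- FALSE
  w <- v * adj
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  nms <- igraph::V(g)$name
  if (!is.null(setSizes))
    igraph::V(g)$size <- as.integer(setSizes[nms])
  stat <- rep(NA_real_, length(nms))
  dirn <- rep(NA_character_, length(nms))
  if (!is.null(setStats)) {
    if (!all(c("set_name", "statistic") %in% names(setStats)))
      stop("setStats must have columns 'set_name' and 'statistic'")
    idx <- match(nms, setStats$set_name)
    if (anyNA(idx))
      warning(sprintf("no statistic supplied for %d gene-set(s); recorded as missing",
                      sum(is.na(idx))))
    stat <- as.numeric(setStats$statistic[idx])
    if ("direction" %in% names(setStats))
      dirn <- as.character(setStats$direction[idx])
  }
  igraph::V(g)$statistic <- stat
  igraph::V(g)$direction <- dirn
  g
}

#' Drop gene-sets without any connections
#'
#' Gene-sets with no edge above the threshold carry no overlap information
#' for theme detection and are removed from the graph. They are reported, not
#' discarded silently: disconnected sets can still be biologically relevant
#' outside the clustering.
#'
#' @param graph an overlap graph from [buildOverlapGraph()].
#' @return a list with \code{graph} (minimum degree >= 1) and \code{dropped}
#'   (set names in input vertex order).
#' @export
pruneIsolated <- function(graph) {
  deg <- igraph::degree(graph)
  dropped <- igraph::V(graph)$name[deg == 0]
  list(graph = igraph::delete_vertices(graph, dropped), dropped = dropped)
}

#' Export / import an overlap graph
#'
#' Serialises the graph with node attributes and edge weights to GraphML, a
#' TSV edge list (with a companion node table written alongside as
#' \code{<path>.nodes.tsv}), or node-link JSON.
#'
#' @param graph an \pkg{igraph} graph.
#' @param path output path.
#' @param format \code{"graphml"}, \code{"tsv"} or \code{"json"}.
#' @return invisibly, \code{path}.
#' @export
exportGraph <- function(graph, path, format = c("graphml", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else if (format == "tsv") {
    ed <- igraph::as_data_frame(graph, what = "edges")
    utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
    nd <- igraph::as_data_frame(graph, what = "vertices")
    utils::write.table(nd, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    nd <- igraph::as_data_frame(graph, what = "vertices")
    ed <- igraph::as_data_frame(graph, what = "edges")
    payload <- list(
      nodes = if (nrow(nd)) nd else list(),
      links = if (nrow(ed)) ed else list()
    )
    jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' @rdname exportGraph
#' @export
importGraph <- function(path, format = c("graphml", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (!is.null(igraph::vertex_attr(g, "id")) &&
        is.null(igraph::vertex_attr(g, "name")))
      igraph::V(g)$name <- igraph::vertex_attr(g, "id")
    return(g)
  }
  if (format == "tsv") {
    ed <- utils::read.delim(path, stringsAsFactors = FALSE)
    nd <- utils::read.delim(paste0(path, ".nodes.tsv"), stringsAsFactors = FALSE)
    return(igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nd))
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  nd <- as.data.frame(payload$nodes, stringsAsFactors = FALSE)
  ed <- as.data.frame(payload$links, stringsAsFactors = FALSE)
  if (nrow(nd) == 0L) return(igraph::make_empty_graph(directed = FALSE))
  if (!all(c("from", "to") %in% names(ed)))
    ed <- data.frame(from = character(0), to = character(0))
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nd)
}
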