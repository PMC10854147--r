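#' Identify gene-set clusters (higher-order themes) with walktrap
#'
#' Runs the Pons-Latapy walktrap algorithm (short random walks, agglomerative
#' merging, merge tree cut at maximum modularity) on the pruned overlap
#' graph. Edge weights (similarities) act as random-walk transition weights.
#' Clusters never span disconnected components. Cluster ids are renumbered
#' deterministically by the lexicographically smallest member name so that
#' output is stable regardless of internal community labels.
#'
#' @param graph an overlap graph (see [buildOverlapGraph()] and
#'   [pruneIsolated()]); may also contain isolated vertices, each of which
#'   forms its own singleton cluster.
#' @param steps random-walk length (default 4).
#' @return a \linkS4class{ThemePartition} (unordered; see [orderThemes()]).
#' @export
detectThemes <- function(graph, steps = 4L) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0L) {
    return(new("ThemePartition", membership = structure(integer(0), names = character(0)),
               clusters = data.frame(cluster = integer(0), size = integer(0),
                                     members = character(0),
                                     stringsAsFactors = FALSE),
               ordered = FALSE))
  }
  w <- igraph::E(graph)$weight
  if (!is.null(w) && any(w < 0))
    stop("edge weights must be non-negative for random-walk clustering")
  if (igraph::ecount(graph) == 0L) {
    memb <- seq_len(igraph::vcount(graph))
  } else {
    cm <- igraph::cluster_walktrap(graph, weights = w, steps = steps)
    memb <- igraph::membership(cm)
  }
  nms <- igraph::V(graph)$name
  names(memb) <- nms
  # deterministic relabelling: clusters ordered by their smallest member name
  first <- vapply(split(nms, memb), function(m) min(m), character(1))
  relab <- match(names(first), names(sort(first)))
  names(relab) <- names(first)
  memb <- relab[as.character(memb)]
  names(memb) <- nms
  members <- split(nms, memb)
  clusters <- data.frame(
    cluster = as.integer(names(members)),
    size = lengths(members),
    members = vapply(members, function(m) paste(sort(m), collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  new("ThemePartition",
      membership = structure(as.integer(memb), names = nms),
      clusters = clusters, ordered = FALSE)
}

#' @rdname ThemePartition-class
#' @export
setMethod("themeMembership", "ThemePartition", function(x) x@membership)

#' @rdname ThemePartition-class
#' @export
setMethod("themeTable", "ThemePartition", function(x) x@clusters)

#' @rdname ThemePartition-class
#' @export
setMethod("nThemes", "ThemePartition", function(x) nrow(x@clusters))

setMethod("show", "ThemePartition", function(object) {
  cat(sprintf("ThemePartition: %d gene-set(s) in %d cluster(s)%s\n",
              length(object@membership), nrow(object@clusters),
              if (object@ordered) " (ordered)" else ""))
  if (nrow(object@clusters)) {
    tab <- utils::head(object@clusters, 5L)
    tab$members <- ifelse(nchar(tab$members) > 40,
                          paste0(substr(tab$members, 1, 37), "..."),
                          tab$members)
    print(tab, row.names = FALSE)
    if (nrow(object@clusters) > 5L) cat("  ...\n")
  }
})

#' Order themes with the product-of-ranks statistic
#'
#' Clusters are prioritised so that large clusters with strong gene-set
#' statistics come first: the size rank (1 = largest) is multiplied by the
#' median-statistic rank (1 = best under \code{direction}), and clusters are
#' sorted ascending by this rank product (the lower the better). Ties in the
#' product are broken by the better statistic rank, then by cluster id.
#' Clusters whose members all lack a statistic get the worst statistic rank.
#'
#' @param partition a \linkS4class{ThemePartition}.
#' @param setStats data.frame with columns \code{set_name}, \code{statistic}.
#' @param direction \code{"larger-better"} (default; e.g. -log10 FDR or
#'   absolute logFC) or \code{"smaller-better"} (e.g. raw p-values).
#' @param absolute take \code{abs(statistic)} before the median, for signed
#'   two-sided statistics such as logFC.
#' @return the partition with \code{medianStat}, \code{sizeRank},
#'   \code{statRank}, \code{rankProduct} and \code{order} columns filled and
#'   the cluster table sorted by \code{order}.
#' @export
orderThemes <- function(partition, setStats,
                        direction = c("larger-better", "smaller-better"),
                        absolute = FALSE) {
  stopifnot(is(partition, "ThemePartition"))
  direction <- match.arg(direction)
  cl <- partition@clusters
  if (nrow(cl) == 0L) {
    partition@ordered <- TRUE
    return(partition)
  }
  stat <- setStats$statistic[match(names(partition@membership),
                                   setStats$set_name)]
  if (absolute) stat <- abs(stat)
  med <- vapply(split(stat, partition@membership),
                function(s) stats::median(s, na.rm = TRUE), numeric(1))
  cl$medianStat <- as.numeric(med[as.character(cl$cluster)])
  cl$sizeRank <- rank(-cl$size, ties.method = "average")
  key <- if (direction == "larger-better") -cl$medianStat else cl$medianStat
  key[is.na(key)] <- Inf   # missing statistic -> worst rank
  cl$statRank <- rank(key, ties.method = "average")
  cl$rankProduct <- cl$sizeRank * cl$statRank
  ord <- order(cl$rankProduct, cl$statRank, cl$cluster)
  cl <- cl[ord, , drop = FALSE]
  cl$order <- seq_len(nrow(cl))
  rownames(cl) <- NULL
  partition@clusters <- cl
  partition@ordered <- TRUE
  partition
}

#' Member gene-set names of one theme
#'
#' @param partition a \linkS4class{ThemePartition}.
#' @param cluster a cluster id.
#' @return character vector of gene-set names.
#' @export
themeMembers <- function(partition, cluster) {
  stopifnot(is(partition, "ThemePartition"))
  names(partition@membership)[partition@membership == cluster]
}

#' Export the cluster table as TSV
#'
#' @param partition a \linkS4class{ThemePartition}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeThemes <- function(partition, path) {
  stopifnot(is(partition, "ThemePartition"))
  utils::write.table(partition@clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
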