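ppiEdgeFrame <- function(gene_a = character(0), gene_b = character(0),
                         confidence = numeric(0), inferred = logical(0)) {
  data.frame(gene_a = as.character(gene_a), gene_b = as.character(gene_b),
             confidence = as.numeric(confidence),
             inferred = as.logical(inferred), stringsAsFactors = FALSE)
}

mitabId <- function(field) {
  # "uniprotkb:P12345|intact:EBI-123" -> first identifier value
  first <- vapply(strsplit(field, "|", fixed = TRUE), `[[`, character(1), 1L)
  sub("^[^:]*:", "", first)
}

mitabTaxid <- function(field) {
  out <- rep(NA_character_, length(field))
  has <- grepl("taxid:-?[0-9]+", field)
  out[has] <- sub("^taxid:", "",
                  regmatches(field, regexpr("taxid:-?[0-9]+", field)))
  out
}

mitabConfidence <- function(field) {
  m <- regmatches(field, regexpr("[0-9]*\\.?[0-9]+", field))
  has <- grepl("[0-9]*\\.?[0-9]+", field)
  out <- rep(NA_real_, length(field))
  out[has] <- as.numeric(m)
  out
}

#' Read a protein-protein interaction edge list
#'
#' Two dialects: \code{"tsv"} (canonical; header with columns \code{gene_a},
#' \code{gene_b}, \code{confidence} and optional \code{inferred}) and
#' \code{"psimitab"}, a minimal PSI-MI TAB 2.5 subset parsing interactor
#' identifiers (columns 1-2), interactor taxids (columns 10-11) and a
#' miscore-style confidence (column 15). Cross-species records (different
#' taxids) are dropped; self-edges are dropped; duplicated edges (same
#' unordered gene pair) are combined keeping the maximum confidence score.
#' Unparsable lines are skipped with a warning.
#'
#' @param path path to the interaction file.
#' @param dialect \code{"tsv"} (default) or \code{"psimitab"}.
#' @return a deduplicated PPI edge data.frame with columns \code{gene_a},
#'   \code{gene_b}, \code{confidence}, \code{inferred}.
#' @export
readPpi <- function(path, dialect = c("tsv", "psimitab")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(ppiEdgeFrame())
    if (!all(c("gene_a", "gene_b", "confidence") %in% names(df)))
      stop("PPI TSV must have columns 'gene_a', 'gene_b', 'confidence'")
    inferred <- if ("inferred" %in% names(df)) as.logical(df$inferred)
                else rep(FALSE, nrow(df))
    edges <- ppiEdgeFrame(df$gene_a, df$gene_b, as.numeric(df$confidence),
                          inferred)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) return(ppiEdgeFrame())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(fields) < 15L
    if (any(bad))
      warning(sprintf("skipped %d unparsable PSI-MI TAB line(s)", sum(bad)))
    fields <- fields[!bad]
    if (length(fields) == 0L) return(ppiEdgeFrame())
    ida <- mitabId(vapply(fields, `[[`, character(1), 1L))
    idb <- mitabId(vapply(fields, `[[`, character(1), 2L))
    taxa <- mitabTaxid(vapply(fields, `[[`, character(1), 10L))
    taxb <- mitabTaxid(vapply(fields, `[[`, character(1), 11L))
    conf <- mitabConfidence(vapply(fields, `[[`, character(1), 15L))
    sameSpecies <- !is.na(taxa) & !is.na(taxb) & taxa == taxb
    edges <- ppiEdgeFrame(ida[sameSpecies], idb[sameSpecies],
                          conf[sameSpecies],
                          rep(FALSE, sum(sameSpecies)))
  }
  dedupeEdges(edges)
}

#' Deduplicate PPI edges with the max-confidence rule
#'
#' Edges are unordered pairs; duplicated records of the same pair are
#' combined, keeping the maximum confidence score. A merged edge is flagged
#' inferred only if every contributing record was inferred (native evidence
#' wins). Self-edges are dropped. The operation is idempotent and
#' order-independent.
#'
#' @param edges a PPI edge data.frame (\code{gene_a}, \code{gene_b},
#'   \code{confidence}, \code{inferred}).
#' @return a deduplicated edge data.frame, sorted by gene pair.
#' @export
dedupeEdges <- function(edges) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0L) return(ppiEdgeFrame())
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  conf <- edges$confidence[keep]
  inf <- edges$inferred[keep]
  if (length(a) == 0L) return(ppiEdgeFrame())
  key <- paste(a, b, sep = "\r")
  ord <- order(key)
  key <- key[ord]; a <- a[ord]; b <- b[ord]; conf <- conf[ord]; inf <- inf[ord]
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  out <- ppiEdgeFrame(
    a[first], b[first],
    vapply(split(conf, grp), function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE), numeric(1)),
    vapply(split(inf, grp), all, logical(1))
  )
  rownames(out) <- NULL
  out
}

#' Infer cross-species PPI edges from an ortholog map
#'
#' Maps every edge endpoint through a (possibly one-to-many) two-column
#' ortholog table (columns: source id, target id). Edges with any unmappable
#' endpoint produce no inferred edge; mapped edges keep the original
#' confidence and are flagged \code{inferred = TRUE}. The inferred edges are
#' merged with \code{existing} (if supplied) under the max-confidence dedup
#' rule, so a native edge duplicated by inference keeps its native flag.
#'
#' @param edges source-organism PPI edge data.frame.
#' @param orthologTable data.frame whose first column holds source-organism
#'   ids and second column target-organism ids.
#' @param existing optional target-organism edges to merge with.
#' @return a PPI edge data.frame in the target organism.
#' @export
mapOrthologs <- function(edges, orthologTable, existing = NULL) {
  stopifnot(is.data.frame(edges), is.data.frame(orthologTable),
            ncol(orthologTable) >= 2L)
  src <- as.character(orthologTable[[1L]])
  tgt <- as.character(orthologTable[[2L]])
  inferred <- ppiEdgeFrame()
  if (nrow(edges) > 0L) {
    mapped <- lapply(seq_len(nrow(edges)), function(i) {
      ta <- tgt[src == edges$gene_a[i]]
      tb <- tgt[src == edges$gene_b[i]]
      if (length(ta) == 0L || length(tb) == 0L) return(NULL)
      grid <- expand.grid(gene_a = ta, gene_b = tb,
                          stringsAsFactors = FALSE)
      grid$confidence <- edges$confidence[i]
      grid$inferred <- TRUE
      grid
    })
    mapped <- mapped[!vapply(mapped, is.null, logical(1))]
    if (length(mapped))
      inferred <- do.call(rbind, mapped)
  }
  combined <- rbind(if (!is.null(existing)) existing else ppiEdgeFrame(),
                    inferred)
  dedupeEdges(combined)
}

#' Induce a PPI subnetwork on a cluster's genes
#'
#' Keeps edges whose both endpoints belong to the supplied gene-set-cluster
#' genes, whose confidence passes \code{minConfidence}, and (optionally)
#' drops ortholog-inferred edges. Node degree is then computed once on this
#' filtered graph; nodes below \code{minDegree} are removed together with
#' their incident edges, and nodes left isolated by that removal are removed
#' as well (no further iteration). Per-gene statistics are attached as a
#' vertex attribute when supplied.
#'
#' @param edges a PPI edge data.frame.
#' @param genes character vector of cluster gene ids.
#' @param minConfidence minimum edge confidence (default 0).
#' @param minDegree minimum node degree (default 0 = keep all).
#' @param includeInferred keep ortholog-inferred edges (default TRUE).
#' @param geneStats optional per-gene statistics (\code{gene},
#'   \code{statistic}).
#' @return an undirected simple \pkg{igraph} graph with vertex attributes
#'   \code{degree} (final degree) and \code{statistic}, and edge attributes
#'   \code{confidence} and \code{inferred}.
#' @export
induceSubnetwork <- function(edges, genes, minConfidence = 0,
                             minDegree = 0L, includeInferred = TRUE,
                             geneStats = NULL) {
  stopifnot(is.data.frame(edges))
  genes <- unique(as.character(genes))
  edges <- dedupeEdges(edges)
  keep <- edges$gene_a %in% genes & edges$gene_b %in% genes &
    !is.na(edges$confidence) & edges$confidence >= minConfidence
  if (!includeInferred) keep <- keep & !edges$inferred
  ed <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ed[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = sort(unique(c(ed$gene_a, ed$gene_b))),
                          stringsAsFactors = FALSE)
  )
  igraph::E(g)$confidence <- ed$confidence
  igraph::E(g)$inferred <- ed$inferred
  if (minDegree > 0L) {
    low <- igraph::V(g)$name[igraph::degree(g) < minDegree]
    g <- igraph::delete_vertices(g, low)
    isolated <- igraph::V(g)$name[igraph::degree(g) == 0]
    g <- igraph::delete_vertices(g, isolated)
  }
  igraph::V(g)$degree <- igraph::degree(g)
  stat <- rep(NA_real_, igraph::vcount(g))
  if (!is.null(geneStats) && nrow(geneStats) > 0L)
    stat <- as.numeric(geneStats$statistic[match(igraph::V(g)$name,
                                                 geneStats$gene)])
  igraph::V(g)$statistic <- stat
  g
}
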