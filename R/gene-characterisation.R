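#' Gene frequency across the gene-sets of a cluster
#'
#' For one theme (cluster of gene-sets), counts for every distinct member
#' gene the number of cluster gene-sets it belongs to. Computed on the
#' universe-restricted sets so the result reflects measured genes only. High
#' frequency genes are representative of the cluster's higher-order process.
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param members character vector of gene-set names forming the cluster.
#' @return data.frame with columns \code{gene}, \code{frequency}, one row per
#'   distinct gene of the cluster union.
#' @export
geneFrequency <- function(x, members) {
  stopifnot(is(x, "GeneSetCollection"), length(members) > 0L)
  missing <- setdiff(members, names(x))
  if (length(missing))
    stop(sprintf("unknown gene-set(s): %s", paste(missing, collapse = ", ")))
  genes <- unlist(x@sets[members], use.names = FALSE)
  if (length(genes) == 0L)
    return(data.frame(gene = character(0), frequency = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(genes)
  data.frame(gene = names(tab), frequency = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Attach per-gene experimental statistics to a frequency table
#'
#' Joins caller-supplied per-gene statistics (logFC, loadings, ...) to the
#' output of [geneFrequency()] by gene id. Genes with no statistic are
#' retained and flagged missing. The result is sorted by frequency
#' (descending), then by absolute statistic (descending), surfacing
#' high-frequency, high-statistic genes first.
#'
#' @param freqTable data.frame from [geneFrequency()].
#' @param geneStats data.frame with columns \code{gene}, \code{statistic}
#'   (or NULL for none).
#' @return the table with \code{statistic} and \code{missingStat} columns.
#' @export
attachGeneStatistics <- function(freqTable, geneStats = NULL) {
  stopifnot(is.data.frame(freqTable),
            all(c("gene", "frequency") %in% names(freqTable)))
  stat <- rep(NA_real_, nrow(freqTable))
  if (!is.null(geneStats) && nrow(geneStats) > 0L) {
    if (!all(c("gene", "statistic") %in% names(geneStats)))
      stop("geneStats must have columns 'gene' and 'statistic'")
    stat <- as.numeric(geneStats$statistic[match(freqTable$gene,
                                                 geneStats$gene)])
  }
  out <- freqTable
  out$statistic <- stat
  out$missingStat <- is.na(stat)
  absStat <- abs(stat)
  absStat[is.na(absStat)] <- -Inf
  out <- out[order(-out$frequency, -absStat, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene tables for every theme of a partition
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param partition a \linkS4class{ThemePartition}.
#' @param geneStats optional per-gene statistics data.frame.
#' @return named list (by cluster id) of gene tables.
#' @export
themeGeneTables <- function(x, partition, geneStats = NULL) {
  stopifnot(is(partition, "ThemePartition"))
  ids <- sort(unique(partition@membership))
  out <- lapply(ids, function(cid)
    attachGeneStatistics(geneFrequency(x, themeMembers(partition, cid)),
                         geneStats))
  names(out) <- as.character(ids)
  out
}
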