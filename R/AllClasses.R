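#' @import methods
NULL

#' GeneSetCollection: an ordered, named collection of gene-sets
#'
#' Holds named gene-sets (character vectors of gene identifiers with set
#' semantics), their free-text descriptions, and the measured-gene universe
#' over which all similarity computations are defined. Gene identifiers are
#' opaque, case-sensitive strings; no identifier conversion is attempted.
#'
#' @slot sets named list of character vectors; one element per gene-set,
#'   duplicate members collapsed.
#' @slot descriptions named character vector, parallel to \code{sets}.
#' @slot universe character vector of measured gene identifiers.
#' @slot emptySets character vector of names of sets that became empty when
#'   the collection was restricted to a universe; these are retained for
#'   reporting but excluded from similarity computations.
#'
#' @seealso [geneSetCollection()], [readGmt()], [restrictToUniverse()]
#' @export
setClass("GeneSetCollection",
  slots = c(
    sets = "list",
    descriptions = "character",
    universe = "character",
    emptySets = "character"
  )
)

setValidity("GeneSetCollection", function(object) {
  nm <- names(object@sets)
  if (length(object@sets) > 0L) {
    if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm)))
      return("all gene-sets must have non-empty names")
    if (anyDuplicated(nm))
      return(sprintf("duplicate gene-set name(s): %s",
                     paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (!all(vapply(object@sets, is.character, logical(1))))
      return("gene-set members must be character vectors")
    if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0L))
      return("gene-set members must be unique within a set")
  }
  if (!identical(names(object@descriptions), nm))
    return("descriptions must be named in parallel with the sets")
  if (anyDuplicated(object@universe))
    return("universe must not contain duplicate gene identifiers")
  if (!all(object@emptySets %in% nm))
    return("emptySets must name sets present in the collection")
  TRUE
})

#' SimilarityMatrix: pairwise gene-set similarity under one measure
#'
#' A symmetric square matrix of pairwise gene-set similarities keyed by
#' gene-set name, together with the measure used to compute it. The diagonal
#' is 1 for every (non-empty) set; Jaccard and overlap-coefficient entries
#' lie in [0, 1] while adjusted-Rand entries can be negative.
#'
#' @slot values symmetric numeric matrix with identical row/column names.
#' @slot measure one of \code{"ari"}, \code{"jaccard"}, \code{"overlap"}.
#' @slot universeSize number of measured genes the similarities refer to.
#'
#' @seealso [pairwiseSimilarity()]
#' @export
setClass("SimilarityMatrix",
  slots = c(values = "matrix", measure = "character", universeSize = "integer")
)

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("similarity matrix must be square")
  if (!identical(rownames(v), colnames(v)))
    return("row and column names must agree")
  if (nrow(v) > 0L && !isTRUE(all.equal(v, t(v), tolerance = 1e-8)))
    return("similarity matrix must be symmetric")
  if (length(object@measure) != 1L ||
      !object@measure %in% c("ari", "jaccard", "overlap"))
    return("measure must be one of 'ari', 'jaccard', 'overlap'")
  TRUE
})

#' ThemePartition: gene-set clusters and their ranking
#'
#' The result of community detection on the gene-set overlap graph: a
#' non-overlapping assignment of every (pruned-graph) gene-set to a cluster,
#' plus a per-cluster table. After [orderThemes()] the table additionally
#' carries the median gene-set statistic, the size and statistic ranks, the
#' rank product, and the final cluster order (1 = top theme; lower rank
#' product is better).
#'
#' @slot membership named integer vector mapping gene-set name to cluster id.
#' @slot clusters data.frame with one row per cluster: \code{cluster},
#'   \code{size}, \code{members} (semicolon-joined names), and, once ordered,
#'   \code{medianStat}, \code{sizeRank}, \code{statRank}, \code{rankProduct},
#'   \code{order}.
#' @slot ordered logical; has [orderThemes()] been applied?
#'
#' @seealso [detectThemes()], [orderThemes()]
#' @export
setClass("ThemePartition",
  slots = c(membership = "integer", clusters = "data.frame", ordered = "logical")
)

setValidity("ThemePartition", function(object) {
  m <- object@membership
  if (length(m) > 0L) {
    if (is.null(names(m)) || any(!nzchar(names(m))))
      return("membership must be named by gene-set")
    if (any(is.na(m)) || any(m < 1L))
      return("cluster ids must be positive integers")
    if (!all(sort(unique(m)) %in% object@clusters$cluster))
      return("every cluster id in membership must appear in the cluster table")
  }
  sz <- vapply(
    strsplit(object@clusters$members, ";", fixed = TRUE), length, integer(1)
  )
  if (length(sz) && !identical(as.integer(object@clusters$size), sz))
    return("cluster sizes must equal the member list lengths")
  TRUE
})

#' CorpusIdf: inverse document frequencies over a gene-set corpus
#'
#' Document frequencies and inverse document frequencies for every term
#' appearing in the tokenised names (or descriptions) of a reference gene-set
#' corpus. A gene-set counts once towards a term's document frequency
#' regardless of how often the term occurs in its text. idf(t) = log(N /
#' df(t)) in the configured base, so idf is 0 exactly for terms present in
#' every corpus gene-set.
#'
#' @slot N number of gene-sets in the corpus.
#' @slot df named integer vector of document frequencies.
#' @slot idf named numeric vector of inverse document frequencies.
#' @slot logBase base of the logarithm (\code{exp(1)} by default).
#' @slot source which text was mined, \code{"name"} or \code{"description"}.
#'
#' @seealso [buildCorpusIdf()], [clusterTermScores()]
#' @export
setClass("CorpusIdf",
  slots = c(N = "integer", df = "integer", idf = "numeric",
            logBase = "numeric", source = "character")
)

setValidity("CorpusIdf", function(object) {
  if (length(object@N) != 1L || object@N < 1L)
    return("corpus must contain at least one gene-set")
  if (!identical(names(object@df), names(object@idf)))
    return("df and idf must be named identically")
  if (length(object@df) && (any(object@df < 1L) || any(object@df > object@N)))
    return("document frequencies must lie in [1, N]")
  if (length(object@idf) && any(object@idf < -1e-12))
    return("idf must be non-negative")
  TRUE
})
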