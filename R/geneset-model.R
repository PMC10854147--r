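#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene identifiers. Duplicate
#'   members within a set are collapsed (set semantics).
#' @param descriptions optional named or unnamed character vector of free-text
#'   descriptions, recycled to empty strings when absent.
#' @param universe optional character vector of measured gene identifiers.
#'   When \code{NULL} (the default) the universe is the union of all set
#'   members, so the collection degrades gracefully when no experimental
#'   universe is supplied.
#'
#' @return a \linkS4class{GeneSetCollection}. Note the universe default does
#'   not restrict the sets; use [restrictToUniverse()] to impose an
#'   experimental universe.
#' @examples
#' gsc <- geneSetCollection(list(S1 = c("A", "B"), S2 = c("B", "C")))
#' universe(gsc)
#' @export
geneSetCollection <- function(sets, descriptions = NULL, universe = NULL) {
  stopifnot(is.list(sets))
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (is.null(descriptions)) {
    descriptions <- rep("", length(sets))
  }
  descriptions <- as.character(descriptions)
  if (length(descriptions) != length(sets))
    stop("descriptions must be one per gene-set")
  names(descriptions) <- names(sets)
  if (is.null(universe)) {
    universe <- unique(unlist(sets, use.names = FALSE))
    if (is.null(universe)) universe <- character(0)
  }
  new("GeneSetCollection",
      sets = sets, descriptions = descriptions,
      universe = as.character(universe), emptySets = character(0))
}

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("setDescriptions", "GeneSetCollection", function(x) x@descriptions)

#' @rdname GeneSetCollection-class
#' @export
setMethod("universe", "GeneSetCollection", function(x) x@universe)

#' @rdname GeneSetCollection-class
#' @export
setMethod("setSizes", "GeneSetCollection", function(x) {
  lengths(x@sets)
})

#' @rdname GeneSetCollection-class
#' @export
setMethod("emptySets", "GeneSetCollection", function(x) x@emptySets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname GeneSetCollection-class
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @rdname GeneSetCollection-class
#' @param i character, integer or logical index of gene-sets to keep.
#' @export
setMethod("[", "GeneSetCollection", function(x, i) {
  sets <- x@sets[i]
  if (any(vapply(sets, is.null, logical(1))))
    stop("undefined gene-sets selected")
  new("GeneSetCollection",
      sets = sets, descriptions = x@descriptions[names(sets)],
      universe = x@universe,
      emptySets = intersect(x@emptySets, names(sets)))
})

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection with %d gene-set(s) over %d universe gene(s)\n",
              length(object@sets), length(object@universe)))
  if (length(object@emptySets))
    cat(sprintf("  %d set(s) empty after universe restriction\n",
                length(object@emptySets)))
  nshow <- min(5L, length(object@sets))
  if (nshow > 0L) {
    for (nm in names(object@sets)[seq_len(nshow)])
      cat(sprintf("  %s (%d genes)\n", nm, length(object@sets[[nm]])))
    if (length(object@sets) > nshow) cat("  ...\n")
  }
})

#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-separated interchange format used by MSigDB: one gene-set
#' per line as \code{name<TAB>description<TAB>gene1<TAB>gene2...}. Duplicate
#' member tokens within a line are collapsed. Empty lines are skipped.
#'
#' @param path path to a GMT file (UTF-8).
#' @param universe optional measured-gene universe; defaults to the union of
#'   all members.
#' @return a \linkS4class{GeneSetCollection}.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("S1\tdemo set\tA\tB", f)
#' readGmt(f)
#' @export
readGmt <- function(path, universe = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    return(geneSetCollection(structure(list(), names = character(0)),
                             universe = universe))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields",
                 lineno[bad[1L]]))
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop(sprintf("duplicate gene-set name(s) in GMT: %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  desc <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(members) <- nms
  geneSetCollection(members, descriptions = desc, universe = universe)
}

#' Write a gene-set collection to a GMT file
#'
#' Member order is canonicalised (sorted) so that read/write round-trips are
#' byte-stable.
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGmt <- function(x, path) {
  stopifnot(is(x, "GeneSetCollection"))
  lines <- vapply(names(x@sets), function(nm) {
    paste(c(nm, x@descriptions[[nm]], sort(x@sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Restrict a collection to a measured-gene universe
#'
#' Intersects every gene-set with the supplied universe (the n genes measured
#' in the experiment). Sets rendered empty are retained but flagged in
#' [emptySets()]; they are excluded from similarity computation downstream
#' rather than silently dropped.
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param universe non-empty character vector of gene identifiers.
#' @return a restricted \linkS4class{GeneSetCollection} whose universe is
#'   \code{universe}.
#' @export
restrictToUniverse <- function(x, universe) {
  stopifnot(is(x, "GeneSetCollection"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe must be non-empty")
  sets <- lapply(x@sets, intersect, y = universe)
  empty <- names(sets)[lengths(sets) == 0L]
  new("GeneSetCollection", sets = sets, descriptions = x@descriptions,
      universe = universe, emptySets = empty)
}

#' Binary membership vector of one gene-set over the universe
#'
#' Encodes a gene-set as an n-dimensional 0/1 indicator over a fixed gene
#' ordering of the universe (the order in which \code{universe} is stored).
#'
#' @param members character vector of gene identifiers; must already lie
#'   inside the universe (restrict first).
#' @param universe character vector defining the gene ordering.
#' @return named integer vector of 0/1 with \code{sum} equal to the set size.
#' @export
membershipVector <- function(members, universe) {
  members <- unique(as.character(members))
  outside <- setdiff(members, universe)
  if (length(outside))
    stop(sprintf("gene(s) outside the universe: %s (restrict the collection first)",
                 paste(utils::head(outside, 5L), collapse = ", ")))
  v <- as.integer(universe %in% members)
  names(v) <- universe
  v
}

#' Binary membership matrix (genes x sets) of a collection
#'
#' @param x a \linkS4class{GeneSetCollection}, restricted to its universe.
#' @param dropEmpty drop sets flagged empty after restriction (default TRUE).
#' @return integer matrix, rows = universe genes, columns = gene-sets.
#' @export
membershipMatrix <- function(x, dropEmpty = TRUE) {
  stopifnot(is(x, "GeneSetCollection"))
  keep <- names(x@sets)
  if (dropEmpty) keep <- setdiff(keep, x@emptySets)
  m <- vapply(x@sets[keep], function(s) as.integer(x@universe %in% s),
              integer(length(x@universe)))
  m <- matrix(m, nrow = length(x@universe), ncol = length(keep),
              dimnames = list(x@universe, keep))
  m
}

#' Read per-gene-set or per-gene statistics tables
#'
#' Tab-separated tables with a header. Gene-set statistics need columns
#' \code{set_name} and \code{statistic} (optional \code{direction}); gene
#' statistics need \code{gene} and \code{statistic}. The statistic is any
#' caller-supplied numeric value (logFC, -log10 FDR, factor score, ...).
#'
#' @param path path to a TSV file.
#' @return a data.frame.
#' @export
readSetStats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("set_name", "statistic")
  if (!all(need %in% names(df)))
    stop("gene-set statistics TSV must have columns 'set_name' and 'statistic'")
  df$statistic <- as.numeric(df$statistic)
  df
}

#' @rdname readSetStats
#' @export
readGeneStats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "statistic")
  if (!all(need %in% names(df)))
    stop("gene statistics TSV must have columns 'gene' and 'statistic'")
  df$statistic <- as.numeric(df$statistic)
  df
}
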