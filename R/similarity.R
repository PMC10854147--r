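#' Contingency table between two gene-sets over the universe
#'
#' Cross-tabulates the measured-gene universe by joint membership in two
#' gene-sets X and Y: n11 = |X intersect Y|, n10 = |X \ Y|, n01 = |Y \ X|,
#' n00 = the remaining genes. Both sets must already be restricted to the
#' universe.
#'
#' @param x,y character vectors of gene identifiers (members of X and Y).
#' @param universe character vector of measured genes; must be non-empty.
#' @return an object of class \code{"ContingencyTable"}: a list with counts
#'   \code{n00, n01, n10, n11}, margins \code{a0, a1, b0, b1} and total
#'   \code{n}.
#' @examples
#' ct <- contingencyTable(LETTERS[1:4], LETTERS[3:6], LETTERS[1:10])
#' ct$n11
#' @export
contingencyTable <- function(x, y, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe must be non-empty")
  x <- unique(as.character(x)); y <- unique(as.character(y))
  out <- c(setdiff(x, universe), setdiff(y, universe))
  if (length(out))
    stop("sets must be restricted to the universe before building the table")
  n <- length(universe)
  n11 <- length(intersect(x, y))
  n10 <- length(x) - n11
  n01 <- length(y) - n11
  n00 <- n - n11 - n10 - n01
  structure(
    list(n00 = n00, n01 = n01, n10 = n10, n11 = n11,
         a0 = n00 + n01, a1 = n10 + n11, b0 = n00 + n10, b1 = n01 + n11,
         n = n),
    class = "ContingencyTable"
  )
}

#' @export
print.ContingencyTable <- function(x, ...) {
  m <- matrix(c(x$n00, x$n01, x$n10, x$n11), 2, 2, byrow = TRUE,
              dimnames = list(c("X=0", "X=1"), c("Y=0", "Y=1")))
  print(m)
  cat("n =", x$n, "\n")
  invisible(x)
}

choose2 <- function(k) k * (k - 1) / 2

#' Adjusted Rand index between two gene-sets
#'
#' Chance-corrected agreement between the binary in/out-of-set partitions of
#' the universe induced by two gene-sets. Equals 1 when the partitions are
#' identical and can be negative for agreement below chance. For degenerate
#' denominators (both partitions trivial, e.g. both sets empty or both equal
#' to the universe) the conventional value is 1 if the partitions are
#' identical and 0 otherwise.
#'
#' @param ct a \code{"ContingencyTable"} from [contingencyTable()].
#' @return a numeric similarity, at most 1.
#' @examples
#' ariIndex(contingencyTable(LETTERS[1:4], LETTERS[2:5], LETTERS[1:10]))
#' @export
ariIndex <- function(ct) {
  stopifnot(inherits(ct, "ContingencyTable"))
  if (ct$n < 2L) stop("adjusted Rand index requires a universe of size >= 2")
  sumnij <- choose2(ct$n00) + choose2(ct$n01) + choose2(ct$n10) + choose2(ct$n11)
  A <- choose2(ct$a0) + choose2(ct$a1)
  B <- choose2(ct$b0) + choose2(ct$b1)
  expected <- A * B / choose2(ct$n)
  denom <- (A + B) / 2 - expected
  if (denom == 0) {
    # both partitions trivial: identical as partitions (same blocks, labels
    # aside) -> 1, else 0
    same <- (ct$n10 == 0L && ct$n01 == 0L) || (ct$n11 == 0L && ct$n00 == 0L)
    return(if (same) 1 else 0)
  }
  (sumnij - expected) / denom
}

#' Jaccard index between two gene-sets
#'
#' n11 / (n01 + n10 + n11): the intersection over the union. Defined as 0
#' when both sets are empty.
#'
#' @inheritParams ariIndex
#' @return a numeric similarity in [0, 1].
#' @export
jaccardIndex <- function(ct) {
  stopifnot(inherits(ct, "ContingencyTable"))
  denom <- ct$n01 + ct$n10 + ct$n11
  if (denom == 0L) return(0)
  ct$n11 / denom
}

#' Overlap coefficient between two gene-sets
#'
#' n11 / min(|X|, |Y|): equals 1 whenever one set contains the other, which
#' highlights parent-child relationships in hierarchically structured
#' databases. Defined as 0 when either set is empty.
#'
#' @inheritParams ariIndex
#' @return a numeric similarity in [0, 1].
#' @export
overlapCoefficient <- function(ct) {
  stopifnot(inherits(ct, "ContingencyTable"))
  m <- min(ct$a1, ct$b1)
  if (m == 0L) return(0)
  ct$n11 / m
}

#' Pairwise gene-set similarity matrix
#'
#' Computes the symmetric matrix of pairwise similarities between all
#' non-empty gene-sets of a collection over its measured-gene universe,
#' under the adjusted Rand index, the Jaccard index, or the overlap
#' coefficient. The collection should be restricted to the universe first
#' (sets flagged empty after restriction are excluded).
#'
#' Internally the n11 counts for all pairs come from a single cross-product
#' of the binary membership matrix; each entry equals the corresponding
#' single-pair computation ([ariIndex()], [jaccardIndex()],
#' [overlapCoefficient()]).
#'
#' @param x a \linkS4class{GeneSetCollection} with at least 2 non-empty sets.
#' @param measure \code{"ari"} (default), \code{"jaccard"} or
#'   \code{"overlap"}.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
pairwiseSimilarity <- function(x, measure = c("ari", "jaccard", "overlap")) {
  stopifnot(is(x, "GeneSetCollection"))
  measure <- match.arg(measure)
  M <- membershipMatrix(x, dropEmpty = TRUE)
  if (ncol(M) < 2L)
    stop("pairwise similarity needs at least 2 non-empty gene-sets")
  n <- length(x@universe)
  sizes <- colSums(M)
  n11 <- crossprod(M)                      # |X intersect Y| for all pairs
  # rows of the output correspond to set X, columns to set Y
  szX <- matrix(sizes, ncol(M), ncol(M), byrow = FALSE)
  szY <- matrix(sizes, ncol(M), ncol(M), byrow = TRUE)
  vals <- switch(measure,
    jaccard = {
      denom <- szX + szY - n11
      out <- ifelse(denom == 0, 0, n11 / denom)
      out
    },
    overlap = {
      m <- pmin(szX, szY)
      ifelse(m == 0, 0, n11 / m)
    },
    ari = {
      if (n < 2L) stop("adjusted Rand index requires a universe of size >= 2")
      n10 <- szX - n11
      n01 <- szY - n11
      n00 <- n - szX - szY + n11
      sumnij <- choose2(n00) + choose2(n01) + choose2(n10) + choose2(n11)
      A <- choose2(n - szX) + choose2(szX)
      B <- choose2(n - szY) + choose2(szY)
      expected <- A * B / choose2(n)
      denom <- (A + B) / 2 - expected
      out <- ifelse(denom == 0,
                    ifelse((n10 == 0 & n01 == 0) | (n11 == 0 & n00 == 0), 1, 0),
                    (sumnij - expected) / denom)
      out
    }
  )
  vals <- (vals + t(vals)) / 2   # enforce exact symmetry against fp noise
  dimnames(vals) <- dimnames(n11)
  new("SimilarityMatrix", values = vals, measure = measure,
      universeSize = as.integer(n))
}

#' @rdname SimilarityMatrix-class
#' @export
setMethod("simMeasure", "SimilarityMatrix", function(x) x@measure)

#' @rdname SimilarityMatrix-class
#' @export
setMethod("dim", "SimilarityMatrix", function(x) dim(x@values))

#' @rdname SimilarityMatrix-class
#' @export
as.matrix.SimilarityMatrix <- function(x, ...) x@values

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s) for %d gene-set(s), universe n = %d\n",
              object@measure, nrow(object@values), object@universeSize))
  off <- object@values[upper.tri(object@values)]
  if (length(off))
    cat(sprintf("  off-diagonal range: [%.4g, %.4g]\n", min(off), max(off)))
})

#' Export a similarity matrix as a long-form TSV
#'
#' Writes one row per unordered pair: \code{setA, setB, measure, value}.
#'
#' @param x a \linkS4class{SimilarityMatrix}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSimilarity <- function(x, path) {
  stopifnot(is(x, "SimilarityMatrix"))
  v <- x@values
  idx <- which(upper.tri(v), arr.ind = TRUE)
  df <- data.frame(
    setA = rownames(v)[idx[, 1L]],
    setB = colnames(v)[idx[, 2L]],
    measure = x@measure,
    value = v[idx],
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
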