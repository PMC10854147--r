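#' Rank genes by factor loading
#'
#' Ascending ranks (1 = smallest loading, n = largest) with mid-ranked ties,
#' as used for rank-based single-sample gene-set scoring of factor loadings
#' (e.g. principal-component gene loadings). Genes with missing loadings are
#' excluded with a message.
#'
#' @param loadings named numeric vector, one loading per gene.
#' @return named numeric vector of ranks over the retained genes.
#' @export
rankByLoading <- function(loadings) {
  if (is.null(names(loadings)) || any(!nzchar(names(loadings))))
    stop("loadings must be named by gene")
  drop <- is.na(loadings)
  if (any(drop)) {
    message(sprintf("excluding %d gene(s) with missing loadings", sum(drop)))
    loadings <- loadings[!drop]
  }
  if (length(loadings) < 2L) stop("need at least 2 genes with loadings")
  rank(loadings, ties.method = "average")
}

#' Rank-based (singscore-style) gene-set score against ranked loadings
#'
#' The normalised, centred mean rank of the scored members: with n ranked
#' genes and m = |members in the ranked list|, the score is
#' \deqn{(\bar R - (m+1)/2) / (n - m) - 1/2,} which spans exactly
#' [-0.5, +0.5]: +0.5 when the members occupy the top m ranks and -0.5 when
#' they occupy the bottom m. Scores are invariant under strictly monotone
#' transforms of the loadings and antisymmetric under loading negation.
#'
#' @param ranks named rank vector from [rankByLoading()].
#' @param members character vector of gene ids (a gene-set).
#' @return a list with \code{size} (m), \code{meanRank} and \code{score};
#'   \code{score} is NA (degenerate, with a warning) when no member is
#'   ranked or when the set covers the whole ranked list.
#' @examples
#' r <- rankByLoading(c(a = .1, b = .5, c = -.2, d = .9))
#' setScore(r, c("b", "d"))$score
#' @export
setScore <- function(ranks, members) {
  n <- length(ranks)
  members <- unique(as.character(members))
  inRanks <- members[members %in% names(ranks)]
  m <- length(inRanks)
  if (m == 0L) {
    warning("no gene-set member is in the ranked list; score undefined")
    return(list(size = 0L, meanRank = NA_real_, score = NA_real_))
  }
  if (m == n) {
    warning("gene-set covers the entire ranked list; score undefined")
    return(list(size = m, meanRank = mean(ranks), score = NA_real_))
  }
  meanRank <- mean(ranks[inRanks])
  score <- (meanRank - (m + 1) / 2) / (n - m) - 0.5
  list(size = m, meanRank = meanRank, score = score)
}

#' Score every gene-set of a collection against factor loadings
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param loadings named numeric vector of per-gene loadings.
#' @return data.frame with columns \code{set_name}, \code{size_scored},
#'   \code{score}; degenerate sets carry NA scores.
#' @export
scoreCollection <- function(x, loadings) {
  stopifnot(is(x, "GeneSetCollection"))
  ranks <- rankByLoading(loadings)
  rows <- lapply(names(x@sets), function(nm) {
    s <- suppressWarnings(setScore(ranks, x@sets[[nm]]))
    data.frame(set_name = nm, size_scored = s$size, score = s$score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select gene-sets by absolute score for theme detection
#'
#' Keeps gene-sets with |score| strictly greater than the threshold (default
#' 0.2, the working cut-off for factor-loading workflows) and returns them as
#' a gene-set statistics table ready for [buildOverlapGraph()]: the score is
#' the statistic and its sign the direction.
#'
#' @param scores data.frame from [scoreCollection()].
#' @param threshold absolute-score threshold (default 0.2).
#' @return data.frame with columns \code{set_name}, \code{statistic},
#'   \code{direction} ("up"/"down").
#' @export
selectScoredSets <- function(scores, threshold = 0.2) {
  stopifnot(is.data.frame(scores),
            all(c("set_name", "score") %in% names(scores)))
  keep <- !is.na(scores$score) & abs(scores$score) > threshold
  out <- data.frame(
    set_name = scores$set_name[keep],
    statistic = scores$score[keep],
    direction = ifelse(scores$score[keep] >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read a per-gene loading table
#'
#' TSV with columns \code{gene} and \code{loading}.
#'
#' @param path path to the TSV.
#' @return named numeric vector of loadings.
#' @export
readLoadings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "loading") %in% names(df)))
    stop("loadings TSV must have columns 'gene' and 'loading'")
  structure(as.numeric(df$loading), names = as.character(df$gene))
}
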