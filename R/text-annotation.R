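the_word_cache <- new.env(parent = emptyenv())

readWordFile <- function(file) {
  path <- system.file("extdata", file, package = "gsThemes", mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Default stop-word and exclusion-word lists
#'
#' The stop words are the standard English (Snowball-style) list packaged
#' under \code{inst/extdata}. The exclusion words are database
#' prefixes/suffixes commonly used to name gene-set collections (kegg,
#' reactome, hallmark, gobp, ...); informative biological words such as
#' "pathway" or "signaling" are deliberately not excluded. Both lists are
#' plain-text files the user can replace.
#'
#' @return a character vector of lowercase words.
#' @export
defaultStopWords <- function() {
  if (is.null(the_word_cache$stop))
    the_word_cache$stop <- readWordFile("stopwords_en.txt")
  the_word_cache$stop
}

#' @rdname defaultStopWords
#' @export
defaultExclusionWords <- function() {
  if (is.null(the_word_cache$excl))
    the_word_cache$excl <- readWordFile("exclusion_words.txt")
  the_word_cache$excl
}

#' Dictionary + rule English lemmatiser
#'
#' Maps plural word forms to their lemma: a small packaged exception
#' dictionary (matrices -> matrix, analyses -> analysis, mice -> mouse, ...)
#' is consulted first, then regular plural-stripping rules are applied
#' (-ies -> -y; -xes/-ses/-zes/-ches/-shes -> drop "es"; trailing -s dropped
#' except after s/u/i). Words not matching any rule map to themselves.
#'
#' @param words character vector of lowercase words.
#' @return character vector of lemmas, same length.
#' @export
lemmatizeWords <- function(words) {
  if (length(words) == 0L) return(character(0))
  if (is.null(the_word_cache$lemma)) {
    path <- system.file("extdata", "lemma_exceptions.tsv",
                        package = "gsThemes", mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    the_word_cache$lemma <- structure(tab$lemma, names = tab$word)
  }
  dict <- the_word_cache$lemma
  out <- words
  hit <- words %in% names(dict)
  out[hit] <- dict[words[hit]]
  reg <- !hit
  out[reg] <- sub("(?<=[a-z]{2})ies$", "y", out[reg], perl = TRUE)
  out[reg] <- sub("(?<=[a-z])(ss|x|z|ch|sh)es$", "\\1", out[reg], perl = TRUE)
  out[reg] <- sub("(?<=[a-z]{2})(?<![sui])s$", "", out[reg], perl = TRUE)
  out
}

#' Tokenise gene-set names or descriptions
#'
#' Applies the text-cleaning pipeline used for theme annotation: text is
#' split on the characters \code{_ / @ ( ) |} and whitespace; everything is
#' lowercased; punctuation characters are stripped; purely numeric tokens,
#' English stop words and exclusion words are removed; the remaining words
#' are lemmatised (see [lemmatizeWords()]) and the exclusion lists are
#' re-applied to the lemmas.
#'
#' @param text character vector; each element is tokenised separately.
#' @param exclusions words to exclude (default [defaultExclusionWords()]);
#'   user words are matched after lowercasing.
#' @param stopWords stop-word list (default [defaultStopWords()]).
#' @param lemmatize apply lemmatisation (default TRUE).
#' @return a list of character vectors of tokens (one per input element).
#' @examples
#' tokenizeText("HALLMARK_EPITHELIAL_MESENCHYMAL_TRANSITION")[[1]]
#' @export
tokenizeText <- function(text, exclusions = defaultExclusionWords(),
                         stopWords = defaultStopWords(), lemmatize = TRUE) {
  exclusions <- tolower(exclusions)
  stopWords <- tolower(stopWords)
  toks <- strsplit(tolower(as.character(text)), "[_/@()|[:space:]]+")
  lapply(toks, function(tk) {
    tk <- gsub("[[:punct:]]", "", tk)
    tk <- tk[nzchar(tk)]
    tk <- tk[!grepl("^[0-9]+([.][0-9]+)?$", tk)]
    tk <- tk[!(tk %in% stopWords) & !(tk %in% exclusions)]
    if (lemmatize) {
      tk <- lemmatizeWords(tk)
      tk <- tk[!(tk %in% stopWords) & !(tk %in% exclusions)]
    }
    tk
  })
}

collectionText <- function(x, source = c("name", "description")) {
  source <- match.arg(source)
  if (source == "name") names(x) else as.character(setDescriptions(x))
}

#' Build corpus-wide inverse document frequencies
#'
#' Each gene-set's tokenised name (or description) is one document; df(t) is
#' the number of gene-sets whose token set contains t, and idf(t) =
#' log(N / df(t)). Using the full reference collection (e.g. all of MSigDB)
#' as the corpus down-weights words over-represented in the database.
#'
#' @param corpus a \linkS4class{GeneSetCollection} (non-empty).
#' @param source mine \code{"name"} (default) or \code{"description"}.
#' @param exclusions,stopWords,lemmatize passed to [tokenizeText()].
#' @param logBase base of the idf logarithm: \code{exp(1)} (default) or 2.
#' @return a \linkS4class{CorpusIdf}.
#' @export
buildCorpusIdf <- function(corpus, source = c("name", "description"),
                           exclusions = defaultExclusionWords(),
                           stopWords = defaultStopWords(),
                           lemmatize = TRUE, logBase = exp(1)) {
  stopifnot(is(corpus, "GeneSetCollection"), length(corpus) > 0L)
  source <- match.arg(source)
  toks <- tokenizeText(collectionText(corpus, source), exclusions = exclusions,
                       stopWords = stopWords, lemmatize = lemmatize)
  N <- length(toks)
  df <- table(unlist(lapply(toks, unique), use.names = FALSE))
  df <- structure(as.integer(df), names = names(df))
  idf <- log(N / df) / log(logBase)
  new("CorpusIdf", N = as.integer(N), df = df, idf = idf,
      logBase = logBase, source = source)
}

setMethod("show", "CorpusIdf", function(object) {
  cat(sprintf("CorpusIdf: %d term(s) over %d gene-set(s) (source = %s, log base %s)\n",
              length(object@df), object@N, object@source,
              if (isTRUE(all.equal(object@logBase, exp(1)))) "e"
              else format(object@logBase)))
})

#' TF-IDF term scores for one gene-set cluster
#'
#' The tokenised names (or descriptions) of all gene-sets in a cluster form
#' one document; tf(t) is the raw count of t in that document and tfidf(t) =
#' tf(t) x idf(t) against the corpus. Up to \code{topN} terms with the
#' highest tf-idf represent the cluster (ties broken alphabetically). Terms
#' absent from the corpus (possible when the cluster text differs from the
#' corpus source) are scored with df = 1 (maximal idf) and flagged.
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param members character vector of gene-set names forming the cluster.
#' @param corpusIdf a \linkS4class{CorpusIdf} from [buildCorpusIdf()].
#' @param topN maximum number of terms returned (default 25).
#' @param exclusions,stopWords,lemmatize passed to [tokenizeText()].
#' @param relativeTf divide tf by the document length (default FALSE: raw
#'   counts).
#' @return data.frame with columns \code{term}, \code{tf}, \code{idf},
#'   \code{tfidf}, \code{rank}, \code{novelTerm}, sorted descending by
#'   \code{tfidf}.
#' @export
clusterTermScores <- function(x, members, corpusIdf, topN = 25L,
                              exclusions = defaultExclusionWords(),
                              stopWords = defaultStopWords(),
                              lemmatize = TRUE, relativeTf = FALSE) {
  stopifnot(is(x, "GeneSetCollection"), is(corpusIdf, "CorpusIdf"),
            length(members) > 0L)
  missing <- setdiff(members, names(x))
  if (length(missing))
    stop(sprintf("unknown gene-set(s): %s", paste(missing, collapse = ", ")))
  txt <- collectionText(x[members], corpusIdf@source)
  toks <- unlist(tokenizeText(txt, exclusions = exclusions,
                              stopWords = stopWords, lemmatize = lemmatize),
                 use.names = FALSE)
  if (length(toks) == 0L) {
    return(data.frame(term = character(0), tf = numeric(0), idf = numeric(0),
                      tfidf = numeric(0), rank = integer(0),
                      novelTerm = logical(0), stringsAsFactors = FALSE))
  }
  tf <- table(toks)
  tf <- structure(as.numeric(tf), names = names(tf))
  if (relativeTf) tf <- tf / sum(tf)
  idf <- corpusIdf@idf[names(tf)]
  novel <- is.na(idf)
  idf[novel] <- log(corpusIdf@N / 1) / log(corpusIdf@logBase)
  if (any(novel))
    warning(sprintf("%d term(s) absent from the corpus; scored with df = 1",
                    sum(novel)))
  tfidf <- tf * idf
  ord <- order(-tfidf, names(tf))
  keep <- utils::head(ord, topN)
  out <- data.frame(
    term = names(tf)[keep], tf = tf[keep], idf = as.numeric(idf[keep]),
    tfidf = as.numeric(tfidf[keep]), rank = seq_along(keep),
    novelTerm = novel[keep], stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' Term tables for every theme of a partition
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param partition a \linkS4class{ThemePartition}.
#' @param corpusIdf a \linkS4class{CorpusIdf}; defaults to an idf built from
#'   \code{x} itself (use the full reference database when available).
#' @param ... passed to [clusterTermScores()].
#' @return named list (by cluster id) of term-score data.frames.
#' @export
themeTermTables <- function(x, partition, corpusIdf = NULL, ...) {
  stopifnot(is(partition, "ThemePartition"))
  if (is.null(corpusIdf)) corpusIdf <- buildCorpusIdf(x)
  ids <- sort(unique(partition@membership))
  out <- lapply(ids, function(cid)
    clusterTermScores(x, themeMembers(partition, cid), corpusIdf, ...))
  names(out) <- as.character(ids)
  out
}

#' Export term tables as one long TSV
#'
#' Columns: cluster, term, tf, idf, tfidf, rank.
#'
#' @param termTables named list from [themeTermTables()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTermTables <- function(termTables, path) {
  rows <- lapply(names(termTables), function(cid) {
    tt <- termTables[[cid]]
    if (nrow(tt) == 0L) return(NULL)
    cbind(cluster = as.integer(cid),
          tt[, c("term", "tf", "idf", "tfidf", "rank")])
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(cluster = integer(0), term = character(0),
                     tf = numeric(0), idf = numeric(0), tfidf = numeric(0),
                     rank = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
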