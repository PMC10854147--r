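#' Simulate a gene-set collection with planted theme structure
#'
#' Generates a synthetic benchmark in which the ground truth is known at
#' every level, so the whole pipeline (similarity, graph, clustering,
#' annotation, gene tables, scoring) can be validated without downloads.
#' Each of K themes owns a disjoint pool of P genes (optionally overlapping
#' between consecutive themes via \code{poolOverlap}); every theme generates
#' s gene-sets, each sampling \code{ceiling(f * P)} genes from its pool plus
#' q uniform background genes. Set names concatenate the theme keyword with
#' random filler tokens and a numeric index using "_" separators (numeric
#' tokens exercise the tokeniser and are removed there). Per-gene statistics
#' are Normal(theme mean, themeSd) for pool genes and Normal(0, backgroundSd)
#' otherwise; each set's statistic is the mean statistic of its members.
#'
#' Output is fully determined by \code{seed}.
#'
#' @param n universe size (default 5000).
#' @param K number of themes (default 5).
#' @param setsPerTheme gene-sets per theme (default 20).
#' @param poolSize theme gene-pool size P (default 150).
#' @param samplingFraction within-theme sampling fraction f in (0, 1]
#'   (default 0.4).
#' @param noiseGenes background genes per set q (default 10).
#' @param poolOverlap number of genes shared between consecutive theme pools
#'   (default 0: clean planted structure).
#' @param themeMeans per-theme gene-statistic means (default equally spaced
#'   from 2 to 4).
#' @param themeSd,backgroundSd gene-statistic standard deviations (defaults
#'   0.5).
#' @param keywords per-theme annotation keywords (default: first K of the
#'   packaged keyword list).
#' @param seed integer seed (default 1).
#' @return a list with \code{collection} (a
#'   \linkS4class{GeneSetCollection}), \code{setStats}, \code{geneStats}
#'   (data.frames as accepted by the pipeline), and \code{truth} (list with
#'   \code{setTheme}, \code{geneTheme}, \code{themeKeyword}).
#' @export
simulateCollection <- function(n = 5000L, K = 5L, setsPerTheme = 20L,
                               poolSize = 150L, samplingFraction = 0.4,
                               noiseGenes = 10L, poolOverlap = 0L,
                               themeMeans = seq(2, 4, length.out = K),
                               themeSd = 0.5, backgroundSd = 0.5,
                               keywords = NULL, seed = 1L) {
  if (samplingFraction <= 0 || samplingFraction > 1)
    stop("samplingFraction must lie in (0, 1]")
  if (poolSize * K > n)
    stop("infeasible: K theme pools of size P exceed the universe")
  if (length(themeMeans) != K) stop("themeMeans must have one value per theme")
  if (is.null(keywords)) {
    kw <- readWordFile("theme_keywords.txt")
    if (K > length(kw))
      stop(sprintf("supply keywords: only %d packaged keywords for K = %d",
                   length(kw), K))
    keywords <- kw[seq_len(K)]
  }
  if (length(keywords) != K || anyDuplicated(keywords))
    stop("keywords must be K distinct words")
  fillers <- readWordFile("filler_words.txt")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  genes <- sprintf("g%05d", seq_len(n))
  poolStart <- (seq_len(K) - 1L) * (poolSize - poolOverlap)
  pools <- lapply(seq_len(K), function(k)
    genes[poolStart[k] + seq_len(poolSize)])
  poolGenes <- unique(unlist(pools))
  background <- setdiff(genes, poolGenes)

  geneTheme <- structure(rep(NA_integer_, n), names = genes)
  for (k in seq_len(K)) {
    idx <- pools[[k]]
    geneTheme[idx][is.na(geneTheme[idx])] <- k   # overlap genes keep first theme
  }

  perSet <- ceiling(samplingFraction * poolSize)
  sets <- list(); setTheme <- integer(0)
  for (k in seq_len(K)) {
    for (s in seq_len(setsPerTheme)) {
      members <- sample(pools[[k]], perSet)
      if (noiseGenes > 0L)
        members <- unique(c(members, sample(background, noiseGenes)))
      nm <- paste(toupper(c(keywords[k],
                            sample(fillers, sample(2:3, 1L)),
                            sprintf("%d", (k - 1L) * setsPerTheme + s))),
                  collapse = "_")
      sets[[nm]] <- members
      setTheme[nm] <- k
    }
  }

  stat <- stats::rnorm(n, mean = 0, sd = backgroundSd)
  inPool <- !is.na(geneTheme)
  stat[inPool] <- stats::rnorm(sum(inPool),
                               mean = themeMeans[geneTheme[inPool]],
                               sd = themeSd)
  names(stat) <- genes
  geneStats <- data.frame(gene = genes, statistic = as.numeric(stat),
                          stringsAsFactors = FALSE)
  setStats <- data.frame(
    set_name = names(sets),
    statistic = vapply(sets, function(m) mean(stat[m]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(setStats) <- NULL

  desc <- sprintf("synthetic gene-set for the %s theme",
                  keywords[setTheme[names(sets)]])
  collection <- geneSetCollection(sets, descriptions = desc, universe = genes)
  list(
    collection = collection,
    setStats = setStats,
    geneStats = geneStats,
    truth = list(setTheme = setTheme,
                 geneTheme = geneTheme[!is.na(geneTheme)],
                 themeKeyword = structure(keywords, names = seq_len(K)))
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a simulated benchmark as standard pipeline inputs
#'
#' Writes the GMT collection, the two statistics TSVs and a truth TSV into a
#' directory, so the files can drive the command-line pipeline.
#'
#' @param sim result of [simulateCollection()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gmt = file.path(dir, "collection.gmt"),
    setStats = file.path(dir, "set_stats.tsv"),
    geneStats = file.path(dir, "gene_stats.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  writeGmt(sim$collection, paths[["gmt"]])
  utils::write.table(sim$setStats, paths[["setStats"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$geneStats, paths[["geneStats"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- data.frame(set_name = names(sim$truth$setTheme),
                      theme = sim$truth$setTheme,
                      keyword = sim$truth$themeKeyword[sim$truth$setTheme],
                      stringsAsFactors = FALSE)
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
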