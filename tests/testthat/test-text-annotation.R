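test_that("tokeniser applies splitting, cleaning, stop/exclusion and number rules", {
  expect_equal(tokenizeText("HALLMARK_EPITHELIAL_MESENCHYMAL_TRANSITION")[[1]],
               c("epithelial", "mesenchymal", "transition"))
  expect_equal(tokenizeText("GO_CELL_CYCLE_PHASE_2")[[1]],
               c("cell", "cycle", "phase"))
  expect_equal(tokenizeText("")[[1]], character(0))

  # the stated split characters all act as separators
  expect_equal(tokenizeText("alpha/beta@gamma(delta)epsilon|zeta_eta")[[1]],
               c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta"))

  # punctuation stripped, stop words and numbers removed, case folded
  expect_equal(tokenizeText("The Wnt, signaling: of 123 CELLS!")[[1]],
               c("wnt", "signaling", "cell"))

  # user exclusions are honoured on top of the defaults
  toks <- tokenizeText("KEGG_COLLAGEN_FIBRIL",
                       exclusions = c(defaultExclusionWords(), "fibril"))[[1]]
  expect_equal(toks, "collagen")
})

test_that("lemmatiser maps plurals by dictionary then rules", {
  expect_equal(lemmatizeWords(c("genes", "matrices", "bodies", "processes",
                                "viruses", "phases", "mice", "analyses",
                                "transition", "glycolysis", "boxes")),
               c("gene", "matrix", "body", "process", "virus", "phase",
                 "mouse", "analysis", "transition", "glycolysis", "box"))
  # -is and -us singulars survive
  expect_equal(lemmatizeWords(c("apoptosis", "locus", "status")),
               c("apoptosis", "locus", "status"))
})

test_that("idf follows log(N / df) with the documented analytic cases", {
  mk <- function(names) {
    sets <- lapply(seq_along(names), function(i) sprintf("g%d", i))
    names(sets) <- names
    geneSetCollection(sets)
  }
  # term in all N sets -> idf 0
  corp <- mk(sprintf("SHARED_WORD%d_%d", 1:100, 1:100))
  idf <- buildCorpusIdf(corp)
  expect_equal(unname(idf@idf["shared"]), 0)

  # N = 100, term in 10 sets -> ln 10
  nm <- sprintf("FILLER%d_%d", 1:100, 1:100)
  nm[1:10] <- sprintf("MARKER_FILLER%d_%d", 1:10, 1:10)
  idf2 <- buildCorpusIdf(mk(nm))
  expect_equal(unname(idf2@idf["marker"]), log(10), tolerance = 1e-12)
  expect_equal(unname(idf2@df["marker"]), 10L)

  # term in 1 of N = 8 sets -> ln 8; base-2 option gives log2
  nm8 <- sprintf("PAD%d_%d", 1:8, 1:8)
  nm8[1] <- "UNIQUE_PAD1_1"
  idf8 <- buildCorpusIdf(mk(nm8))
  expect_equal(unname(idf8@idf["unique"]), log(8), tolerance = 1e-12)
  idf8b <- buildCorpusIdf(mk(nm8), logBase = 2)
  expect_equal(unname(idf8b@idf["unique"]), 3, tolerance = 1e-12)
})

test_that("cluster term scores rank planted keywords first and cap at topN", {
  withr::local_seed(12)
  # corpus of 500 sets; "collagen" appears only in the 10 cluster sets
  filler <- c("LATE", "EARLY", "CORE", "DISTAL", "PROXIMAL")
  nms <- sprintf("%s_PROGRAM_%d", sample(filler, 500, replace = TRUE), 1:500)
  nms[1:10] <- sprintf("COLLAGEN_%s_PROGRAM_%d", sample(filler, 10, TRUE), 1:10)
  sets <- lapply(1:500, function(i) sprintf("g%d", i))
  names(sets) <- nms
  corp <- geneSetCollection(sets)
  idf <- buildCorpusIdf(corp)
  tt <- clusterTermScores(corp, nms[1:10], idf)
  expect_equal(tt$term[1], "collagen")
  expect_equal(tt$tf[1], 10)
  expect_equal(tt$tfidf[1], 10 * log(500 / 10), tolerance = 1e-12)
  expect_lte(nrow(tt), 25L)
  expect_true(all(diff(tt$tfidf) <= 1e-12))

  # every token in every corpus set -> all tf-idf zero, rows still returned
  uni <- geneSetCollection(structure(lapply(1:4, function(i) "g1"),
                                     names = sprintf("WORD_%d", 1:4)))
  idfu <- buildCorpusIdf(uni)
  ttu <- clusterTermScores(uni, names(geneSets(uni))[1:2], idfu)
  expect_equal(ttu$tfidf, rep(0, nrow(ttu)))

  # 3 distinct tokens with topN = 25 -> 3 rows ("up to" semantics)
  tri <- geneSetCollection(list(ALPHA_BRAVO_CHARLIE = "g1",
                                PAD_X = "g2", PAD_Y = "g3"))
  idft <- buildCorpusIdf(tri)
  expect_equal(nrow(clusterTermScores(tri, "ALPHA_BRAVO_CHARLIE", idft)), 3L)
})

test_that("terms missing from the corpus get maximal idf and a flag", {
  corp <- geneSetCollection(list(ALPHA_ONE = "g1", ALPHA_TWO = "g2"))
  idf <- buildCorpusIdf(corp, source = "name")
  clus <- geneSetCollection(list(ALPHA_ONE = "g1"),
                            descriptions = "novelword alpha")
  # score the cluster on descriptions against a name-built corpus
  idfDesc <- new("CorpusIdf", N = idf@N, df = idf@df, idf = idf@idf,
                 logBase = idf@logBase, source = "description")
  expect_warning(tt <- clusterTermScores(clus, "ALPHA_ONE", idfDesc),
                 "absent from the corpus")
  expect_true(tt$novelTerm[tt$term == "novelword"])
  expect_equal(tt$idf[tt$term == "novelword"], log(2), tolerance = 1e-12)
})

test_that("user exclusion words vanish from every output table", {
  sim <- simulateCollection(K = 3L, setsPerTheme = 6L, n = 1200L,
                            poolSize = 80L, seed = 5L)
  gsc <- sim$collection
  excl <- c(defaultExclusionWords(), "binding")
  idf <- buildCorpusIdf(gsc, exclusions = excl)
  sm <- pairwiseSimilarity(gsc, "jaccard")
  part <- detectThemes(pruneIsolated(buildOverlapGraph(sm, 0.2))$graph)
  tts <- themeTermTables(gsc, part, corpusIdf = idf, exclusions = excl)
  expect_false(any(vapply(tts, function(tt) "binding" %in% tt$term,
                          logical(1))))
})

test_that("planted theme keywords surface in the top-5 terms", {
  sim <- simulateCollection(seed = 77L)
  gsc <- sim$collection
  idf <- buildCorpusIdf(gsc)
  sm <- pairwiseSimilarity(gsc, "ari")
  part <- detectThemes(pruneIsolated(buildOverlapGraph(sm, 0.25))$graph)
  tts <- themeTermTables(gsc, part, corpusIdf = idf)
  hits <- vapply(names(tts), function(cid) {
    members <- themeMembers(part, as.integer(cid))
    theme <- sim$truth$setTheme[members[1]]
    kw <- unname(sim$truth$themeKeyword[theme])
    kw %in% head(tts[[cid]]$term, 5L)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
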