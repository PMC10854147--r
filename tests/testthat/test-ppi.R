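edgeDf <- function(a, b, conf, inf = FALSE) {
  data.frame(gene_a = a, gene_b = b, confidence = conf,
             inferred = rep_len(inf, length(a)), stringsAsFactors = FALSE)
}

test_that("TSV ingest applies max-confidence dedup and drops self edges", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tconfidence",
               "A\tB\t0.4", "B\tA\t0.7", "A\tA\t0.9"), f)
  edges <- readPpi(f)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$gene_a, "A"); expect_equal(edges$gene_b, "B")
  expect_equal(edges$confidence, 0.7)

  writeLines("gene_a\tgene_b\tconfidence", f)
  expect_equal(nrow(readPpi(f)), 0L)
})

test_that("PSI-MI TAB subset parses ids, species filter and miscore", {
  f <- withr::local_tempfile(fileext = ".txt")
  mk <- function(a, b, taxa, taxb, sc)
    paste(c(sprintf("uniprotkb:%s", a), sprintf("uniprotkb:%s", b),
            rep("-", 7),
            sprintf("taxid:%d(human)", taxa), sprintf("taxid:%d(x)", taxb),
            rep("-", 3), sprintf("intact-miscore:%s", sc)),
          collapse = "\t")
  writeLines(c(
    mk("P1", "P2", 9606L, 9606L, "0.56"),
    mk("P1", "P2", 9606L, 9606L, "0.90"),   # duplicate, higher confidence
    mk("P3", "P4", 9606L, 10090L, "0.80"),  # cross-species -> dropped
    mk("P5", "P5", 9606L, 9606L, "0.70"),   # self edge -> dropped
    "truncated\tline"
  ), f)
  expect_warning(edges <- readPpi(f, dialect = "psimitab"), "unparsable")
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$confidence, 0.9)
  expect_setequal(c(edges$gene_a, edges$gene_b), c("P1", "P2"))
})

test_that("dedup is idempotent and order-independent on shuffled duplicates", {
  withr::local_seed(4)
  base <- edgeDf(c("A", "B", "A", "C", "B"), c("B", "A", "B", "D", "C"),
                 c(0.2, 0.9, 0.5, 0.3, 0.6))
  d1 <- dedupeEdges(base)
  expect_equal(nrow(d1), 3L)
  expect_equal(d1$confidence[d1$gene_a == "A" & d1$gene_b == "B"], 0.9)

  for (rep in 1:10) {
    shuffled <- base[sample(nrow(base)), ]
    expect_equal(dedupeEdges(shuffled), d1)
  }
  expect_equal(dedupeEdges(d1), d1)   # idempotent
})

test_that("ortholog mapping infers, drops unmappable, and defers to native evidence", {
  map <- data.frame(src = c("Ah", "Bh"), tgt = c("Am", "Bm"))
  edges <- edgeDf("Ah", "Bh", 0.8)
  inf <- mapOrthologs(edges, map)
  expect_equal(nrow(inf), 1L)
  expect_setequal(c(inf$gene_a, inf$gene_b), c("Am", "Bm"))
  expect_equal(inf$confidence, 0.8)
  expect_true(inf$inferred)

  # unmapped endpoint -> no inferred edge
  expect_equal(nrow(mapOrthologs(edgeDf("Ah", "Ch", 0.8), map)), 0L)

  # native 0.9 + inferred duplicate 0.8 -> kept once, 0.9, inferred FALSE
  native <- edgeDf("Am", "Bm", 0.9)
  merged <- mapOrthologs(edges, map, existing = native)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$confidence, 0.9)
  expect_false(merged$inferred)

  # one-to-many maps expand to all target pairs
  map2 <- data.frame(src = c("Ah", "Ah", "Bh"), tgt = c("Am1", "Am2", "Bm"))
  exp2 <- mapOrthologs(edges, map2)
  expect_equal(nrow(exp2), 2L)
})

test_that("induced subnetworks filter by membership, confidence and degree", {
  tri <- edgeDf(c("A", "B", "A"), c("B", "C", "C"), c(0.9, 0.9, 0.2))
  net <- induceSubnetwork(tri, c("A", "B", "C"), minConfidence = 0.5)
  expect_equal(igraph::ecount(net), 2L)
  deg <- structure(igraph::V(net)$degree, names = igraph::V(net)$name)
  expect_equal(deg[c("A", "B", "C")], c(A = 1, B = 2, C = 1))

  # degree filter on a star: single pass drops the leaves, and the centre,
  # isolated by that removal, goes too -> empty network
  star <- edgeDf(rep("HUB", 3), c("L1", "L2", "L3"), rep(0.9, 3))
  empty <- induceSubnetwork(star, c("HUB", "L1", "L2", "L3"), minDegree = 2L)
  expect_equal(igraph::vcount(empty), 0L)

  # genes disjoint from the edge set -> empty network
  none <- induceSubnetwork(tri, c("X", "Y"))
  expect_equal(igraph::vcount(none), 0L)

  # inferred edges can be excluded
  mix <- edgeDf(c("A", "B"), c("B", "C"), c(0.9, 0.8), inf = c(FALSE, TRUE))
  noInf <- induceSubnetwork(mix, c("A", "B", "C"), includeInferred = FALSE)
  expect_equal(igraph::ecount(noInf), 1L)

  # statistics attach to nodes
  gs <- data.frame(gene = c("A", "B", "C"), statistic = c(1, 2, 3))
  withStat <- induceSubnetwork(tri, c("A", "B", "C"), geneStats = gs)
  expect_equal(igraph::V(withStat)$statistic[
    match("B", igraph::V(withStat)$name)], 2)
})

test_that("induced edge sets shrink monotonically in both filters", {
  withr::local_seed(23)
  genes <- sprintf("p%02d", 1:20)
  n <- 60L
  a <- sample(genes, n, TRUE); b <- sample(genes, n, TRUE)
  edges <- edgeDf(a, b, runif(n))
  edges <- edges[edges$gene_a != edges$gene_b, ]

  prevE <- Inf
  for (mc in c(0, 0.3, 0.6, 0.9)) {
    net <- induceSubnetwork(edges, genes, minConfidence = mc)
    expect_lte(igraph::ecount(net), prevE)
    prevE <- igraph::ecount(net)
  }
  prevE <- Inf
  for (md in 0:4) {
    net <- induceSubnetwork(edges, genes, minDegree = md)
    expect_lte(igraph::ecount(net), prevE)
    prevE <- igraph::ecount(net)
  }

  # degree sums to twice the edge count before node filtering
  net0 <- induceSubnetwork(edges, genes)
  expect_equal(sum(igraph::V(net0)$degree), 2 * igraph::ecount(net0))
})
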