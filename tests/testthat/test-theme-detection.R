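namedGraph <- function(g, prefix = "S") {
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(igraph::vcount(g)))
  if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 1
  g
}

test_that("walktrap clustering respects components and the empty graph", {
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  p0 <- detectThemes(empty)
  expect_equal(nThemes(p0), 0L)
  expect_length(themeMembership(p0), 0L)

  # two disjoint triangles: clusters = components
  tri2 <- namedGraph(igraph::disjoint_union(igraph::make_full_graph(3),
                                            igraph::make_full_graph(3)))
  p <- detectThemes(tri2)
  memb <- themeMembership(p)
  expect_equal(nThemes(p), 2L)
  expect_length(unique(memb[1:3]), 1L)
  expect_length(unique(memb[4:6]), 1L)
  expect_false(memb[1] == memb[4])

  # disconnected components never share a cluster, whatever the structure
  withr::local_seed(21)
  for (rep in 1:5) {
    g1 <- igraph::sample_gnp(8, 0.6); g2 <- igraph::sample_gnp(7, 0.6)
    g <- namedGraph(igraph::disjoint_union(g1, g2))
    g <- pruneIsolated(g)$graph
    if (igraph::vcount(g) < 2L) next
    comp <- igraph::components(g)$membership
    memb <- themeMembership(detectThemes(g))
    cross <- outer(memb, memb, "==") & outer(comp, comp, "!=")
    expect_false(any(cross))
  }
})

test_that("two 5-cliques joined by a bridge split at the bridge, as the reference walktrap does", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  g <- namedGraph(g)
  p <- detectThemes(g, steps = 4L)
  memb <- themeMembership(p)
  expect_equal(nThemes(p), 2L)

  adj <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
  ref <- oracleWalktrap(adj, steps = 4L)
  expect_equal(pairAri(memb, ref), 1)
  expect_length(unique(memb[1:5]), 1L)
  expect_length(unique(memb[6:10]), 1L)
})

test_that("walktrap agrees with the reference implementation on weighted graphs", {
  withr::local_seed(31)
  agree <- numeric(0)
  for (rep in 1:8) {
    # planted two-block graph with distinct random weights (no merge ties)
    g <- igraph::sample_sbm(14, pref.matrix = rbind(c(0.9, 0.08), c(0.08, 0.9)),
                            block.sizes = c(7, 7))
    if (igraph::components(g)$no > 1) next
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.5, 1)
    g <- namedGraph(g)
    adj <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
    ref <- oracleWalktrap(adj, steps = 4L)
    memb <- themeMembership(detectThemes(g, steps = 4L))
    agree <- c(agree, pairAri(memb, ref))
  }
  expect_gte(length(agree), 5)
  expect_gte(median(agree), 0.99)
})

test_that("modularity of the cut is at least the singleton partition's", {
  withr::local_seed(17)
  for (rep in 1:5) {
    gsc <- randomCollection(nSets = 15L, universeSize = 60L)
    sm <- pairwiseSimilarity(gsc, "jaccard")
    g <- pruneIsolated(buildOverlapGraph(sm, 0.1))$graph
    if (igraph::vcount(g) < 2L) next
    memb <- themeMembership(detectThemes(g))
    adj <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
    expect_gte(bruteModularity(memb[igraph::V(g)$name], adj),
               bruteModularity(seq_len(nrow(adj)), adj) - 1e-12)
  }
})

test_that("planted themes are recovered on the default synthetic collection", {
  sim <- simulateCollection(seed = 2024L)
  b <- runVisse(sim$collection, sim$setStats, universe = universe(sim$collection),
                verbose = FALSE)
  memb <- themeMembership(b$partition)
  truth <- sim$truth$setTheme[names(memb)]
  expect_gte(pairAri(memb, truth), 0.9)
})

test_that("product-of-ranks ordering reproduces the hand-worked example", {
  # sizes {10, 5, 2}, medians {1, 3, 2}, larger-better:
  # size ranks {1,2,3}, stat ranks {3,1,2}, products {3,2,6} -> c2, c1, c3
  sets <- paste0("S", 1:17)
  memb <- structure(c(rep(1L, 10), rep(2L, 5), rep(3L, 2)), names = sets)
  clusters <- data.frame(
    cluster = 1:3, size = c(10L, 5L, 2L),
    members = vapply(split(sets, memb), paste, character(1), collapse = ";")
  )
  p <- new("ThemePartition", membership = memb, clusters = clusters,
           ordered = FALSE)
  stats <- data.frame(set_name = sets, statistic = c(rep(1, 10), rep(3, 5),
                                                     rep(2, 2)))
  o <- themeTable(orderThemes(p, stats, "larger-better"))
  expect_equal(o$cluster, c(2L, 1L, 3L))
  expect_equal(o$rankProduct, c(2, 3, 6))
  expect_equal(o$order, 1:3)

  # smaller-better reverses the statistic ranks
  o2 <- themeTable(orderThemes(p, stats, "smaller-better"))
  expect_equal(o2$cluster[1], 1L)      # product 1*1

  # single cluster
  p1 <- new("ThemePartition",
            membership = structure(rep(1L, 3), names = paste0("T", 1:3)),
            clusters = data.frame(cluster = 1L, size = 3L,
                                  members = paste(paste0("T", 1:3),
                                                  collapse = ";")),
            ordered = FALSE)
  s1 <- data.frame(set_name = paste0("T", 1:3), statistic = 1:3)
  expect_equal(themeTable(orderThemes(p1, s1))$order, 1L)
})

test_that("rank-product ties break by statistic rank then cluster id", {
  sets <- paste0("S", 1:8)
  memb <- structure(c(rep(1L, 2), rep(2L, 4), rep(3L, 2)), names = sets)
  clusters <- data.frame(
    cluster = 1:3, size = c(2L, 4L, 2L),
    members = vapply(split(sets, memb), paste, character(1), collapse = ";")
  )
  p <- new("ThemePartition", membership = memb, clusters = clusters,
           ordered = FALSE)
  # medians: c1 = 5 (best), c2 = 4, c3 = 3 -> stat ranks 1, 2, 3
  # size ranks: c2 = 1, c1 = c3 = 2.5 -> products: 2.5, 2, 7.5
  stats <- data.frame(set_name = sets,
                      statistic = c(5, 5, 4, 4, 4, 4, 3, 3))
  o <- themeTable(orderThemes(p, stats, "larger-better"))
  expect_equal(o$cluster, c(2L, 1L, 3L))

  # exact product tie -> better statistic rank first
  stats2 <- data.frame(set_name = sets,
                       statistic = c(5, 5, 4, 4, 4, 4, 5, 5))
  # medians c1 = c3 = 5 -> stat ranks 1.5 each; sizes tie at 2.5 ->
  # identical products; statRank ties too -> cluster id breaks the tie
  o2 <- themeTable(orderThemes(p, stats2, "larger-better"))
  expect_lt(which(o2$cluster == 1L), which(o2$cluster == 3L))
})

test_that("ordering is invariant to cluster relabelling", {
  withr::local_seed(55)
  sets <- sprintf("S%02d", 1:20)
  memb <- structure(sample(1:4, 20, replace = TRUE), names = sets)
  memb[1:4] <- 1:4   # ensure all labels present
  stats <- data.frame(set_name = sets, statistic = rnorm(20))
  mk <- function(m) {
    cl <- data.frame(
      cluster = sort(unique(m)),
      size = as.integer(table(m)),
      members = vapply(split(names(m), m), function(x)
        paste(sort(x), collapse = ";"), character(1))
    )
    new("ThemePartition", membership = m, clusters = cl, ordered = FALSE)
  }
  perm <- c(3L, 1L, 4L, 2L)
  memb2 <- structure(perm[memb], names = names(memb))
  o1 <- themeTable(orderThemes(mk(memb), stats))
  o2 <- themeTable(orderThemes(mk(memb2), stats))
  expect_equal(o1$members, o2$members)   # same clusters in the same order
  expect_equal(o1$rankProduct, o2$rankProduct)
})

test_that("every pruned-graph node gets exactly one cluster id", {
  withr::local_seed(61)
  gsc <- randomCollection(nSets = 18L, universeSize = 80L)
  sm <- pairwiseSimilarity(gsc, "jaccard")
  g <- pruneIsolated(buildOverlapGraph(sm, 0.05))$graph
  p <- detectThemes(g)
  memb <- themeMembership(p)
  expect_setequal(names(memb), igraph::V(g)$name)
  expect_false(anyNA(memb))
  expect_equal(sum(themeTable(p)$size), igraph::vcount(g))
})
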