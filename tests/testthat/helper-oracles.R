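# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph, for the walktrap oracle) so that
# implementation and check stay decoupled.

# brute-force pair similarities straight from the raw sets ---------------

bruteJaccard <- function(x, y) {
  u <- length(union(x, y))
  if (u == 0) 0 else length(intersect(x, y)) / u
}

bruteOverlap <- function(x, y) {
  m <- min(length(x), length(y))
  if (m == 0) 0 else length(intersect(x, y)) / m
}

# ARI from the displayed formula, recomputed from scratch (no contingency
# object shared with the implementation)
bruteAri <- function(x, y, universe) {
  n <- length(universe)
  n11 <- length(intersect(x, y))
  n10 <- length(x) - n11
  n01 <- length(y) - n11
  n00 <- n - n11 - n10 - n01
  ch2 <- function(k) k * (k - 1) / 2
  sumnij <- ch2(n00) + ch2(n01) + ch2(n10) + ch2(n11)
  A <- ch2(n00 + n01) + ch2(n10 + n11)
  B <- ch2(n00 + n10) + ch2(n01 + n11)
  E <- A * B / ch2(n)
  den <- (A + B) / 2 - E
  if (den == 0)
    return(if ((n10 == 0 && n01 == 0) || (n11 == 0 && n00 == 0)) 1 else 0)
  (sumnij - E) / den
}

# binary label vectors for the mclust adjusted-Rand cross-check
labelVector <- function(x, universe) as.integer(universe %in% x)

# random gene-set pair generator over a fixed universe -------------------

randomSetPair <- function(universe, maxSize = 200L) {
  s1 <- sample(2:maxSize, 1L)
  s2 <- sample(2:maxSize, 1L)
  x <- sample(universe, s1)
  # force a spread of overlaps, from disjoint to heavily shared
  shared <- sample(0:min(s1, s2), 1L)
  y <- unique(c(sample(x, shared), sample(setdiff(universe, x), s2 - shared)))
  list(x = x, y = y)
}

randomCollection <- function(nSets = 12L, universeSize = 60L,
                             minSize = 2L, maxSize = 20L) {
  universe <- sprintf("u%03d", seq_len(universeSize))
  sets <- lapply(seq_len(nSets), function(i)
    sample(universe, sample(minSize:maxSize, 1L)))
  names(sets) <- sprintf("S%02d", seq_len(nSets))
  geneSetCollection(sets, universe = universe)
}

# weighted Newman modularity, computed directly from the formula ---------

bruteModularity <- function(memb, adj) {
  m2 <- sum(adj)                      # 2m for an undirected weight matrix
  if (m2 == 0) return(0)
  d <- rowSums(adj)
  q <- 0
  for (i in seq_len(nrow(adj))) for (j in seq_len(ncol(adj))) {
    if (memb[i] == memb[j]) q <- q + adj[i, j] - d[i] * d[j] / m2
  }
  q / m2
}

# reference Pons-Latapy walktrap on a weight matrix -----------------------
# Short random walks of length `steps`; agglomerative merging of adjacent
# communities minimising the variance increase; merge tree cut at maximum
# modularity. Written without igraph.

oracleWalktrap <- function(adj, steps = 4L) {
  n <- nrow(adj)
  stopifnot(n >= 1L)
  if (n == 1L) return(1L)
  d <- rowSums(adj)
  stopifnot(all(d > 0))               # prune isolated vertices first
  Pt <- adj / d
  P <- Pt
  if (steps > 1L) for (s in seq_len(steps - 1L)) P <- P %*% Pt

  comm <- as.list(seq_len(n))
  Pc <- P
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  memb <- seq_len(n)
  bestMod <- bruteModularity(memb, adj)
  bestMemb <- memb

  repeat {
    ids <- which(active)
    if (length(ids) < 2L) break
    bestDelta <- Inf; bestPair <- NULL
    for (ai in seq_along(ids)) for (bi in seq_along(ids)) {
      if (bi <= ai) next
      a <- ids[ai]; b <- ids[bi]
      if (sum(adj[comm[[a]], comm[[b]], drop = FALSE]) <= 0) next
      delta <- (sizes[a] * sizes[b] / (sizes[a] + sizes[b])) *
        sum((Pc[a, ] - Pc[b, ])^2 / d) / n
      if (delta < bestDelta - 1e-12) { bestDelta <- delta; bestPair <- c(a, b) }
    }
    if (is.null(bestPair)) break      # remaining communities disconnected
    a <- bestPair[1L]; b <- bestPair[2L]
    Pc[a, ] <- (sizes[a] * Pc[a, ] + sizes[b] * Pc[b, ]) / (sizes[a] + sizes[b])
    comm[[a]] <- c(comm[[a]], comm[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active[b] <- FALSE
    memb[comm[[a]]] <- a
    mod <- bruteModularity(memb, adj)
    if (mod > bestMod + 1e-12) { bestMod <- mod; bestMemb <- memb }
  }
  match(bestMemb, unique(bestMemb))
}

# partition agreement without mclust (used where mclust is the object
# under cross-check elsewhere)
pairAri <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(k) k * (k - 1) / 2
  sumnij <- sum(ch2(tab))
  A <- sum(ch2(rowSums(tab)))
  B <- sum(ch2(colSums(tab)))
  n <- sum(tab)
  E <- A * B / ch2(n)
  den <- (A + B) / 2 - E
  if (den == 0) return(if (sumnij == E) 1 else 0)
  (sumnij - E) / den
}
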