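# Modularity, Louvain, the exhaustive partition oracle and module reports.

test_that("modularity reproduces closed-form values", {
  net <- twoCliquesBridge()
  all1 <- setNames(rep(0L, 6), nodes(net)$code)
  expect_equal(modularityScore(net, all1), 0, tolerance = 1e-12)
  cliques <- setNames(c(0L, 0L, 0L, 1L, 1L, 1L), c("a", "b", "c",
                                                   "d", "e", "f"))
  expect_equal(modularityScore(net, cliques), 5 / 14, tolerance = 1e-12)
  tri <- triangleNetwork()
  singles <- setNames(0:2, nodes(tri)$code)
  expect_equal(modularityScore(tri, singles), -1 / 3, tolerance = 1e-12)
  # invariant under community relabelling
  expect_equal(modularityScore(net, cliques + 7L),
               modularityScore(net, cliques))
  # edgeless network: undefined
  lonely <- toyNetwork(data.frame(from = "a", to = "b"))
  lonely@edges <- lonely@edges[0, ]
  expect_error(modularityScore(lonely, setNames(0:1, c("a", "b"))),
               "edgeless")
})

test_that("modularity agrees with igraph on weighted graphs", {
  set.seed(99)
  for (i in 1:10) {
    net <- erdosRenyi(8, 0.4, seed = i)
    ed <- edges(net)
    ed$weight <- sample(1:5, nrow(ed), replace = TRUE)
    net@edges <- ed
    memb <- setNames(sample(0:2, 8, replace = TRUE), nodes(net)$code)
    g <- asIgraph(net)
    qIg <- igraph::modularity(g, memb[igraph::V(g)$name] + 1,
                              weights = igraph::E(g)$weight)
    expect_equal(modularityScore(net, memb), qIg, tolerance = 1e-12)
  }
})

test_that("louvain recovers the two-clique partition for any seed", {
  net <- twoCliquesBridge()
  for (s in c(1, 7, 42, 1234)) {
    p <- louvain(net, seed = s)
    expect_equal(modularityValue(p), 5 / 14, tolerance = 1e-12)
    expect_equal(nCommunities(p), 2L)
    m <- membershipVector(p)
    expect_equal(length(unique(m[c("a", "b", "c")])), 1L)
    expect_equal(length(unique(m[c("d", "e", "f")])), 1L)
    # stored Q is consistent with modularityScore
    expect_equal(modularityValue(p), modularityScore(net, p),
                 tolerance = 1e-12)
  }
  # the oracle confirms this is the optimum
  bf <- bruteForceBestPartition(net)
  expect_equal(modularityValue(bf), 5 / 14, tolerance = 1e-12)
  expect_equal(nCommunities(bf), 2L)
})

test_that("disjoint cliques each become their own community", {
  net <- disjointCliques(c(3, 4, 2, 3))
  p <- louvain(net, seed = 5)
  expect_equal(nCommunities(p), 4L)
  # community labels constant within cliques
  m <- membershipVector(p)
  sizes <- c(3, 4, 2, 3); off <- 0
  for (s in sizes) {
    ids <- sprintf("n%02d", off + seq_len(s))
    expect_equal(length(unique(m[ids])), 1L)
    off <- off + s
  }
  bf <- bruteForceBestPartition(net)
  expect_equal(modularityValue(p), modularityValue(bf), tolerance = 1e-12)
})

test_that("louvain never beats, and usually matches, the exhaustive oracle", {
  gaps <- numeric(0)
  exact <- 0L
  trials <- cbind(n = rep(c(5, 6, 7, 8), each = 6), seed = 1:24)
  for (i in seq_len(nrow(trials))) {
    net <- erdosRenyi(trials[i, "n"], 0.3, seed = trials[i, "seed"])
    bf <- bruteForceBestPartition(net)
    lv <- louvain(net, seed = trials[i, "seed"] + 100)
    expect_lte(modularityValue(lv), modularityValue(bf) + 1e-9)
    gap <- modularityValue(bf) - modularityValue(lv)
    gaps <- c(gaps, gap)
    if (gap < 1e-9) exact <- exact + 1L
  }
  expect_lte(max(gaps), 0.05)
  expect_gte(exact / nrow(trials), 0.7)   # equality in the large majority
})

test_that("the exhaustive oracle matches a segment-DP check on a path", {
  # path on 5 nodes (4 unit edges): optimal communities of a path are
  # contiguous, so dynamic programming over segmentations is exact
  codes <- letters[1:5]
  net <- toyNetwork(data.frame(from = codes[1:4], to = codes[2:5]))
  m <- 4
  deg <- c(1, 2, 2, 2, 1)
  segQ <- function(i, j) {     # segment [i..j] as one community
    W <- j - i                 # intra edges of a contiguous segment
    d <- sum(deg[i:j])
    W / m - (d / (2 * m))^2
  }
  best <- rep(-Inf, 6)         # best[k]: optimal Q of nodes 1..k-1
  best[1] <- 0
  for (k in 2:6) for (i in 1:(k - 1))
    best[k] <- max(best[k], best[i] + segQ(i, k - 1))
  bf <- bruteForceBestPartition(net)
  expect_equal(modularityValue(bf), best[6], tolerance = 1e-12)
})

test_that("single-edge network collapses to one community", {
  net <- toyNetwork(data.frame(from = "a", to = "b"))
  bf <- bruteForceBestPartition(net)
  expect_equal(nCommunities(bf), 1L)
  expect_equal(modularityValue(bf), 0, tolerance = 1e-12)
  expect_error(bruteForceBestPartition(erdosRenyi(13, 0.3, 1)), "12")
})

test_that("louvain is deterministic given a seed and flags non-convergence", {
  net <- erdosRenyi(9, 0.35, seed = 77)
  p1 <- louvain(net, seed = 3)
  p2 <- louvain(net, seed = 3)
  expect_identical(membershipVector(p1), membershipVector(p2))
  expect_identical(modularityValue(p1), modularityValue(p2))
  expect_true(p1@converged)
  expect_warning(p3 <- louvain(twoCliquesBridge(), seed = 1, maxPasses = 1),
                 "convergence|pass limit")
  expect_false(p3@converged)
})

test_that("louvain modularity dominates trivial partitions", {
  set.seed(2024)
  for (i in 1:5) {
    net <- erdosRenyi(10, 0.3, seed = 300 + i)
    lv <- louvain(net, seed = i)
    singletons <- setNames(seq_len(nNodes(net)) - 1L, nodes(net)$code)
    expect_gte(modularityValue(lv),
               modularityScore(net, singletons) - 1e-12)
    g <- asIgraph(net)
    compQ <- modularityScore(net, setNames(
      igraph::components(g)$membership[nodes(net)$code] - 1L,
      nodes(net)$code))
    if (compQ > 0) expect_gte(modularityValue(lv), 0)
  }
})

test_that("module report orders modules by size and members by prevalence", {
  ed <- data.frame(from = c("a", "a", "b", "d"), to = c("b", "c", "c", "e"))
  net <- toyNetwork(ed)
  nd <- nodes(net)
  nd$prevalence <- c(a = 0.1, b = 0.5, c = 0.3, d = 0.2, e = 0.4)[nd$code]
  net@nodes <- nd
  part <- new("CommunityPartition",
              membership = setNames(c(0L, 0L, 0L, 1L, 1L), letters[1:5]),
              modularity = modularityScore(net, setNames(
                c(0L, 0L, 0L, 1L, 1L), letters[1:5])),
              gamma = 1, seed = 1L, converged = TRUE)
  rep_ <- moduleReport(net, part)
  expect_equal(rep_$size, c(3L, 2L))
  expect_equal(rep_$members[[1]], c("b", "c", "a"))   # prevalence order
  expect_equal(rep_$members[[2]], c("e", "d"))
})

test_that("planted modules are recovered and reported at their sizes", {
  gen <- generateCohort(recoveryConfig(), seed = 41)
  prev <- prevalenceTable(gen$cohort)
  net <- buildNetwork(relativeRisk(pairCounts(gen$cohort), prev), prev)
  p <- louvain(net, seed = 41)
  rep_ <- moduleReport(net, p)
  expect_equal(sort(rep_$size), c(5L, 5L, 5L))
  expect_equal(adjustedRandIndex(membershipVector(p),
                                 gen$moduleOf[names(membershipVector(p))]),
               1)
  # membership is invariant to node input order
  ord <- rev(seq_len(nNodes(net)))
  net2 <- ComorbidNet:::.makeNetwork(nodes(net)[ord, ], edges(net))
  p2 <- louvain(net2, seed = 41)
  expect_equal(adjustedRandIndex(membershipVector(p),
                                 membershipVector(p2)[names(
                                   membershipVector(p))]), 1)
})

test_that("louvain Q is in the same range as igraph's implementation", {
  gen <- generateCohort(defaultSyntheticConfig(2000L), seed = 55)
  prev <- prevalenceTable(gen$cohort)
  net <- buildNetwork(relativeRisk(pairCounts(gen$cohort), prev), prev)
  p <- louvain(net, seed = 55)
  g <- asIgraph(net)
  set.seed(55)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  qIg <- igraph::modularity(g, igraph::membership(cl),
                            weights = igraph::E(g)$weight)
  expect_gte(modularityValue(p), qIg - 0.03)
})
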