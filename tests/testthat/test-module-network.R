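test_that("cross-edge counts match closed forms and brute force", {
  g <- igraph::make_full_bipartite_graph(3, 4)
  igraph::V(g)$name <- letters[1:7]
  expect_equal(crossEdgeCount(g, letters[1:3], letters[4:7]), 12L)

  # no edges between two sets drawn inside the same side
  g2 <- namedGraph(igraph::make_full_graph(4))
  g2 <- igraph::add_vertices(g2, 4)
  igraph::V(g2)$name[5:8] <- letters[1:4]
  expect_equal(crossEdgeCount(g2, c("a", "b"), c("c", "d")), 0L)

  expect_error(crossEdgeCount(g, c("a", "b"), c("b", "d")), "overlap")

  # brute-force oracle over random graphs
  for (seed in 1:5) {
    g3 <- randomGraph(20, 0.3, seed)
    a <- igraph::V(g3)$name[1:5]
    b <- igraph::V(g3)$name[6:10]
    expect_equal(crossEdgeCount(g3, a, b), bruteCrossCount(g3, a, b))
  }
})

test_that("crosstalk p-values detect planted cross-talk and respect bounds", {
  set.seed(50)
  g <- igraph::sample_gnp(200, 0.01)
  a <- 1:6
  b <- 7:12
  # plant 20 cross edges between the two 6-gene sets
  pairs <- expand.grid(a, b)
  sel <- pairs[sample(nrow(pairs), 20), ]
  for (i in seq_len(nrow(sel))) {
    if (!igraph::are_adjacent(g, sel[i, 1], sel[i, 2])) {
      g <- igraph::add_edges(g, as.numeric(sel[i, ]))
    }
  }
  g <- namedGraph(igraph::simplify(g), "n")
  aN <- sprintf("n%02d", a)
  bN <- sprintf("n%02d", b)
  p <- crosstalkPvalue(g, aN, bN, nPerm = 999, seed = 1)
  expect_equal(as.numeric(p), 1 / 1000) # no permutation reaches the planted count

  # observed 0 gives p = 1, and the add-one estimator never returns 0
  g0 <- namedGraph(igraph::disjoint_union(
    igraph::make_full_graph(5), igraph::make_full_graph(5)
  ))
  expect_equal(
    as.numeric(crosstalkPvalue(g0, sprintf("v%02d", 1:5), sprintf("v%02d", 6:10),
                               nPerm = 99, seed = 2)),
    1
  )
  expect_error(crosstalkPvalue(g0, "v01", "v02", nPerm = 0), "nPerm")
})

test_that("adding cross edges never increases the p-value at fixed seed", {
  set.seed(51)
  base <- randomGraph(60, 0.05, 51)
  a <- igraph::V(base)$name[1:6]
  b <- igraph::V(base)$name[7:12]
  pPrev <- Inf
  g <- base
  for (extra in c(0, 4, 8)) {
    gx <- base
    added <- 0L
    for (x in a) {
      for (y in b) {
        if (added < extra && !igraph::are_adjacent(gx, x, y)) {
          gx <- igraph::add_edges(gx, c(x, y))
          added <- added + 1L
        }
      }
    }
    p <- crosstalkPvalue(gx, a, b, nPerm = 199, seed = 99)
    expect_lte(p, pPrev)
    pPrev <- p
  }
})

test_that("module networks keep only pairs below alpha and stay reproducible", {
  set.seed(52)
  g <- igraph::sample_gnp(80, 0.02)
  mods <- list(m1 = 1:6, m2 = 7:12, m3 = 13:18)
  # only the (m1, m2) pair is densely connected
  for (i in mods$m1) {
    for (j in mods$m2) {
      if (runif(1) < 0.6 && !igraph::are_adjacent(g, i, j)) {
        g <- igraph::add_edges(g, c(i, j))
      }
    }
  }
  g <- namedGraph(igraph::simplify(g), "n")
  geneMods <- lapply(mods, function(ix) sprintf("n%02d", ix))
  asModules <- mapply(function(genes, id) {
    new("GeneModule", id = id, genes = genes, seed = genes[1],
        score = 1, coreK = 1L)
  }, geneMods, c("m1", "m2", "m3"))
  net <- suppressMessages(
    buildModuleNetwork(g, asModules, nPerm = 499, alpha = 0.05, seed = 7)
  )
  expect_setequal(net@nodes, c("m1", "m2", "m3"))
  expect_equal(nrow(net@edges), 1L)
  expect_setequal(unlist(net@edges[1, c("moduleA", "moduleB")]), c("m1", "m2"))
  expect_true(all(net@edges$pValue < 0.05))
  expect_equal(nrow(net@allPairs), 3L)

  net2 <- suppressMessages(
    buildModuleNetwork(g, asModules, nPerm = 499, alpha = 0.05, seed = 7)
  )
  expect_identical(net@allPairs, net2@allPairs)

  # alpha = 1 keeps pairs with p < 1 but excludes p exactly 1
  netAll <- suppressMessages(
    buildModuleNetwork(g, asModules, nPerm = 499, alpha = 1, seed = 7)
  )
  expect_true(all(netAll@edges$pValue < 1))
  expect_equal(nrow(netAll@edges), sum(netAll@allPairs$pValue < 1))
})

test_that("module networks with no cross edges anywhere are edgeless", {
  g <- namedGraph(igraph::disjoint_union(
    igraph::make_full_graph(5), igraph::make_full_graph(5),
    igraph::make_full_graph(5)
  ))
  mods <- lapply(1:3, function(i) {
    genes <- sprintf("v%02d", (i - 1) * 5 + 1:5)
    new("GeneModule", id = paste0("m", i), genes = genes, seed = genes[1],
        score = 1, coreK = 1L)
  })
  net <- suppressMessages(buildModuleNetwork(g, mods, nPerm = 99, seed = 3))
  expect_equal(nrow(net@edges), 0L)
  expect_length(net@nodes, 3L)
})
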