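test_that("every qualifying gene contributes exactly k selection edges", {
  set.seed(30)
  m <- matrix(rnorm(10 * 20), 10, 20,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:20)))
  net <- suppressMessages(buildComethylationNetwork(m, k = 4))
  expect_equal(selectionEdgeCount(net), 40L)
  outDeg <- table(selectionEdges(net)$gene)
  expect_true(all(outDeg == 4L))
  expect_lte(igraph::ecount(simpleGraph(net)), 40L)
  expect_false(igraph::any_loop(simpleGraph(net)))

  # property: k * n holds across sizes
  for (n in c(7, 23)) {
    mm <- matrix(rnorm(n * 15), n, 15,
                 dimnames = list(sprintf("x%02d", 1:n), sprintf("s%d", 1:15)))
    nn <- suppressMessages(buildComethylationNetwork(mm, k = 4))
    expect_equal(selectionEdgeCount(nn), 4L * n)
  }
})

test_that("planted correlation blocks keep all selection edges within-block", {
  set.seed(31)
  n <- 100
  blocks <- lapply(1:3, function(b) {
    f <- rnorm(n)
    t(sapply(1:6, function(i) 0.9 * f + rnorm(n, sd = 0.3)))
  })
  v <- do.call(rbind, blocks)
  dimnames(v) <- list(sprintf("g%02d", 1:18), sprintf("s%03d", 1:n))
  net <- suppressMessages(buildComethylationNetwork(v, k = 4))
  sel <- selectionEdges(net)
  blockOf <- rep(1:3, each = 6)
  names(blockOf) <- rownames(v)
  expect_true(all(blockOf[sel$gene] == blockOf[sel$neighbor]))
})

test_that("perfectly correlated genes select each other first", {
  set.seed(32)
  n <- 50
  x <- rnorm(n)
  v <- rbind(twin1 = x, twin2 = x, matrix(rnorm(8 * n), 8, n))
  rownames(v)[3:10] <- sprintf("noise%d", 1:8)
  colnames(v) <- sprintf("s%02d", 1:n)
  net <- suppressMessages(buildComethylationNetwork(v, k = 4))
  sel <- selectionEdges(net)
  expect_equal(sel$neighbor[sel$gene == "twin1"][1], "twin2")
  expect_equal(sel$neighbor[sel$gene == "twin2"][1], "twin1")
})

test_that("constant genes are dropped and tiny gene sets link to all others", {
  set.seed(33)
  v <- rbind(matrix(rnorm(3 * 10), 3, 10), flat = rep(2, 10))
  dimnames(v) <- list(c("a", "b", "c", "flat"), sprintf("s%d", 1:10))
  expect_warning(
    net <- suppressMessages(buildComethylationNetwork(v, k = 4)),
    "constant"
  )
  expect_equal(nodeCount(net), 3L)
  # 3 genes, k capped at 2 partners each
  expect_equal(selectionEdgeCount(net), 6L)
})

test_that("network construction is invariant to gene relabeling and affine maps", {
  set.seed(34)
  v <- matrix(rnorm(12 * 25), 12, 25,
              dimnames = list(sprintf("g%02d", 1:12), sprintf("s%d", 1:25)))
  net1 <- suppressMessages(buildComethylationNetwork(v, k = 3))
  # affine transform of every gene leaves Pearson correlations unchanged
  v2 <- v * 3.7 - 11
  net2 <- suppressMessages(buildComethylationNetwork(v2, k = 3))
  expect_identical(selectionEdges(net1)[, 1:2], selectionEdges(net2)[, 1:2])

  # relabeling genes yields the same network up to the renaming
  perm <- sample(nrow(v))
  v3 <- v[perm, ]
  rename <- setNames(sprintf("h%02d", seq_len(nrow(v))), rownames(v)[perm])
  rownames(v3) <- rename
  net3 <- suppressMessages(buildComethylationNetwork(v3, k = 3))
  e1 <- sort(apply(igraph::as_edgelist(simpleGraph(net1)), 1,
                   function(e) paste(sort(rename[e]), collapse = "-")))
  e3 <- sort(apply(igraph::as_edgelist(simpleGraph(net3)), 1,
                   function(e) paste(sort(e), collapse = "-")))
  expect_identical(e1, e3)
})

test_that("log-log degree fit reproduces closed-form least squares", {
  # build a graph whose degree histogram is exactly {1: 100, 2: 25, 4: 6}:
  # 6 four-leaf stars (6 hubs of degree 4, 24 leaves), 25 three-node paths
  # (25 centres of degree 2, 50 ends), 13 single edges (26 more degree-1)
  g <- igraph::disjoint_union(c(
    lapply(1:6, function(i) igraph::make_star(5, mode = "undirected")),
    lapply(1:25, function(i) igraph::make_ring(3, circular = FALSE)),
    lapply(1:13, function(i) igraph::make_full_graph(2))
  ))
  g <- namedGraph(g)
  expect_equal(unname(table(igraph::degree(g))), c(100L, 25L, 6L),
               ignore_attr = TRUE)
  fit <- degreePowerlawFit(g)
  # closed-form least squares on the three (log10 d, log10 freq) points
  x <- log10(c(1, 2, 4))
  y <- log10(c(100, 25, 6))
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit@exponent, slope, tolerance = 1e-12)
  expect_equal(fit@exponent, -2.03, tolerance = 1e-3)
  expect_equal(fit@correlation, cor(x, y), tolerance = 1e-12)
  expect_equal(fit@rSquare, fit@correlation^2)
  expect_gt(fit@rSquare, 0.999)
})

test_that("degenerate degree distributions are refused", {
  ring <- namedGraph(igraph::make_ring(10))
  expect_error(degreePowerlawFit(ring), "distinct")
  expect_error(degreePowerlawFit(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})
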