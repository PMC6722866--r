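moduleGeneSets <- function(mods) {
  if (is.list(mods) && length(mods) && is(mods[[1L]], "GeneModule")) {
    stats::setNames(lapply(mods, moduleGenes),
                    vapply(mods, function(m) m@id, character(1L)))
  } else if (is.list(mods)) {
    mods
  } else {
    stop("modules must be a list of GeneModule objects or of gene-id vectors")
  }
}

# integer endpoint representation of a graph, for fast repeated cross counts
edgeEndpoints <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  list(
    a = el[, 1L], b = el[, 2L],
    names = igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))),
    n = igraph::vcount(g)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

countCross <- function(ep, idxA, idxB) {
  memb <- integer(ep$n)
  memb[idxA] <- 1L
  memb[idxB] <- 2L
  sum(memb[ep$a] * memb[ep$b] == 2L)
}

#' Count edges between two gene sets
#'
#' Number of edges of the gene-level graph with one endpoint in each of two
#' disjoint gene sets.
#'
#' @param g simple undirected \pkg{igraph} graph.
#' @param a,b disjoint character vectors of gene ids (vertices of \code{g}).
#' @return Integer edge count.
#' @examples
#' g <- igraph::make_full_bipartite_graph(3, 4)
#' igraph::V(g)$name <- letters[1:7]
#' crossEdgeCount(g, letters[1:3], letters[4:7]) # 12
#' @export
crossEdgeCount <- function(g, a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(intersect(a, b))) {
    stop("gene sets overlap: ", fewIds(intersect(a, b)))
  }
  ep <- edgeEndpoints(g)
  ia <- match(a, ep$names)
  ib <- match(b, ep$names)
  if (anyNA(ia) || anyNA(ib)) {
    stop("gene(s) absent from the graph: ",
         fewIds(c(a[is.na(ia)], b[is.na(ib)])))
  }
  countCross(ep, ia, ib)
}

#' Permutation p-value for module cross-talk
#'
#' Tests whether two gene modules are joined by more edges than expected by
#' chance: the observed cross-edge count is compared with the counts
#' between \code{nPerm} pairs of random disjoint gene sets of the same
#' sizes drawn uniformly from the graph's vertices.  The p-value uses the
#' add-one estimator (r + 1) / (nPerm + 1), which is never exactly zero.
#'
#' @param g simple undirected \pkg{igraph} graph.
#' @param a,b disjoint gene sets (vertices of \code{g}).
#' @param nPerm number of permutations (default 1000).
#' @param seed optional integer seed for the permutation stream.
#' @return The permutation p-value, in (0, 1].  The observed count and the
#'   null tallies (\code{permGreater}, \code{permEqual}, \code{nPerm}) are
#'   attached as attributes so that the discreteness of the null can be
#'   accounted for (e.g. when checking calibration).
#' @export
crosstalkPvalue <- function(g, a, b, nPerm = 1000L, seed = NULL) {
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) + length(b) > igraph::vcount(g)) {
    stop("set sizes exceed the number of graph nodes")
  }
  observed <- crossEdgeCount(g, a, b)
  ep <- edgeEndpoints(g)
  na <- length(a)
  nb <- length(b)
  counts <- localSeed(seed, {
    greater <- 0L
    equal <- 0L
    for (i in seq_len(nPerm)) {
      draw <- sample.int(ep$n, na + nb)
      cnt <- countCross(ep, draw[seq_len(na)], draw[(na + 1L):(na + nb)])
      if (cnt > observed) greater <- greater + 1L
      if (cnt == observed) equal <- equal + 1L
    }
    c(greater, equal)
  })
  p <- (counts[1L] + counts[2L] + 1) / (nPerm + 1)
  attr(p, "observed") <- observed
  attr(p, "permGreater") <- counts[1L]
  attr(p, "permEqual") <- counts[2L]
  attr(p, "nPerm") <- nPerm
  p
}

#' Build the module cross-talk network
#'
#' Runs the permutation cross-talk test on every unordered pair of modules
#' and keeps the pairs with p below \code{alpha} as module-network edges.
#' All modules appear as nodes, including isolated ones.  Permutations for
#' each pair are drawn from a substream derived from \code{seed} and the
#' pair's ids, so the result does not depend on the order in which pairs
#' are tested.
#'
#' @param g simple undirected gene-level \pkg{igraph} graph.
#' @param mods list of [GeneModule-class] objects (>= 2).
#' @param nPerm permutations per pair.
#' @param alpha significance level (edges require p < alpha).
#' @param seed optional integer seed.
#' @return A [ModuleNetwork-class].
#' @export
buildModuleNetwork <- function(g, mods, nPerm = 1000L, alpha = 0.05,
                               seed = NULL) {
  sets <- moduleGeneSets(mods)
  if (length(sets) < 2L) stop("need at least 2 modules")
  ids <- names(sets)
  pairs <- utils::combn(length(sets), 2L)
  res <- data.frame(
    moduleA = ids[pairs[1L, ]], moduleB = ids[pairs[2L, ]],
    crossEdges = NA_integer_, pValue = NA_real_, stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]
    i2 <- pairs[2L, j]
    pairSeed <- if (is.null(seed)) NULL else {
      deriveSeed(seed, paste("modnet", ids[i1], ids[i2]))
    }
    res$crossEdges[j] <- crossEdgeCount(g, sets[[i1]], sets[[i2]])
    res$pValue[j] <- crosstalkPvalue(g, sets[[i1]], sets[[i2]],
      nPerm = nPerm, seed = pairSeed
    )
  }
  keep <- res[res$pValue < alpha, , drop = FALSE]
  rownames(keep) <- NULL
  stageLog("modnet", sprintf(
    "%d module pair(s) tested, %d significant at alpha = %g",
    nrow(res), nrow(keep), alpha
  ))
  new("ModuleNetwork",
    nodes = ids, edges = keep, allPairs = res, alpha = alpha
  )
}

moduleNetworkGraph <- function(net) {
  stopifnot(is(net, "ModuleNetwork"))
  igraph::graph_from_data_frame(
    net@edges[, c("moduleA", "moduleB")],
    directed = FALSE, vertices = data.frame(name = net@nodes)
  )
}
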