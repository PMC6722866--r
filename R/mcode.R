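graphDensity <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weighting
#'
#' Scores the local neighbourhood density of every vertex: for a vertex v,
#' take the subgraph induced by v and its neighbours, find its highest
#' k-core (k >= 2), and set weight(v) = k times the density of that core.
#' Vertices whose neighbourhood has no 2-core (isolated and pendant
#' vertices, sparse stars) get weight 0, as do vertices below the degree
#' cutoff.
#'
#' @param g simple undirected \pkg{igraph} graph without self-loops.
#' @param degreeCutoff vertices with fewer neighbours than this are given
#'   weight 0 (MCODE's degree cutoff, default 2).
#' @return Named numeric vector of vertex weights.
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- letters[1:5]
#' vertexWeighting(g) # each vertex: core k = 4, density 1 -> weight 4
#' @export
vertexWeighting <- function(g, degreeCutoff = 2L) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    stop("graph must be simple (no loops or multi-edges)")
  }
  nms <- igraph::V(g)$name
  if (is.null(nms)) {
    nms <- as.character(seq_len(igraph::vcount(g)))
    igraph::V(g)$name <- nms
  }
  deg <- igraph::degree(g)
  w <- stats::setNames(numeric(igraph::vcount(g)), nms)
  for (v in which(deg >= max(degreeCutoff, 1L))) {
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    cn <- igraph::coreness(sub)
    kmax <- max(cn)
    if (kmax < 2L) next
    core <- igraph::induced_subgraph(sub, which(cn == kmax))
    w[v] <- kmax * graphDensity(core)
  }
  w
}

# iterative removal of vertices with degree < 2 (the 2-core)
haircutModule <- function(g, members) {
  sub <- igraph::induced_subgraph(g, members)
  cn <- igraph::coreness(sub)
  igraph::V(sub)$name[cn >= 2L]
}

#' Detect dense gene modules (MCODE)
#'
#' Reimplementation of the MCODE molecular-complex-detection algorithm:
#' vertices are weighted by the density of the highest k-core of their
#' neighbourhood ([vertexWeighting()]); complexes are then grown greedily,
#' seeding on the highest-weight unused vertex and including, breadth
#' first, every neighbouring vertex whose weight is at least
#' \code{seedWeight * (1 - nodeScoreCutoff)}.  Each vertex belongs to at
#' most one complex.  With \code{haircut} the finished complex is reduced
#' to its 2-core (singly-connected vertices removed); with \code{fluff}
#' unused neighbours whose own neighbourhood density exceeds
#' \code{fluffThreshold} are added back afterwards.  Complexes smaller than
#' \code{sizeFloor} genes are discarded.  The module score is the density
#' of the module subgraph times its size.
#'
#' Equal weights are resolved by gene id order, so the output is
#' deterministic.  Members of a complex that ends up below the size floor
#' (and vertices trimmed by the haircut) are released again: they may be
#' absorbed into complexes grown later, but do not seed new complexes;
#' the seed vertex of every grown complex stays consumed.  This keeps
#' returned modules vertex-disjoint while preventing locally dense
#' accidents (e.g. a background vertex attached to several neighbouring
#' module genes) from eating parts of a real module through a complex that
#' is discarded anyway.
#'
#' @param g simple undirected \pkg{igraph} graph.
#' @param nodeScoreCutoff fraction by which a member's weight may fall
#'   below the seed's (default 0.2).
#' @param degreeCutoff minimum degree for a vertex to be weighted.
#' @param haircut remove singly-connected vertices from finished modules.
#' @param fluff add dense unused neighbours to finished modules.
#' @param fluffThreshold neighbourhood-density threshold used by fluff.
#' @param sizeFloor minimum retained module size (default 5).
#' @return List of [GeneModule-class] objects in decreasing score order,
#'   vertex-disjoint, each inducing a connected subgraph.
#' @export
findModules <- function(g, nodeScoreCutoff = 0.2, degreeCutoff = 2L,
                        haircut = TRUE, fluff = FALSE, fluffThreshold = 0.2,
                        sizeFloor = 5L) {
  stopifnot(igraph::is_igraph(g))
  if (nodeScoreCutoff < 0 || nodeScoreCutoff >= 1) {
    stop("nodeScoreCutoff must lie in [0, 1)")
  }
  if (igraph::vcount(g) == 0L) return(list())
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  nms <- igraph::V(g)$name
  w <- vertexWeighting(g, degreeCutoff = degreeCutoff)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))

  seedOrder <- order(-w, nms)
  used <- rep(FALSE, length(nms))
  eligible <- rep(TRUE, length(nms))
  mods <- list()
  for (s in seedOrder) {
    if (used[s] || !eligible[s]) next
    threshold <- w[s] * (1 - nodeScoreCutoff)
    members <- s
    used[s] <- TRUE
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- as.integer(adj[[v]])
      nb <- nb[!used[nb] & w[nb] >= threshold]
      if (length(nb)) {
        nb <- nb[order(nms[nb])]
        used[nb] <- TRUE
        members <- c(members, nb)
        queue <- c(queue, nb)
      }
    }
    grown <- members
    kept <- nms[members]
    if (haircut && length(kept) > 1L) {
      kept <- haircutModule(g, kept)
    }
    if (fluff && length(kept)) {
      extra <- integer()
      for (v in match(kept, nms)) {
        nb <- as.integer(adj[[v]])
        nb <- nb[!used[nb]]
        for (u in nb) {
          nbu <- c(u, as.integer(adj[[u]]))
          dens <- graphDensity(igraph::induced_subgraph(g, nbu))
          if (dens > fluffThreshold) extra <- c(extra, u)
        }
      }
      extra <- unique(extra)
      used[extra] <- TRUE
      grown <- c(grown, extra)
      kept <- union(kept, nms[extra])
    }
    if (length(kept) >= sizeFloor) {
      sub <- igraph::induced_subgraph(g, kept)
      # the haircut can in principle disconnect a grown complex; keep the
      # component holding the seed (the largest one if the seed was trimmed)
      comp <- igraph::components(sub)
      if (comp$no > 1L) {
        seedName <- nms[s]
        keepComp <- if (seedName %in% igraph::V(sub)$name) {
          comp$membership[seedName]
        } else {
          which.max(comp$csize)
        }
        kept <- igraph::V(sub)$name[comp$membership == keepComp]
        sub <- igraph::induced_subgraph(g, kept)
      }
    }
    if (length(kept) >= sizeFloor) {
      mods[[length(mods) + 1L]] <- list(
        seed = nms[s],
        genes = sort(kept),
        score = graphDensity(sub) * length(kept),
        coreK = max(igraph::coreness(sub))
      )
      released <- setdiff(grown, c(match(kept, nms), s))
    } else {
      released <- setdiff(grown, s)
    }
    if (length(released)) {
      used[released] <- FALSE
      eligible[released] <- FALSE
    }
  }
  if (!length(mods)) return(list())
  ord <- order(-vapply(mods, `[[`, numeric(1L), "score"),
               vapply(mods, function(m) m$genes[1L], character(1L)))
  mods <- mods[ord]
  out <- vector("list", length(mods))
  for (i in seq_along(mods)) {
    out[[i]] <- new("GeneModule",
      id = paste0("M", i), genes = mods[[i]]$genes, seed = mods[[i]]$seed,
      score = mods[[i]]$score, coreK = as.integer(mods[[i]]$coreK)
    )
  }
  stageLog("modules", sprintf(
    "%d module(s) of >= %d genes (top score %.3f)",
    length(out), sizeFloor, out[[1L]]@score
  ))
  out
}
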