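# Independent oracles, deliberately naive implementations used only to
# cross-check the package's code paths.

# brute-force mean silhouette: plain double loop over points
bruteSilhouette <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (!length(mates)) {
      s[i] <- 0
      next
    }
    a <- mean(vapply(mates, function(j) d(i, j), 0))
    b <- Inf
    for (cl in setdiff(unique(labels), own)) {
      members <- which(labels == cl)
      b <- min(b, mean(vapply(members, function(j) d(i, j), 0)))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# brute-force k-shell: a node's shell is the largest s such that the s-core
# (computed by repeated pruning from scratch) still contains it
bruteShells <- function(g) {
  nms <- igraph::V(g)$name
  sCore <- function(s) {
    keep <- nms
    repeat {
      sub <- igraph::induced_subgraph(g, keep)
      deg <- igraph::degree(sub)
      drop <- igraph::V(sub)$name[deg < s]
      if (!length(drop)) return(igraph::V(sub)$name)
      keep <- setdiff(keep, drop)
      if (!length(keep)) return(character())
    }
  }
  shell <- stats::setNames(integer(length(nms)), nms)
  s <- 1L
  repeat {
    core <- sCore(s)
    if (!length(core)) break
    shell[core] <- s
    s <- s + 1L
  }
  shell
}

# exhaustive hypergeometric upper tail: enumerate all draws of |B| items
# from the universe and count draws overlapping A at least as much
bruteOverlapP <- function(sizeA, sizeB, universe, observed) {
  items <- seq_len(universe)
  inA <- items <= sizeA
  draws <- utils::combn(universe, sizeB)
  hits <- apply(draws, 2L, function(dr) sum(inA[dr]) >= observed)
  mean(hits)
}

# brute-force cross-edge count over all vertex pairs
bruteCrossCount <- function(g, a, b) {
  cnt <- 0L
  for (x in a) {
    for (y in b) {
      if (igraph::are_adjacent(g, x, y)) cnt <- cnt + 1L
    }
  }
  cnt
}

randomGraph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

namedGraph <- function(g, prefix = "v") {
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(igraph::vcount(g)))
  g
}

# tiny clinical table generator: exponential survival driven by a linear
# predictor, uniform censoring
makeClinical <- function(lp, baseline = 0.01, censorAt = Inf, seed = 1) {
  set.seed(seed)
  n <- length(lp)
  ev <- stats::rexp(n, baseline * exp(lp))
  cn <- if (is.finite(censorAt)) stats::runif(n, 0, censorAt) else rep(Inf, n)
  data.frame(
    sample = sprintf("S%03d", seq_len(n)),
    time = pmin(ev, cn),
    status = as.integer(ev <= cn)
  )
}
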