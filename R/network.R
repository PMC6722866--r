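#' Build a rank-based co-methylation network
#'
#' Computes the Pearson correlation of methylation levels between every two
#' genes and links each gene to its \code{k} most correlated partners
#' ("top-k nearest neighbours"), instead of applying one global correlation
#' threshold.  Each qualifying gene contributes exactly \code{k} selection
#' edges, so a network over n genes reports k*n selection edges; downstream
#' algorithms use the deduplicated simple undirected view.
#'
#' Ranking uses the absolute correlation by default (co-methylation in
#' either direction); ties are broken by gene id so the construction is
#' deterministic.  Constant genes cannot be correlated and are dropped with
#' a warning; a gene with fewer than \code{k} co-measured partners links to
#' all of them.
#'
#' @param m gene-by-sample M-value [MethylationMatrix-class] or numeric
#'   matrix (>= 3 samples).
#' @param k neighbor count (default 4).
#' @param ranking \code{"absolute"} ranks by |r|, \code{"signed"} by r.
#' @return A [CoMethylationNetwork-class].
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(200), 10, 20,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
#' net <- buildComethylationNetwork(m, k = 4)
#' selectionEdgeCount(net) # 40 = 4 * 10
#' @export
buildComethylationNetwork <- function(m, k = 4L, ranking = c("absolute", "signed")) {
  ranking <- match.arg(ranking)
  v <- asValueMatrix(m)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (ncol(v) < 3L) stop("need at least 3 samples to correlate genes")
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant gene(s): ", fewIds(rownames(v)[sds == 0]))
    v <- v[sds > 0, , drop = FALSE]
  }
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 non-constant genes")
  if (n < k + 1L) {
    stageLog("network", sprintf(
      "only %d genes for k = %d: genes link to all others", n, k
    ))
  }
  genes <- rownames(v)
  ord <- order(genes)

  r <- stats::cor(t(v))
  kEff <- min(k, n - 1L)
  from <- rep.int(genes, kEff)
  to <- character(n * kEff)
  w <- numeric(n * kEff)
  for (i in seq_len(n)) {
    s <- if (ranking == "absolute") abs(r[i, ]) else r[i, ]
    s[i] <- -Inf
    top <- order(s, decreasing = TRUE)[seq_len(kEff)]
    # deterministic tie handling at the boundary: among scores equal to the
    # k-th best, prefer lexicographically smaller gene ids
    kth <- s[top[kEff]]
    tied <- which(s == kth)
    if (length(tied) > 1L) {
      above <- top[s[top] > kth]
      need <- kEff - length(above)
      top <- c(above, tied[order(genes[tied])][seq_len(need)])
    }
    sel <- (i - 1L) * kEff + seq_len(kEff)
    from[sel] <- genes[i]
    to[sel] <- genes[top]
    w[sel] <- r[cbind(i, top)]
  }
  selection <- data.frame(gene = from, neighbor = to, r = w,
                          stringsAsFactors = FALSE)

  a <- pmin(selection$gene, selection$neighbor)
  b <- pmax(selection$gene, selection$neighbor)
  key <- paste(a, b, sep = "\r")
  first <- !duplicated(key)
  edges <- data.frame(from = a[first], to = b[first], weight = selection$r[first],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges,
    directed = FALSE, vertices = data.frame(name = genes)
  )
  stageLog("network", sprintf(
    "%d genes, %d selection edges, %d simple edges",
    n, nrow(selection), igraph::ecount(g)
  ))
  new("CoMethylationNetwork", selection = selection, graph = g, k = k)
}

#' Power-law fit of the degree distribution
#'
#' Tabulates the frequency of each degree value in the simple undirected
#' view of the network and fits a least-squares line to (log10 degree,
#' log10 frequency) over degrees with nonzero frequency.  A heavy-tailed
#' (scale-free-like) network shows a strong negative slope with correlation
#' near -1.
#'
#' @param net a [CoMethylationNetwork-class] or an \pkg{igraph} graph.
#' @return A [PowerLawFit-class] with the slope (exponent), the Pearson
#'   correlation of the log-log points and its square.
#' @export
degreePowerlawFit <- function(net) {
  g <- if (is(net, "CoMethylationNetwork")) simpleGraph(net) else net
  if (igraph::vcount(g) == 0L) stop("network is empty")
  deg <- igraph::degree(g)
  deg <- deg[deg > 0]
  tab <- table(deg)
  if (length(tab) < 3L) {
    stop(
      "degree distribution has only ", length(tab),
      " distinct value(s); at least 3 are needed for a log-log fit"
    )
  }
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab))
  fit <- stats::lm(y ~ x)
  rho <- stats::cor(x, y)
  new("PowerLawFit",
    exponent = unname(stats::coef(fit)[2L]),
    correlation = rho, rSquare = rho^2
  )
}
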