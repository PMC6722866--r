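#' Min-max normalization of typing features
#'
#' Rescales each feature (row) to \eqn{[0,1]} by (x - min) / (max - min),
#' the normalization applied before K-means typing.
#'
#' @param features numeric matrix, features in rows, samples in columns.
#' @return Matrix of the same shape with every row spanning [0, 1].
#' @examples
#' minmaxNormalize(matrix(c(1, 3, 5), 1, 3)) # 0, 0.5, 1
#' @export
minmaxNormalize <- function(features) {
  features <- as.matrix(features)
  rng <- apply(features, 1L, range)
  flat <- rng[2L, ] - rng[1L, ] == 0
  if (any(flat)) {
    stop("constant feature(s) cannot be min-max normalized: ",
         fewIds(rownames(features)[flat] %||% which(flat)))
  }
  (features - rng[1L, ]) / (rng[2L, ] - rng[1L, ])
}

#' Mean silhouette coefficient
#'
#' For each point i, a(i) is the mean Euclidean distance to the other
#' points of its own cluster and b(i) the minimum over the other clusters
#' of the mean distance to that cluster's points; the silhouette is
#' S(i) = (b(i) - a(i)) / max(a(i), b(i)).  Points in singleton clusters
#' contribute S(i) = 0 (the standard convention; a(i) is undefined there),
#' as do points with a(i) = b(i) = 0.
#'
#' @param points numeric matrix, samples in rows.
#' @param labels cluster labels, one per row of \code{points}; at least two
#'   non-empty clusters.
#' @return The mean silhouette over all points; the per-point values are
#'   attached as \code{attr(, "widths")}.
#' @export
silhouetteMean <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.vector(labels)
  stopifnot(nrow(points) == length(labels))
  lv <- unique(labels)
  if (length(lv) < 2L) stop("need at least 2 clusters")
  d <- as.matrix(stats::dist(points))
  n <- nrow(points)
  s <- numeric(n)
  sizes <- table(factor(labels, levels = lv))
  # mean distance from every point to every cluster, in one pass
  clusterSum <- sapply(lv, function(cl) rowSums(d[, labels == cl, drop = FALSE]))
  for (i in seq_len(n)) {
    own <- match(labels[i], lv)
    nOwn <- sizes[[own]]
    if (nOwn == 1L) {
      s[i] <- 0
      next
    }
    a <- clusterSum[i, own] / (nOwn - 1L)
    others <- which(lv != labels[i])
    b <- min(clusterSum[i, others] / as.numeric(sizes[others]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  out <- mean(s)
  attr(out, "widths") <- s
  out
}

# k-means++ seeding: spread the initial centers by sampling points with
# probability proportional to the squared distance to the nearest center.
kmeansPlusPlusCenters <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      # all remaining points coincide with a center; fall back to uniform
      centers[j + 1L] <- sample.int(n, 1L)
    } else {
      centers[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    dNew <- rowSums((x - matrix(x[centers[j + 1L], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dNew)
  }
  x[centers, , drop = FALSE]
}

#' K-means molecular typing with silhouette model selection
#'
#' Clusters the samples by K-means on the (min-max normalized) module
#' statistics for each k in \code{kRange}, scoring every k by the mean
#' silhouette coefficient and selecting the k with the highest score (ties
#' go to the smaller k).  Each k runs \code{restarts} k-means++
#' initializations and keeps the solution with the lowest within-cluster
#' sum of squares.  Deterministic under a fixed seed.
#'
#' @param features numeric matrix of typing features, features in rows,
#'   samples in columns (normalize first with [minmaxNormalize()]).
#' @param kRange integer vector of cluster counts to scan (default 2:8);
#'   values outside \code{[2, nSamples - 1]} are clipped with a warning.
#' @param seed optional integer seed.
#' @param restarts k-means++ restarts per k (default 50).
#' @return A [TypingResult-class].
#' @export
kmeansTyping <- function(features, kRange = 2:8, seed = NULL, restarts = 50L) {
  features <- as.matrix(features)
  x <- t(features) # samples in rows for clustering
  n <- nrow(x)
  kRange <- sort(unique(as.integer(kRange)))
  ok <- kRange >= 2L & kRange <= n - 1L
  if (!all(ok)) {
    warning("kRange clipped to [2, ", n - 1L, "]")
    kRange <- kRange[ok]
  }
  if (!length(kRange)) stop("no admissible k in kRange")
  nUnique <- nrow(unique(x))

  labelsByK <- list()
  sil <- stats::setNames(rep(NA_real_, length(kRange)), kRange)
  localSeed(seed, {
    for (k in kRange) {
      if (k > nUnique) {
        warning("k = ", k, " exceeds the number of distinct samples; skipped")
        next
      }
      best <- NULL
      for (r in seq_len(restarts)) {
        centers <- kmeansPlusPlusCenters(unique(x), k)
        fit <- suppressWarnings(
          stats::kmeans(x, centers = centers, iter.max = 100L)
        )
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
      labels <- stats::setNames(as.integer(best$cluster), rownames(x))
      labelsByK[[as.character(k)]] <- labels
      sil[as.character(k)] <- as.numeric(silhouetteMean(x, labels))
    }
  })
  sil <- sil[!is.na(sil)]
  if (!length(sil)) stop("no k could be evaluated")
  selected <- as.integer(names(sil)[which.max(sil)]) # which.max: first max, smaller k
  sizes <- table(labelsByK[[as.character(selected)]])
  new("TypingResult",
    labelsByK = labelsByK, silhouetteByK = sil, selectedK = selected,
    clusterSizes = stats::setNames(as.integer(sizes), names(sizes))
  )
}

#' Multi-group survival comparison of molecular types
#'
#' k-group log-rank test of overall survival across cluster labels, with a
#' Kaplan-Meier curve per cluster.
#'
#' @param labels named vector of cluster labels per sample.
#' @param clinical clinical data.frame covering those samples.
#' @return A [SurvivalComparison-class] (hazard ratio is \code{NA} for more
#'   than two groups).
#' @export
multigroupSurvival <- function(labels, clinical) {
  if (is.null(names(labels))) stop("labels must be named by sample")
  clinical <- checkClinicalTable(clinical)
  idx <- match(names(labels), clinical$sample)
  if (anyNA(idx)) {
    stop("samples missing from the clinical table: ",
         fewIds(names(labels)[is.na(idx)]))
  }
  cl <- clinical[idx, ]
  gf <- factor(labels)
  if (nlevels(gf) < 2L) stop("need at least 2 groups")
  if (any(table(gf) == 0L)) stop("every group must contain samples")
  if (sum(cl$status) < 2L) stop("need at least 2 observed events")
  surv <- survival::Surv(cl$time, cl$status)
  lr <- logrank(surv, gf)
  hr <- if (nlevels(gf) == 2L) {
    exp(unname(stats::coef(survival::coxph(surv ~ gf, ties = "breslow"))[1L]))
  } else {
    NA_real_
  }
  new("SurvivalComparison",
    groups = stats::setNames(as.character(labels), names(labels)),
    logrankStat = lr$stat, logrankP = lr$p, hazardRatio = hr,
    coxP = NA_real_, km = kmCurves(surv, gf)
  )
}
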