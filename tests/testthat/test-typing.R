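test_that("min-max normalization maps each feature onto [0, 1]", {
  expect_equal(unname(minmaxNormalize(matrix(c(1, 3, 5), 1, 3))[1, ]),
               c(0, 0.5, 1))
  expect_equal(unname(minmaxNormalize(matrix(c(-2, 0, 2), 1, 3))[1, ]),
               c(0, 0.5, 1))
  already <- matrix(c(0, 0.25, 1), 1, 3)
  expect_equal(minmaxNormalize(already), already)
  bad <- matrix(c(1, 1, 1, 2, 3, 4), 2, 3, byrow = TRUE,
                dimnames = list(c("flat", "ok"), NULL))
  expect_error(minmaxNormalize(bad), "flat")
})

test_that("silhouette agrees with the brute-force double loop", {
  set.seed(70)
  for (rep in 1:25) {
    n <- sample(6:30, 1)
    k <- sample(2:4, 1)
    pts <- matrix(rnorm(n * 2), n, 2)
    labels <- sample(k, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(as.numeric(silhouetteMean(pts, labels)),
                 bruteSilhouette(pts, labels),
                 tolerance = 1e-12)
  }
})

test_that("silhouette honours its closed-form special cases", {
  # a point equidistant from its own cluster and the nearest other cluster
  # has a(i) = b(i), hence S(i) = 0
  pts <- matrix(c(0, 2, -2), 3, 1)
  widths0 <- attr(silhouetteMean(pts, c(1, 1, 2)), "widths")
  expect_equal(widths0[1], 0)

  # two tight, well-separated clusters on a line
  pts2 <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  s2 <- silhouetteMean(pts2, c(1, 1, 2, 2))
  expect_equal(as.numeric(s2), bruteSilhouette(pts2, c(1, 1, 2, 2)))
  expect_gt(as.numeric(s2), 0.97)

  # singleton clusters contribute S = 0
  pts3 <- matrix(c(0, 0.5, 9), 3, 1)
  widths <- attr(silhouetteMean(pts3, c(1, 1, 2)), "widths")
  expect_equal(widths[3], 0)

  # identical duplicated samples at two distinct points: silhouette 1
  pts4 <- matrix(rep(c(0, 5), each = 3), 6, 1)
  expect_equal(as.numeric(silhouetteMean(pts4, rep(1:2, each = 3))), 1)

  expect_error(silhouetteMean(pts2, rep(1, 4)), "2 clusters")
})

test_that("silhouette and log-rank are invariant to cluster relabeling", {
  set.seed(71)
  pts <- matrix(rnorm(40), 20, 2)
  labels <- sample(3, 20, replace = TRUE)
  relab <- c(2L, 3L, 1L)[labels]
  expect_equal(as.numeric(silhouetteMean(pts, labels)),
               as.numeric(silhouetteMean(pts, relab)))

  cl <- makeClinical(rnorm(20), seed = 71)
  l1 <- setNames(labels, cl$sample)
  l2 <- setNames(relab, cl$sample)
  expect_equal(multigroupSurvival(l1, cl)@logrankP,
               multigroupSurvival(l2, cl)@logrankP)
})

test_that("k-means typing finds planted blob counts and memberships", {
  set.seed(72)
  blob <- function(center, n) {
    t(sapply(seq_len(n), function(i) center + rnorm(2, sd = 0.08)))
  }
  two <- rbind(blob(c(0, 0), 30), blob(c(1, 1), 30))
  feats <- t(two)
  rownames(feats) <- c("f1", "f2")
  colnames(feats) <- sprintf("s%02d", 1:60)
  res <- kmeansTyping(minmaxNormalize(feats), kRange = 2:5, seed = 5,
                      restarts = 10)
  expect_equal(res@selectedK, 2L)
  labels <- res@labelsByK[["2"]]
  planted <- rep(1:2, each = 30)
  agreement <- max(mean(labels == planted), mean(labels != planted))
  expect_equal(agreement, 1) # identical up to relabeling

  three <- rbind(blob(c(0, 0), 25), blob(c(1, 1), 25), blob(c(0, 1.3), 25))
  f3 <- t(three)
  rownames(f3) <- c("f1", "f2")
  colnames(f3) <- sprintf("t%02d", 1:75)
  res3 <- kmeansTyping(minmaxNormalize(f3), kRange = 2:6, seed = 6,
                       restarts = 10)
  expect_equal(res3@selectedK, 3L)
  expect_equal(sum(res3@clusterSizes), 75L)
})

test_that("k-means typing is deterministic and clips silly k ranges", {
  set.seed(73)
  feats <- matrix(rnorm(40), 2, 20,
                  dimnames = list(c("f1", "f2"), sprintf("s%02d", 1:20)))
  r1 <- kmeansTyping(feats, kRange = 2:4, seed = 9, restarts = 5)
  r2 <- kmeansTyping(feats, kRange = 2:4, seed = 9, restarts = 5)
  expect_identical(r1@labelsByK, r2@labelsByK)
  expect_identical(r1@silhouetteByK, r2@silhouetteByK)
  expect_warning(kmeansTyping(feats, kRange = 2:25, seed = 9, restarts = 2),
                 "clipped")
})

test_that("multi-group survival detects a high-hazard cluster", {
  set.seed(74)
  n <- 300
  labels <- rep(1:3, each = 100)
  cl <- makeClinical(ifelse(labels == 2, log(3), 0), seed = 74)
  lab <- setNames(labels, cl$sample)
  cmp <- multigroupSurvival(lab, cl)
  expect_lt(cmp@logrankP, 0.01)
  expect_true(is.na(cmp@hazardRatio))

  # with two groups the test reduces to the two-sample log-rank used by the
  # risk-split comparison
  risks <- setNames(as.numeric(labels == 2) + runif(n, 0, 0.1), cl$sample)
  cmpRisk <- splitAndCompare(risks, cl)
  lab2 <- setNames(ifelse(cmpRisk@groups == "High", 1L, 2L), names(risks))
  cmp2 <- multigroupSurvival(lab2, cl)
  expect_equal(cmp2@logrankStat, cmpRisk@logrankStat, tolerance = 1e-9)
  expect_equal(cmp2@logrankP, cmpRisk@logrankP, tolerance = 1e-9)
})
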