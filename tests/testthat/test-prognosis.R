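test_that("module statistics are per-sample means over module genes", {
  v <- matrix(c(1, 3, 5, 2, 4, 6), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  expect_equal(moduleStatistic(v, c("g1", "g2")), c(s1 = 2, s2 = 3))
  expect_equal(moduleStatistic(v, "g3"), c(s1 = 5, s2 = 6))
  expect_warning(
    st <- moduleStatistic(v, c("g1", "absent")),
    "absent"
  )
  expect_equal(st, c(s1 = 1, s2 = 2))
  expect_error(moduleStatistic(v, "nope"), "none")
})

test_that("risk scores implement the signed-sum formula", {
  stats <- matrix(c(2, 0.5), 2, 1, dimnames = list(c("a", "b"), "s1"))
  model <- new("RiskModel", coefficients = c(a = 1, b = -2),
               positive = "a", negative = "b")
  expect_equal(riskScores(stats, model), c(s1 = 1.5))

  bothPos <- new("RiskModel", coefficients = c(a = 1, b = 2),
                 positive = c("a", "b"), negative = character())
  stats2 <- matrix(c(1, 2), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(riskScores(stats2, bothPos), c(s1 = 3))

  expect_error(
    riskScores(stats[1, , drop = FALSE], model),
    "absent"
  )
})

test_that("risk model recovers planted signs for risky and protective modules", {
  set.seed(60)
  n <- 200
  fRisk <- rnorm(n)
  fProt <- rnorm(n)
  cl <- makeClinical(1.2 * fRisk - 1.2 * fProt, seed = 60)
  stats <- rbind(risky = fRisk + rnorm(n, sd = 0.2),
                 protective = fProt + rnorm(n, sd = 0.2),
                 noise = rnorm(n))
  colnames(stats) <- cl$sample
  model <- fitRiskModel(stats, cl)
  expect_true("risky" %in% model@positive)
  expect_true("protective" %in% model@negative)
  expect_true("noise" %in% c(model@positive, model@negative))
})

test_that("risk split recovers a planted hazard ratio and the KM toy value", {
  set.seed(61)
  n <- 300
  risk <- rnorm(n)
  # two groups split by risk with true HR 2.5 between halves is emulated by
  # a proportional-hazards cohort driven by the risk score itself
  cl <- makeClinical(log(2.5) * risk, baseline = 0.005, seed = 61)
  names(risk) <- cl$sample
  cmp <- splitAndCompare(risk, cl)
  expect_equal(as.vector(table(cmp@groups)[c("High", "Low")]), c(150L, 150L))
  expect_lt(cmp@logrankP, 0.01)
  expect_gt(cmp@hazardRatio, 1.3)

  # Kaplan-Meier product-limit check on a 5-sample toy: times 1..5 with
  # events 1,1,0,1,0 give S(4) = (4/5)(3/4)(1/2) = 0.3
  toy <- data.frame(sample = sprintf("t%d", 1:5), time = 1:5,
                    status = c(1L, 1L, 0L, 1L, 0L))
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = toy)
  expect_equal(summary(fit, times = 4)$surv, 0.3)

  # identical survival in both groups: HR 1, log-rank p 1
  cl2 <- data.frame(sample = sprintf("d%d", 1:8),
                    time = rep(c(5, 10, 15, 20), 2),
                    status = rep(c(1L, 1L, 0L, 1L), 2))
  risks2 <- setNames(c(rep(1, 4), rep(0, 4)), cl2$sample)
  cmp2 <- splitAndCompare(risks2, cl2)
  expect_equal(cmp2@hazardRatio, 1, tolerance = 1e-6)
  expect_equal(cmp2@logrankP, 1, tolerance = 1e-6)

  expect_error(splitAndCompare(setNames(rep(1, 8), cl2$sample), cl2),
               "identical")
})

test_that("risk scoring is affine-equivariant and the split is unchanged", {
  set.seed(62)
  stats <- matrix(rnorm(40), 2, 20,
                  dimnames = list(c("a", "b"), sprintf("s%02d", 1:20)))
  model <- new("RiskModel", coefficients = c(a = 0.5, b = -0.5),
               positive = "a", negative = "b")
  r1 <- riskScores(stats, model)
  r2 <- riskScores(stats + 3, model)
  # a constant added to every statistic shifts all risks by the same amount
  expect_equal(unname(r2 - r1), rep(0, 20), tolerance = 1e-12)
  expect_identical(order(r1), order(r2))
})

test_that("gene median splits report KM, log-rank and continuous Cox p", {
  set.seed(63)
  n <- 300
  x <- rnorm(n)
  cl <- makeClinical(1.3 * x, seed = 63)
  v <- rbind(marker = x, other = rnorm(n))
  colnames(v) <- cl$sample
  cmp <- geneMedianSplitSurvival(v, "marker", cl)
  expect_lt(cmp@coxP, 0.05)
  expect_lt(cmp@logrankP, 0.05)
  expect_gt(cmp@hazardRatio, 1) # higher methylation, worse survival here
  expect_setequal(unique(cmp@groups), c("Lower", "Higher"))
  expect_true(all(cmp@km$survival >= 0 & cmp@km$survival <= 1))
  # KM curves are non-increasing within each group
  for (gr in unique(cmp@km$group)) {
    s <- cmp@km$survival[cmp@km$group == gr]
    expect_true(all(diff(s) <= 1e-12))
  }

  expect_error(geneMedianSplitSurvival(v, "missing", cl), "not in")
  vConst <- rbind(flat = rep(1, n))
  colnames(vConst) <- cl$sample
  expect_error(geneMedianSplitSurvival(vConst, "flat", cl), "constant")

  # no observed events: the log-rank comparison is refused
  clNoEv <- data.frame(sample = sprintf("q%d", 1:4), time = 1:4,
                       status = 0L)
  vq <- rbind(g = c(1, 2, 3, 4))
  colnames(vq) <- clNoEv$sample
  expect_error(geneMedianSplitSurvival(vq, "g", clNoEv), "events")
})

test_that("group value comparison behaves at the null, under shift, and on ties", {
  set.seed(64)
  g <- rep(c("lo", "hi"), each = 50)
  shifted <- c(rnorm(50), rnorm(50, mean = 3))
  expect_lt(groupValueComparison(shifted, g), 1e-6)
  expect_equal(groupValueComparison(rep(1, 100), g), 1)
  expect_error(groupValueComparison(rnorm(10), rep("a", 10)), "two")
  # null calibration: same distribution in both groups rarely significant
  ps <- replicate(20, groupValueComparison(rnorm(40), rep(c("a", "b"), 20)))
  expect_gt(mean(ps > 0.05), 0.7)
})

test_that("train/test splits halve the cohort with the extra sample in training", {
  s <- sprintf("p%03d", 1:101)
  sp <- suppressMessages(trainTestSplit(s, seed = 1))
  expect_length(sp$train, 51L)
  expect_length(sp$test, 50L)
  expect_setequal(c(sp$train, sp$test), s)
  sp2 <- suppressMessages(trainTestSplit(s, seed = 1))
  expect_identical(sp, sp2)
})
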