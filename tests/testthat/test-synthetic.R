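smallSpec <- function(seed = 1L, ...) {
  cohortSpec(nGenes = 120L, nSamples = 150L,
             moduleSizes = rep(15L, 3L),
             crossTalk = data.frame(moduleA = 1L, moduleB = 2L, rho = 0.8),
             hazardWeights = c(1, 0, -1),
             seed = seed, ...)
}

test_that("cohort spec validates its invariants", {
  expect_error(cohortSpec(nGenes = 10, moduleSizes = c(8, 8)), "exceed")
  expect_error(cohortSpec(moduleLoadings = rep(1.2, 5)), "loadings")
  expect_error(
    cohortSpec(crossTalk = data.frame(moduleA = 1, moduleB = 2, rho = 2)),
    "rho"
  )
  expect_error(
    cohortSpec(crossTalk = data.frame(moduleA = c(1, 1), moduleB = c(2, 3),
                                      rho = 0.5)),
    "at most one"
  )
  expect_error(cohortSpec(censoringRate = 1), "censoringRate")
  expect_silent(validObject(cohortSpec()))
})

test_that("generated cohorts have the planted correlation structure", {
  co <- generateCohort(smallSpec(seed = 3))
  v <- methValues(betaToM(co$beta))
  r <- cor(t(v))
  truth <- co$truth$membership

  # block modules: tight five-gene blocks, module-wide correlation well
  # above the background
  blockGenes <- truth[[3]] # plain block module
  withinBlock <- abs(r[blockGenes[3:5], blockGenes[3:5]])
  expect_gt(mean(withinBlock[upper.tri(withinBlock)]), 0.6)
  withinModule <- abs(r[blockGenes, blockGenes])
  background <- setdiff(rownames(v), unlist(truth))
  between <- abs(r[blockGenes, background[1:40]])
  expect_gt(mean(withinModule[upper.tri(withinModule)]), 3 * mean(between))
  expect_lt(mean(between), 0.15)

  # the cross-talk pair is correlated above unrelated module pairs
  crossPair <- abs(r[truth[[1]], setdiff(truth[[2]], co$truth$bridges$gene)])
  unrelated <- abs(r[truth[[1]], truth[[3]]])
  expect_gt(mean(crossPair), mean(unrelated) + 0.1)

  # bridge genes correlate with their partner module's blocks
  br <- co$truth$bridges
  expect_gt(nrow(br), 0L)
  expect_true(all(br$gene %in% truth[[2]]))
  bridgeR <- abs(r[br$gene, truth[[1]], drop = FALSE])
  expect_gt(mean(apply(bridgeR, 1, max)), 0.3)
})

test_that("beta values stay inside (0,1) and invert back to the planted M", {
  co <- generateCohort(smallSpec(seed = 4))
  b <- methValues(co$beta)
  expect_true(all(b > 0 & b < 1))
  expect_equal(methValues(betaToM(co$beta)), co$truth$mValues,
               tolerance = 1e-9)
})

test_that("survival generation hits the censoring target and hazard signs", {
  co <- generateCohort(cohortSpec(nGenes = 60L, nSamples = 2000L,
                                  moduleSizes = rep(15L, 3L),
                                  crossTalk = NULL,
                                  hazardWeights = c(1, 0, -1), seed = 5))
  expect_equal(mean(co$clinical$status == 0), 0.3, tolerance = 0.05)
  expect_true(all(co$clinical$time > 0))
  # the linear predictor follows the planted weights
  f <- co$truth$factors
  expect_equal(unname(co$truth$linearPredictor),
               unname(f[, 1] - f[, 3]), tolerance = 1e-12)

  # all-zero hazard weights give survival independent of the modules: the
  # log-rank p for a module-driven split is not systematically small
  ps <- vapply(1:8, function(s) {
    coN <- generateCohort(cohortSpec(nGenes = 40L, nSamples = 120L,
                                     moduleSizes = c(15L, 15L),
                                     crossTalk = NULL,
                                     hazardWeights = c(0, 0), seed = 100 + s))
    stat <- moduleStatistic(methValues(betaToM(coN$beta)),
                            coN$truth$membership[[1]])
    splitAndCompare(stat, coN$clinical)@logrankP
  }, 0)
  expect_gt(mean(ps > 0.05), 0.6)
  expect_gt(min(ps), 0.001)
})

test_that("cohorts are exactly reproducible from their seed", {
  c1 <- generateCohort(smallSpec(seed = 6))
  c2 <- generateCohort(smallSpec(seed = 6))
  c3 <- generateCohort(smallSpec(seed = 7))
  expect_identical(methValues(c1$beta), methValues(c2$beta))
  expect_identical(c1$clinical, c2$clinical)
  expect_false(identical(methValues(c1$beta), methValues(c3$beta)))
})

test_that("probe-level expansion plants known filter violations", {
  pr <- generateProbeLevel(smallSpec(seed = 8), probesPerGene = 3,
                           badPerCriterion = 2)
  nGenes <- nrow(methValues(pr$cohort$beta))
  expect_equal(nrow(methValues(pr$beta)), nGenes * 3 + 10)

  filtered <- suppressMessages(filterProbes(pr$beta, pr$annotation))
  counts <- attr(filtered, "removalCounts")
  expect_equal(unname(counts), unname(pr$injected))
  expect_equal(nrow(methValues(filtered)), nGenes * 3)

  # collapsing the clean probes approximates the gene-level beta
  genes <- suppressMessages(collapseToGenes(filtered, pr$annotation))
  common <- intersect(featureNames(genes), featureNames(pr$cohort$beta))
  diff <- abs(methValues(genes)[common, ] -
                methValues(pr$cohort$beta)[common, ])
  expect_lt(max(diff), 0.1)

  # probes of one gene average to the gene value on the beta scale
  b <- matrix(c(0.2, 0.4), 2, 1, dimnames = list(c("cgA", "cgB"), "s1"))
  ann <- data.frame(probe = c("cgA", "cgB"), chromosome = "chr1",
                    gene = "G", region = "TSS200", snp = FALSE,
                    crossReactive = FALSE)
  expect_equal(
    unname(methValues(suppressMessages(
      collapseToGenes(MethylationMatrix(b, "beta"), ann)
    ))[1, 1]),
    0.3
  )
})

test_that("expression is anti-correlated with promoter methylation", {
  co <- generateCohort(smallSpec(seed = 9))
  m <- co$truth$mValues
  e <- methValues(co$expression)
  cors <- vapply(seq_len(nrow(m)), function(i) cor(m[i, ], e[i, ]), 0)
  expect_lt(median(cors), -0.3)
})
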