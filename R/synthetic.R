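# Internal generator constants (documented in the methods vignette):
# weight of the module-wide common factor in every gene latent (the common
# variance share is c^2 / (1 + c^2)), the size of the co-methylated gene
# blocks modules are built from, and the backbone loading of the one
# connector gene per block that ties the blocks of a module together.
commonFactorWeight <- sqrt(0.4)
moduleBlockSize <- 5L
connectorWeight <- 0.8

#' Describe a synthetic methylation cohort
#'
#' Builds a validated [CohortSpec-class].  The defaults encode the study
#' conditions used throughout the package's end-to-end tests: 500 genes by
#' 300 samples, five planted 15-gene modules with factor loading 0.9, one
#' cross-talk pair between modules 1 and 2 with factor correlation 0.8,
#' hazard weights +1 and -1 on modules 3 and 4, exponential survival with
#' 30 percent censoring, and promoter methylation repressing expression.
#'
#' @param nGenes,nSamples cohort dimensions.
#' @param moduleSizes integer vector of planted module sizes.
#' @param moduleLoadings factor loading per module, in (0, 1].
#' @param crossTalk data.frame with columns \code{moduleA}, \code{moduleB},
#'   \code{rho}; each module may appear in at most one pair.
#' @param noiseSD residual SD of module genes (M scale).
#' @param backgroundSD SD of background genes (M scale).
#' @param hazardWeights per-module weight of the module factor in the log
#'   hazard.
#' @param baselineHazard exponential baseline hazard, events per day.
#' @param censoringRate target censored fraction, in [0, 1).
#' @param expressionCoupling repression slope of expression on M.
#' @param bridgeFraction fraction of a cross-talk donor module's genes that
#'   become bridge genes.
#' @param bridgeMix weight of the partner-module latent in a bridge gene.
#' @param seed integer seed.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nGenes = 500L, nSamples = 300L,
                       moduleSizes = rep(15L, 5L),
                       moduleLoadings = rep(0.9, length(moduleSizes)),
                       crossTalk = data.frame(
                         moduleA = 1L, moduleB = 2L, rho = 0.8
                       ),
                       noiseSD = 0.3, backgroundSD = 1,
                       hazardWeights = defaultHazardWeights(length(moduleSizes)),
                       baselineHazard = 0.002, censoringRate = 0.3,
                       expressionCoupling = 1,
                       bridgeFraction = 0.2, bridgeMix = 0.5,
                       seed = 1L) {
  if (is.null(crossTalk)) {
    crossTalk <- data.frame(moduleA = integer(), moduleB = integer(),
                            rho = numeric())
  }
  new("CohortSpec",
    nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
    moduleSizes = as.integer(moduleSizes),
    moduleLoadings = as.numeric(moduleLoadings),
    crossTalk = crossTalk,
    noiseSD = noiseSD, backgroundSD = backgroundSD,
    hazardWeights = as.numeric(hazardWeights),
    baselineHazard = baselineHazard, censoringRate = censoringRate,
    expressionCoupling = expressionCoupling,
    bridgeFraction = bridgeFraction, bridgeMix = bridgeMix,
    seed = as.integer(seed)
  )
}

defaultHazardWeights <- function(nModules) {
  w <- numeric(nModules)
  if (nModules >= 3L) w[3L] <- 1
  if (nModules >= 4L) w[4L] <- -1
  w
}

# solve the uniform-censoring horizon T so that the expected censored
# fraction matches the target: P(censored | rate r) = (1 - exp(-rT)) / (rT)
censoringHorizon <- function(rates, target) {
  f <- function(logT) {
    rT <- rates * exp(logT)
    mean((1 - exp(-rT)) / rT) - target
  }
  stats::uniroot(f, lower = log(1e-6 / mean(rates)),
                 upper = log(1e6 / mean(rates)), tol = 1e-10)$root
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [CohortSpec-class].  Each planted module m has a
#' per-sample common factor f_m; a module gene's M value is
#' mu_g + loading * L_g + noise, where the gene latent L_g mixes the common
#' factor with gene-specific structure:
#' \itemize{
#'   \item ordinary modules are built from five-gene blocks: the genes of a
#'     block share a block subfactor (within-block correlation ~0.9, so a
#'     block shows up as a near-clique among each gene's strongest
#'     partners), and one connector gene per block loads on a module-wide
#'     backbone factor that correlates the connectors with each other and
#'     ties the blocks of a module together;
#'   \item the second module of a cross-talk pair is planted as a smooth
#'     circular correlation gradient ("ring") plus bridge genes: a bridge
#'     gene is private noise plus loadings on the latents of (up to three
#'     of) the partner module's blocks, which is what makes the planted
#'     cross-talk visible as actual between-module edges in a top-k network
#'     (the correlated common factors alone can never outrank a gene's own
#'     module neighbours there); the pair's common factors are also
#'     correlated at the requested rho.
#' }
#' Background genes are independent noise.  Beta values are the logistic
#' transform of M, so they always lie strictly inside (0, 1).  Survival is
#' exponential with log hazard sum(w_m * f_m), censored by independent
#' uniform times whose horizon is solved numerically to hit the requested
#' censoring fraction; expression is -coupling * M plus unit noise
#' (promoter methylation represses expression).
#'
#' @param spec a [CohortSpec-class].
#' @return List with elements \code{beta} (gene-level beta
#'   [MethylationMatrix-class]), \code{clinical} (data.frame
#'   \code{sample}/\code{time}/\code{status}), \code{expression}
#'   ([MethylationMatrix-class]), and \code{truth}: a list holding
#'   \code{membership} (gene ids per module), \code{bridges}, \code{factors}
#'   (the common factors, samples x modules), \code{linearPredictor},
#'   \code{eventTimes} (pre-censoring), \code{crossTalk} and \code{mValues}.
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  nG <- spec@nGenes
  nS <- spec@nSamples
  sizes <- spec@moduleSizes
  nMod <- length(sizes)
  cc <- commonFactorWeight
  norm0 <- sqrt(1 + cc^2)

  genes <- sprintf("G%0*d", max(4L, nchar(nG)), seq_len(nG))
  samples <- sprintf("S%0*d", max(3L, nchar(nS)), seq_len(nS))

  localSeed(spec@seed, {
    # the second module of each cross-talk pair carries the bridge genes
    # (and is planted as a ring); the first keeps the block structure
    donors <- integer(0)
    partnerOf <- integer(0)
    if (nrow(spec@crossTalk)) {
      donors <- as.integer(spec@crossTalk$moduleB)
      partnerOf <- stats::setNames(as.integer(spec@crossTalk$moduleA), donors)
    }

    # common factors, correlated within cross-talk pairs
    f0 <- matrix(stats::rnorm(nS * max(nMod, 1L)), nS, max(nMod, 1L))
    if (nrow(spec@crossTalk)) {
      for (r in seq_len(nrow(spec@crossTalk))) {
        i <- spec@crossTalk$moduleA[r]
        j <- spec@crossTalk$moduleB[r]
        rho <- spec@crossTalk$rho[r]
        f0[, j] <- rho * f0[, i] + sqrt(1 - rho^2) * f0[, j]
      }
    }

    # per-module gene latents (samples x size). Modules are planted as
    # chained co-methylated blocks: the genes of a block share a block
    # subfactor (so each gene's strongest partners are its block mates and
    # the blocks appear as near-cliques in a top-k network) and one
    # connector gene per block loads on a module backbone factor that ties
    # the blocks together.  Cross-talk donor modules instead place their
    # non-bridge genes on a smooth circular correlation gradient ("ring").
    ringLatents <- function(m, size = sizes[m]) {
      F1 <- stats::rnorm(nS)
      F2 <- stats::rnorm(nS)
      th <- 2 * pi * (seq_len(size) - 1L) / size
      sapply(th, function(t) (cos(t) * F1 + sin(t) * F2 + cc * f0[, m]) / norm0)
    }
    blockLatents <- function(m) {
      size <- sizes[m]
      nFull <- size %/% moduleBlockSize
      blockOf <- c(
        rep(seq_len(max(nFull, 1L)), each = moduleBlockSize),
        rep(nFull + 1L, moduleBlockSize)
      )[seq_len(size)]
      nBlocks <- max(blockOf)
      d <- matrix(stats::rnorm(nS * nBlocks), nS, nBlocks)
      lat <- sapply(seq_len(size),
                    function(g) (d[, blockOf[g]] + cc * f0[, m]) / norm0)
      # one connector gene per full block loads on a module backbone
      # factor, so the connectors of a module correlate with each other and
      # chain its blocks together in the top-k graph
      if (nFull >= 2L) {
        backbone <- stats::rnorm(nS)
        v <- connectorWeight
        for (b in seq_len(nFull)) {
          conn <- which(blockOf == b)[1L]
          lat[, conn] <- sqrt(1 - v^2) * lat[, conn] + v * backbone
        }
      }
      attr(lat, "block") <- blockOf
      lat
    }

    latents <- vector("list", nMod)
    bridges <- list()
    for (m in setdiff(seq_len(nMod), donors)) {
      latents[[m]] <- blockLatents(m)
    }
    # a donor module consists of a ring plus bridge ("coupling") genes:
    # a bridge gene's methylation is private noise plus a loading on the
    # latent of one of the acceptor's blocks, which is what makes the
    # planted cross-talk visible as actual donor-acceptor edges in a top-k
    # network (the correlated common factors alone cannot outrank a gene's
    # own module neighbours)
    for (m in donors) {
      j <- partnerOf[[as.character(m)]]
      blockOfJ <- attr(latents[[j]], "block")
      targetBlocks <- which(tabulate(blockOfJ) >= moduleBlockSize)
      nB <- min(round(spec@bridgeFraction * sizes[m]), sizes[m] - 1L)
      if (!length(targetBlocks)) nB <- 0L
      lat <- matrix(NA_real_, nS, sizes[m])
      lat[, seq_len(sizes[m] - nB)] <- ringLatents(m, sizes[m] - nB)
      if (nB >= 1L) {
        bIdx <- (sizes[m] - nB + 1L):sizes[m]
        # each bridge couples to (up to) three partner blocks, so its picks
        # straddle blocks and its own local density stays clearly below
        # that of a genuine block member
        nT <- min(3L, length(targetBlocks))
        wt <- spec@bridgeMix / sqrt(nT)
        for (b in seq_len(nB)) {
          tgt <- targetBlocks[(b - 1L + seq_len(nT) - 1L) %%
                                length(targetBlocks) + 1L]
          pures <- vapply(tgt, function(tb) which(blockOfJ == tb)[2L], 1L)
          lat[, bIdx[b]] <- sqrt(1 - nT * wt^2) * stats::rnorm(nS) +
            latents[[j]][, pures, drop = FALSE] %*% rep(wt, nT)
        }
        bridges[[length(bridges) + 1L]] <- data.frame(
          module = m, geneIndex = bIdx, partnerModule = j,
          partnerBlock = rep_len(targetBlocks, nB)
        )
      }
      latents[[m]] <- lat
    }

    # assemble the M matrix: module genes first, then background
    mu <- stats::rnorm(nG)
    M <- matrix(NA_real_, nG, nS, dimnames = list(genes, samples))
    offset <- 0L
    membership <- vector("list", nMod)
    for (m in seq_len(nMod)) {
      idx <- offset + seq_len(sizes[m])
      lam <- spec@moduleLoadings[m]
      M[idx, ] <- t(lam * latents[[m]]) +
        mu[idx] +
        matrix(stats::rnorm(sizes[m] * nS, 0, spec@noiseSD), sizes[m], nS)
      membership[[m]] <- genes[idx]
      offset <- offset + sizes[m]
    }
    if (offset < nG) {
      bg <- (offset + 1L):nG
      M[bg, ] <- mu[bg] +
        matrix(stats::rnorm(length(bg) * nS, 0, spec@backgroundSD),
               length(bg), nS)
    }
    names(membership) <- paste0("planted", seq_len(nMod))

    bridgeGenes <- if (length(bridges)) {
      b <- do.call(rbind, bridges)
      moduleOffsets <- cumsum(c(0L, sizes))[b$module]
      data.frame(
        gene = genes[moduleOffsets + b$geneIndex],
        module = paste0("planted", b$module),
        partner = paste0("planted", b$partnerModule),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(gene = character(), module = character(), partner = character())
    }

    # survival under exponential proportional hazards
    lp <- as.vector(f0[, seq_len(nMod), drop = FALSE] %*% spec@hazardWeights)
    rates <- spec@baselineHazard * exp(lp)
    eventTimes <- stats::rexp(nS, rates)
    if (spec@censoringRate > 0) {
      horizon <- exp(censoringHorizon(rates, spec@censoringRate))
      censorTimes <- stats::runif(nS, 0, horizon)
      time <- pmin(eventTimes, censorTimes)
      status <- as.integer(eventTimes <= censorTimes)
    } else {
      time <- eventTimes
      status <- rep(1L, nS)
    }
    clinical <- data.frame(sample = samples, time = time, status = status,
                           stringsAsFactors = FALSE)

    expr <- -spec@expressionCoupling * M +
      matrix(stats::rnorm(nG * nS), nG, nS)
    dimnames(expr) <- dimnames(M)

    beta <- 2^M / (1 + 2^M)
    factorMat <- f0[, seq_len(nMod), drop = FALSE]
    colnames(factorMat) <- names(membership)

    list(
      beta = MethylationMatrix(beta, "beta"),
      clinical = clinical,
      expression = MethylationMatrix(expr, "expression"),
      truth = list(
        membership = membership,
        bridges = bridgeGenes,
        factors = factorMat,
        hazardWeights = stats::setNames(spec@hazardWeights, names(membership)),
        linearPredictor = stats::setNames(lp, samples),
        eventTimes = stats::setNames(eventTimes, samples),
        crossTalk = spec@crossTalk,
        mValues = M
      )
    )
  })
}

#' Expand a cohort to probe level, with planted filter violations
#'
#' Expands each gene of a generated cohort into \code{probesPerGene} probes
#' whose beta values are the gene's beta plus small independent noise, and
#' appends \code{badPerCriterion} designated probes violating each of the
#' five probe filters (missing beta, X/Y chromosome, SNP-affected,
#' cross-reactive, non-promoter region), so the per-criterion removal
#' counts of [filterProbes()] are known by construction.
#'
#' @param spec a [CohortSpec-class].
#' @param probesPerGene probes per gene (>= 1).
#' @param annotationNoise SD of the probe-level noise on the beta scale.
#' @param badPerCriterion number of injected probes per filter criterion.
#' @return List with \code{beta} (probe-level [MethylationMatrix-class]),
#'   \code{annotation} (data.frame), \code{cohort} (the underlying
#'   [generateCohort()] result) and \code{injected} (named count vector of
#'   planted violations, in filter order).
#' @export
generateProbeLevel <- function(spec, probesPerGene = 3L, annotationNoise = 0.02,
                               badPerCriterion = 2L) {
  stopifnot(is(spec, "CohortSpec"))
  probesPerGene <- as.integer(probesPerGene)
  if (probesPerGene < 1L) stop("probesPerGene must be >= 1")
  cohort <- generateCohort(spec)
  b <- methValues(cohort$beta)
  nG <- nrow(b)

  localSeed(deriveSeed(spec@seed, "probe-level"), {
    nClean <- nG * probesPerGene
    clean <- b[rep(seq_len(nG), each = probesPerGene), , drop = FALSE] +
      matrix(stats::rnorm(nClean * ncol(b), 0, annotationNoise),
             nClean, ncol(b))
    clean <- pmin(pmax(clean, 1e-4), 1 - 1e-4)
    geneOf <- rep(rownames(b), each = probesPerGene)

    nBad <- 5L * badPerCriterion
    badGene <- sample(rownames(b), nBad, replace = TRUE)
    bad <- matrix(stats::runif(nBad * ncol(b), 0.05, 0.95), nBad, ncol(b))
    criteria <- rep(c("missingBeta", "sexChromosome", "snpAffected",
                      "crossReactive", "nonPromoter"), each = badPerCriterion)

    values <- rbind(clean, bad)
    probes <- sprintf("cg%07d", seq_len(nrow(values)))
    rownames(values) <- probes
    ann <- data.frame(
      probe = probes,
      chromosome = sample(paste0("chr", 1:22), nrow(values), replace = TRUE),
      gene = c(geneOf, badGene),
      region = sample(promoterRegionClasses, nrow(values), replace = TRUE),
      snp = FALSE, crossReactive = FALSE,
      stringsAsFactors = FALSE
    )
    badRows <- nClean + seq_len(nBad)
    for (k in seq_len(nBad)) {
      row <- badRows[k]
      switch(criteria[k],
        missingBeta = { values[row, sample(ncol(values), 1L)] <- NA },
        sexChromosome = { ann$chromosome[row] <- sample(c("chrX", "chrY"), 1L) },
        snpAffected = { ann$snp[row] <- TRUE },
        crossReactive = { ann$crossReactive[row] <- TRUE },
        nonPromoter = { ann$region[row] <- "Body" }
      )
    }
    list(
      beta = MethylationMatrix(values, "beta"),
      annotation = ann,
      cohort = cohort,
      injected = stats::setNames(
        rep(badPerCriterion, 5L),
        c("missingBeta", "sexChromosome", "snpAffected", "crossReactive",
          "nonPromoter")
      )
    )
  })
}
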