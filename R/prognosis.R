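#' Per-sample module statistic
#'
#' The statistical value of a module in a sample is the mean M value of the
#' module's genes in that sample.  Module genes missing from the matrix are
#' logged and the mean is taken over the present ones.
#'
#' @param m gene-by-sample [MethylationMatrix-class] or numeric matrix.
#' @param mod a [GeneModule-class] or a character vector of gene ids.
#' @return Named numeric vector, one value per sample.
#' @export
moduleStatistic <- function(m, mod) {
  v <- asValueMatrix(m)
  genes <- if (is(mod, "GeneModule")) moduleGenes(mod) else as.character(mod)
  present <- intersect(genes, rownames(v))
  if (!length(present)) {
    stop("none of the module's genes are present in the matrix")
  }
  if (length(present) < length(genes)) {
    warning(
      length(genes) - length(present), " module gene(s) absent from the matrix: ",
      fewIds(setdiff(genes, present))
    )
  }
  colMeans(v[present, , drop = FALSE])
}

#' Module statistics for a set of modules
#'
#' @param m gene-by-sample matrix (see [moduleStatistic()]).
#' @param mods list of [GeneModule-class] objects.
#' @return Matrix of module statistics, modules in rows, samples in columns.
#' @export
moduleStatistics <- function(m, mods) {
  sets <- moduleGeneSets(mods)
  out <- t(vapply(sets, function(genes) moduleStatistic(m, genes),
                  numeric(ncol(asValueMatrix(m)))))
  rownames(out) <- names(sets)
  out
}

#' Random equal train/test split of samples
#'
#' @param samples character vector of sample ids.
#' @param seed optional integer seed.
#' @return List with \code{train} and \code{test} halves.  With an odd
#'   sample count the training half receives the extra sample (logged).
#' @export
trainTestSplit <- function(samples, seed = NULL) {
  samples <- as.character(samples)
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples to split")
  if (n %% 2L == 1L) {
    stageLog("prognosis", "odd sample count: training half receives the extra sample")
  }
  perm <- localSeed(seed, sample(n))
  nTrain <- ceiling(n / 2)
  list(train = samples[perm[seq_len(nTrain)]],
       test = samples[perm[(nTrain + 1L):n]])
}

#' Fit the signed-module risk model
#'
#' Fits a univariate Cox proportional-hazards regression of survival on
#' each module's statistic over the training samples; the sign of the
#' fitted coefficient assigns the module to the risk-increasing (x_i) or
#' risk-decreasing (y_j) side of the GGI-style score.  Modules whose fit
#' fails are dropped with a warning; a zero coefficient goes to the
#' positive side with a warning.
#'
#' @param trainStats module-by-sample statistic matrix (training samples).
#' @param clinical clinical data.frame (\code{sample}, \code{time},
#'   \code{status}) covering the training samples.
#' @return A [RiskModel-class].
#' @export
fitRiskModel <- function(trainStats, clinical) {
  stopifnot(is.matrix(trainStats))
  clinical <- checkClinicalTable(clinical)
  idx <- match(colnames(trainStats), clinical$sample)
  if (anyNA(idx)) {
    stop("samples missing from the clinical table: ",
         fewIds(colnames(trainStats)[is.na(idx)]))
  }
  cl <- clinical[idx, ]
  if (ncol(trainStats) < 10L) stop("need at least 10 training samples")
  if (sum(cl$status) < 2L) stop("need at least 2 observed events")
  surv <- survival::Surv(cl$time, cl$status)

  coefs <- stats::setNames(numeric(0), character(0))
  for (mod in rownames(trainStats)) {
    est <- univariateCoxP(surv, trainStats[mod, ], returnCoef = TRUE)
    if (is.na(est[1L])) {
      warning("module '", mod, "' dropped: Cox fit failed")
      next
    }
    coefs[mod] <- est[1L]
  }
  if (!length(coefs)) stop("no module survived the Cox fits")
  zero <- names(coefs)[coefs == 0]
  if (length(zero)) {
    warning("zero Cox coefficient; assigned to the positive set: ",
            fewIds(zero))
  }
  new("RiskModel",
    coefficients = coefs,
    positive = names(coefs)[coefs >= 0],
    negative = names(coefs)[coefs < 0]
  )
}

#' GGI-style prognosis risk scores
#'
#' risk = sum of the statistics of the positive-sign modules minus the sum
#' of the statistics of the negative-sign modules, per sample.
#'
#' @param stats module-by-sample statistic matrix (e.g. the test samples).
#' @param model a [RiskModel-class].
#' @return Named numeric vector of risk scores.
#' @examples
#' stats <- matrix(c(2, 0.5), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' model <- new("RiskModel", coefficients = c(a = 1, b = -1),
#'              positive = "a", negative = "b")
#' riskScores(stats, model) # 2 - 0.5 = 1.5
#' @export
riskScores <- function(stats, model) {
  stopifnot(is(model, "RiskModel"), is.matrix(stats))
  need <- c(model@positive, model@negative)
  if (!length(need)) stop("risk model is empty")
  missing <- setdiff(need, rownames(stats))
  if (length(missing)) {
    stop("module(s) absent from the statistics: ", fewIds(missing))
  }
  pos <- if (length(model@positive)) {
    colSums(stats[model@positive, , drop = FALSE])
  } else {
    stats::setNames(numeric(ncol(stats)), colnames(stats))
  }
  neg <- if (length(model@negative)) {
    colSums(stats[model@negative, , drop = FALSE])
  } else {
    0
  }
  pos - neg
}

kmCurves <- function(surv, groups) {
  fit <- survival::survfit(surv ~ groups)
  if (is.null(fit$strata)) {
    data.frame(group = as.character(unique(groups)), time = fit$time,
               survival = fit$surv, stringsAsFactors = FALSE)
  } else {
    data.frame(
      group = rep(sub("^groups=", "", names(fit$strata)), fit$strata),
      time = fit$time, survival = fit$surv, stringsAsFactors = FALSE
    )
  }
}

logrank <- function(surv, groups) {
  sd <- survival::survdiff(surv ~ groups)
  df <- length(unique(groups)) - 1L
  list(stat = sd$chisq, p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Split samples by risk and compare survival
#'
#' Ranks the samples by risk score and labels the upper half "High" and the
#' lower half "Low" (equal group sizes; with an odd count the median sample
#' goes to the Low group; risk ties at the boundary are resolved by sample
#' id so the sizes stay equal).  The two groups are compared by the
#' two-sample log-rank test, and the hazard ratio of High versus Low is
#' estimated from a univariate Cox fit on the group indicator.
#'
#' @param risks named numeric vector of per-sample risk scores.
#' @param clinical clinical data.frame covering those samples.
#' @return A [SurvivalComparison-class].
#' @export
splitAndCompare <- function(risks, clinical) {
  if (is.null(names(risks))) stop("risks must be named by sample")
  clinical <- checkClinicalTable(clinical)
  idx <- match(names(risks), clinical$sample)
  if (anyNA(idx)) {
    stop("samples missing from the clinical table: ",
         fewIds(names(risks)[is.na(idx)]))
  }
  cl <- clinical[idx, ]
  n <- length(risks)
  if (n < 4L) stop("need at least 4 samples")
  if (sum(cl$status) < 2L) stop("need at least 2 observed events")
  if (stats::sd(risks) == 0) stop("all risk scores are identical: no split possible")

  ord <- order(-risks, names(risks))
  nHigh <- floor(n / 2)
  groups <- stats::setNames(rep("Low", n), names(risks))
  groups[ord[seq_len(nHigh)]] <- "High"
  gf <- factor(groups, levels = c("Low", "High"))

  surv <- survival::Surv(cl$time, cl$status)
  lr <- logrank(surv, gf)
  hr <- exp(unname(stats::coef(
    survival::coxph(surv ~ gf, ties = "breslow")
  )[1L]))
  new("SurvivalComparison",
    groups = groups, logrankStat = lr$stat, logrankP = lr$p,
    hazardRatio = hr, coxP = NA_real_, km = kmCurves(surv, gf)
  )
}

#' Median-split survival analysis of a single gene
#'
#' Splits the patients at the median methylation of one gene into lower-
#' and higher-methylation groups, compares the groups by the log-rank test
#' and a Cox fit on the group indicator (hazard ratio of Higher versus
#' Lower), and additionally reports the Wald p-value of a univariate Cox
#' regression on the continuous methylation value.
#'
#' @param m gene-by-sample matrix.
#' @param gene gene id (must be present and non-constant).
#' @param clinical clinical data.frame covering the matrix samples.
#' @return A [SurvivalComparison-class]; the continuous Cox p-value is in
#'   slot \code{coxP}.
#' @export
geneMedianSplitSurvival <- function(m, gene, clinical) {
  v <- asValueMatrix(m)
  if (!gene %in% rownames(v)) stop("gene '", gene, "' not in the matrix")
  x <- v[gene, ]
  if (stats::sd(x) == 0) stop("gene '", gene, "' is constant")
  clinical <- checkClinicalTable(clinical)
  idx <- match(colnames(v), clinical$sample)
  if (anyNA(idx)) {
    stop("samples missing from the clinical table: ",
         fewIds(colnames(v)[is.na(idx)]))
  }
  cl <- clinical[idx, ]
  if (length(x) < 4L) stop("need at least 4 samples")
  if (sum(cl$status) < 2L) {
    stop("log-rank test undefined: need at least 2 observed events")
  }
  groups <- stats::setNames(
    ifelse(x > stats::median(x), "Higher", "Lower"), colnames(v)
  )
  if (length(unique(groups)) < 2L) {
    stop("median split produced a single group")
  }
  gf <- factor(groups, levels = c("Lower", "Higher"))
  surv <- survival::Surv(cl$time, cl$status)
  lr <- logrank(surv, gf)
  hr <- exp(unname(stats::coef(
    survival::coxph(surv ~ gf, ties = "breslow")
  )[1L]))
  coxP <- univariateCoxP(surv, x)
  new("SurvivalComparison",
    groups = groups, logrankStat = lr$stat, logrankP = lr$p,
    hazardRatio = hr, coxP = coxP, km = kmCurves(surv, gf)
  )
}

#' Compare a numeric value between two groups
#'
#' Two-sided Mann-Whitney-Wilcoxon test (used e.g. to compare a gene's
#' expression between its lower- and higher-methylation patient groups).
#'
#' @param values named numeric vector per sample.
#' @param groups vector of two group labels, aligned with \code{values}.
#' @return The MWW p-value.
#' @export
groupValueComparison <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two non-empty groups are required")
  x <- values[groups == lv[1L]]
  y <- values[groups == lv[2L]]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (length(unique(values)) == 1L) {
    return(1)
  }
  suppressWarnings(stats::wilcox.test(x, y))$p.value
}
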