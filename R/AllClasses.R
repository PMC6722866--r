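#' @import methods
NULL

validMethylationMatrix <- function(object) {
  v <- object@values
  msgs <- character()
  if (!is.matrix(v) || !is.numeric(v)) {
    return("values must be a numeric matrix")
  }
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    msgs <- c(msgs, "values must have row (feature) and column (sample) names")
  } else {
    if (anyDuplicated(rownames(v))) {
      msgs <- c(msgs, paste0(
        "duplicate feature ids: ",
        fewIds(unique(rownames(v)[duplicated(rownames(v))]))
      ))
    }
    if (anyDuplicated(colnames(v))) {
      msgs <- c(msgs, paste0(
        "duplicate sample ids: ",
        fewIds(unique(colnames(v)[duplicated(colnames(v))]))
      ))
    }
  }
  if (!object@kind %in% c("beta", "M", "expression")) {
    msgs <- c(msgs, "kind must be one of 'beta', 'M', 'expression'")
  }
  if (object@kind == "beta") {
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(v))
      msgs <- c(msgs, sprintf(
        "beta values must lie in [0,1]; first offending cell: feature '%s', sample '%s' (value %g), %d offending cell(s) in total",
        rownames(v)[rc[1L]], colnames(v)[rc[2L]], v[bad[1L]], length(bad)
      ))
    }
  }
  if (object@kind == "M" && any(!is.finite(v) & !is.na(v))) {
    msgs <- c(msgs, "M values must be finite (or missing)")
  }
  if (length(msgs)) msgs else TRUE
}

#' MethylationMatrix: the pipeline's numeric carrier
#'
#' A features-by-samples numeric matrix tagged with the kind of value it
#' holds: \code{"beta"} (methylated fraction in \eqn{[0,1]}), \code{"M"}
#' (the logit2 transform of beta) or \code{"expression"}.  Row ids are probes
#' or gene symbols, column ids are samples; both must be unique.
#'
#' @slot values numeric matrix with unique row and column names.
#' @slot kind one of \code{"beta"}, \code{"M"}, \code{"expression"}.
#' @seealso [MethylationMatrix()], [betaToM()], [readMethylationMatrix()]
#' @export
setClass("MethylationMatrix",
  slots = c(values = "matrix", kind = "character"),
  validity = validMethylationMatrix
)

#' Construct a MethylationMatrix
#'
#' @param values numeric matrix (features x samples) with dimnames.
#' @param kind value kind: \code{"beta"}, \code{"M"} or \code{"expression"}.
#' @return A [MethylationMatrix-class] object.
#' @examples
#' m <- matrix(c(0.1, 0.5, 0.9, 0.2, 0.6, 0.8), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' MethylationMatrix(m, "beta")
#' @export
MethylationMatrix <- function(values, kind = c("beta", "M", "expression")) {
  kind <- match.arg(kind)
  if (is.data.frame(values)) values <- as.matrix(values)
  new("MethylationMatrix", values = values, kind = kind)
}

validCoMethylationNetwork <- function(object) {
  msgs <- character()
  se <- object@selection
  if (!all(c("gene", "neighbor", "r") %in% colnames(se))) {
    msgs <- c(msgs, "selection edges need columns gene, neighbor, r")
  } else {
    if (any(se$gene == se$neighbor)) msgs <- c(msgs, "self-loops are not allowed")
    perGene <- table(se$gene)
    if (length(perGene) && max(perGene) > object@k) {
      msgs <- c(msgs, "a gene may select at most k neighbors")
    }
  }
  if (length(msgs)) msgs else TRUE
}

#' CoMethylationNetwork: rank-based gene graph
#'
#' Holds both views of a top-k co-methylation network: the directed
#' \emph{selection} edges (each gene points to its k most correlated
#' partners; this is the edge convention in which network sizes are
#' reported) and the deduplicated simple undirected graph used by all
#' downstream algorithms.
#'
#' @slot selection data.frame with columns \code{gene}, \code{neighbor},
#'   \code{r} (signed Pearson correlation of the selected pair).
#' @slot graph simple undirected \pkg{igraph} graph over all genes.
#' @slot k neighbor count used during construction.
#' @seealso [buildComethylationNetwork()]
#' @export
setClass("CoMethylationNetwork",
  slots = c(selection = "data.frame", graph = "ANY", k = "integer"),
  validity = validCoMethylationNetwork
)

#' GeneModule: a dense gene cluster
#'
#' @slot id module identifier.
#' @slot genes member gene ids.
#' @slot seed the seed gene the module was grown from.
#' @slot score MCODE score: density of the module subgraph times its size.
#' @slot coreK highest k-core number of the module subgraph.
#' @seealso [findModules()]
#' @export
setClass("GeneModule",
  slots = c(
    id = "character", genes = "character", seed = "character",
    score = "numeric", coreK = "integer"
  ),
  validity = function(object) {
    if (anyDuplicated(object@genes)) "duplicate genes in module" else TRUE
  }
)

validModuleNetwork <- function(object) {
  msgs <- character()
  ed <- object@edges
  need <- c("moduleA", "moduleB", "crossEdges", "pValue")
  if (!all(need %in% colnames(ed))) {
    msgs <- c(msgs, paste("edges need columns", paste(need, collapse = ", ")))
  } else if (nrow(ed)) {
    if (any(ed$moduleA == ed$moduleB)) {
      msgs <- c(msgs, "edges must join distinct modules")
    }
    if (any(ed$pValue <= 0 | ed$pValue > 1)) {
      msgs <- c(msgs, "p-values must lie in (0, 1]")
    }
    if (any(ed$pValue >= object@alpha)) {
      msgs <- c(msgs, "retained edges must have p < alpha")
    }
  }
  if (length(msgs)) msgs else TRUE
}

#' ModuleNetwork: permutation-tested module cross-talk graph
#'
#' Nodes are gene modules; an edge joins two modules whose number of
#' connecting edges in the gene-level co-methylation graph exceeds the
#' permutation null at the chosen significance level.
#'
#' @slot nodes ids of all modules (including isolated ones).
#' @slot edges data.frame of retained edges: \code{moduleA}, \code{moduleB},
#'   \code{crossEdges} (observed cross-edge count), \code{pValue}.
#' @slot allPairs data.frame with one row per tested module pair (same
#'   columns as \code{edges}), kept for reporting.
#' @slot alpha significance level applied to the permutation p-values.
#' @seealso [buildModuleNetwork()], [kshellDecomposition()]
#' @export
setClass("ModuleNetwork",
  slots = c(
    nodes = "character", edges = "data.frame",
    allPairs = "data.frame", alpha = "numeric"
  ),
  validity = validModuleNetwork
)

#' PowerLawFit: log-log degree distribution fit
#'
#' @slot exponent slope of the least-squares line of log10 frequency on
#'   log10 degree (negative for heavy-tailed networks).
#' @slot correlation Pearson correlation of the two log vectors.
#' @slot rSquare squared correlation (coefficient of determination of the
#'   simple linear fit).
#' @seealso [degreePowerlawFit()]
#' @export
setClass("PowerLawFit",
  slots = c(exponent = "numeric", correlation = "numeric", rSquare = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (abs(object@correlation) > 1 + 1e-8) msgs <- c(msgs, "correlation outside [-1,1]")
    if (object@rSquare < -1e-8 || object@rSquare > 1 + 1e-8) msgs <- c(msgs, "rSquare outside [0,1]")
    if (length(msgs)) msgs else TRUE
  }
)

#' ShellAssignment: K-shell indices of a module network
#'
#' @slot shell named integer vector, shell index per module (0 for isolated
#'   modules).
#' @slot core ids of the modules in the maximal shell.
#' @seealso [kshellDecomposition()], [coreModules()]
#' @export
setClass("ShellAssignment",
  slots = c(shell = "integer", core = "character"),
  validity = function(object) {
    if (any(object@shell < 0)) "shell indices must be >= 0" else TRUE
  }
)

#' RiskModel: signed module contributions to the prognosis risk score
#'
#' Each core module enters the GGI-style risk score with the sign of its
#' univariate Cox coefficient: risk = sum of positive-sign module statistics
#' minus sum of negative-sign module statistics.
#'
#' @slot coefficients named numeric vector of fitted per-module Cox
#'   coefficients.
#' @slot positive module ids with positive coefficient (the x_i terms).
#' @slot negative module ids with negative coefficient (the y_j terms).
#' @seealso [fitRiskModel()], [riskScores()]
#' @export
setClass("RiskModel",
  slots = c(coefficients = "numeric", positive = "character", negative = "character"),
  validity = function(object) {
    if (length(intersect(object@positive, object@negative))) {
      "a module cannot carry both signs"
    } else {
      TRUE
    }
  }
)

#' SurvivalComparison: grouped survival analysis result
#'
#' @slot groups named character vector, group label per sample.
#' @slot logrankStat log-rank chi-square statistic.
#' @slot logrankP log-rank p-value.
#' @slot hazardRatio hazard ratio of the comparison group versus the
#'   reference (from a Cox fit on the group indicator); \code{NA} for >2
#'   groups.
#' @slot coxP Wald p-value of a univariate Cox fit on the underlying
#'   continuous value, when one exists (\code{NA} otherwise).
#' @slot km data.frame of Kaplan-Meier curve points: \code{group},
#'   \code{time}, \code{survival}.
#' @seealso [splitAndCompare()], [geneMedianSplitSurvival()]
#' @export
setClass("SurvivalComparison",
  slots = c(
    groups = "character", logrankStat = "numeric", logrankP = "numeric",
    hazardRatio = "numeric", coxP = "numeric", km = "data.frame"
  )
)

#' StabilityResult: prognostic stability comparison of two data types
#'
#' @slot pValues replicate-by-datatype matrix of hypergeometric overlap
#'   p-values.
#' @slot indicators the stability indicators, \code{-log10(pValues)}.
#' @slot mwwP two-sided Mann-Whitney-Wilcoxon p-value comparing the two
#'   indicator columns.
#' @seealso [stabilityComparison()]
#' @export
setClass("StabilityResult",
  slots = c(pValues = "matrix", indicators = "matrix", mwwP = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (ncol(object@pValues) != 2L) msgs <- c(msgs, "pValues must have two columns")
    if (any(object@pValues <= 0 | object@pValues > 1)) {
      msgs <- c(msgs, "p-values must lie in (0, 1]")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' TypingResult: K-means molecular typing over a range of k
#'
#' @slot labelsByK list (named by k) of per-sample integer cluster labels.
#' @slot silhouetteByK named numeric vector of mean silhouette coefficients.
#' @slot selectedK the k with the highest mean silhouette (ties go to the
#'   smaller k).
#' @slot clusterSizes per-cluster sample counts at the selected k.
#' @seealso [kmeansTyping()], [silhouetteMean()]
#' @export
setClass("TypingResult",
  slots = c(
    labelsByK = "list", silhouetteByK = "numeric",
    selectedK = "integer", clusterSizes = "integer"
  ),
  validity = function(object) {
    s <- object@silhouetteByK
    if (length(s) && any(s < -1 - 1e-8 | s > 1 + 1e-8)) {
      "mean silhouettes must lie in [-1, 1]"
    } else {
      TRUE
    }
  }
)

validCohortSpec <- function(object) {
  msgs <- character()
  if (object@nGenes < 1L || object@nSamples < 2L) {
    msgs <- c(msgs, "need at least 1 gene and 2 samples")
  }
  sizes <- object@moduleSizes
  loadings <- object@moduleLoadings
  if (length(sizes) != length(loadings)) {
    msgs <- c(msgs, "one loading per module is required")
  }
  if (any(sizes < 1L)) msgs <- c(msgs, "module sizes must be >= 1")
  if (sum(sizes) > object@nGenes) {
    msgs <- c(msgs, "module sizes exceed the gene count")
  }
  if (length(loadings) && any(loadings <= 0 | loadings > 1)) {
    msgs <- c(msgs, "loadings must lie in (0, 1]")
  }
  ct <- object@crossTalk
  if (nrow(ct)) {
    if (!all(c("moduleA", "moduleB", "rho") %in% colnames(ct))) {
      msgs <- c(msgs, "crossTalk needs columns moduleA, moduleB, rho")
    } else {
      if (any(ct$rho < -1 | ct$rho > 1)) msgs <- c(msgs, "rho must lie in [-1, 1]")
      idx <- c(ct$moduleA, ct$moduleB)
      if (any(idx < 1 | idx > length(sizes))) {
        msgs <- c(msgs, "crossTalk refers to unknown modules")
      }
      if (anyDuplicated(idx)) {
        msgs <- c(msgs, "each module may take part in at most one cross-talk pair")
      }
    }
  }
  if (length(object@hazardWeights) != length(sizes)) {
    msgs <- c(msgs, "one hazard weight per module is required")
  }
  if (object@censoringRate < 0 || object@censoringRate >= 1) {
    msgs <- c(msgs, "censoringRate must lie in [0, 1)")
  }
  if (object@noiseSD <= 0 || object@backgroundSD <= 0) {
    msgs <- c(msgs, "noise standard deviations must be positive")
  }
  if (object@bridgeFraction < 0 || object@bridgeFraction > 1) {
    msgs <- c(msgs, "bridgeFraction must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
}

#' CohortSpec: parameters of a synthetic methylation cohort
#'
#' Describes a factor-model cohort: each planted module is driven by one
#' standard-normal latent factor per sample; a module gene's M value is its
#' baseline plus loading times the factor plus Gaussian noise; background
#' genes are independent noise. Cross-talk pairs correlate the two module
#' factors and additionally turn a fraction of each module's genes into
#' bridge genes with mixed loadings (see [generateCohort()]).  Survival
#' times follow an exponential proportional-hazards model whose linear
#' predictor is the weighted sum of the module factors, with independent
#' uniform censoring calibrated to the requested censoring fraction.
#'
#' @slot nGenes,nSamples cohort dimensions.
#' @slot moduleSizes,moduleLoadings planted module sizes and factor loadings.
#' @slot crossTalk data.frame (\code{moduleA}, \code{moduleB}, \code{rho}).
#' @slot noiseSD residual SD of module genes on the M scale.
#' @slot backgroundSD SD of background genes on the M scale.
#' @slot hazardWeights per-module contribution to the log hazard.
#' @slot baselineHazard exponential baseline hazard (events per day).
#' @slot censoringRate target fraction of censored samples.
#' @slot expressionCoupling slope of the repression of expression by
#'   promoter methylation (expression = -coupling * M + noise).
#' @slot bridgeFraction fraction of each cross-talk module's genes converted
#'   to bridge genes.
#' @slot bridgeMix weight of the partner factor in a bridge gene's latent.
#' @slot seed integer seed making the cohort reproducible.
#' @seealso [cohortSpec()], [generateCohort()], [generateProbeLevel()]
#' @export
setClass("CohortSpec",
  slots = c(
    nGenes = "integer", nSamples = "integer",
    moduleSizes = "integer", moduleLoadings = "numeric",
    crossTalk = "data.frame",
    noiseSD = "numeric", backgroundSD = "numeric",
    hazardWeights = "numeric", baselineHazard = "numeric",
    censoringRate = "numeric", expressionCoupling = "numeric",
    bridgeFraction = "numeric", bridgeMix = "numeric",
    seed = "integer"
  ),
  validity = validCohortSpec
)
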