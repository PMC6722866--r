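#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("methValues", "MethylationMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("valueKind", "MethylationMatrix", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("featureNames", "MethylationMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("sampleNames", "MethylationMatrix", function(x) colnames(x@values))

#' @describeIn MethylationMatrix dimensions (features, samples).
#' @param x a \code{MethylationMatrix}.
#' @export
setMethod("dim", "MethylationMatrix", function(x) dim(x@values))

#' @describeIn MethylationMatrix subset features/samples, keeping the kind tag.
#' @param i,j feature and sample indices.
#' @param drop ignored; the result is always a \code{MethylationMatrix}.
#' @param ... unused.
#' @export
setMethod("[", "MethylationMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values[i, j, drop = FALSE]
  new("MethylationMatrix", values = v, kind = x@kind)
})

setMethod("show", "MethylationMatrix", function(object) {
  cat(sprintf(
    "MethylationMatrix: %d features x %d samples (%s values)\n",
    nrow(object@values), ncol(object@values), object@kind
  ))
  if (nrow(object@values)) {
    cat("  features: ", fewIds(rownames(object@values), 4L), "\n", sep = "")
  }
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("selectionEdges", "CoMethylationNetwork", function(x) x@selection)

#' @rdname accessors
#' @export
setMethod("simpleGraph", "CoMethylationNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setMethod("nodeCount", "CoMethylationNetwork", function(x) {
  as.integer(igraph::vcount(x@graph))
})

#' @rdname accessors
#' @export
setMethod("selectionEdgeCount", "CoMethylationNetwork", function(x) {
  nrow(x@selection)
})

setMethod("show", "CoMethylationNetwork", function(object) {
  cat(sprintf(
    "CoMethylationNetwork: %d genes, %d selection edges (k = %d), %d simple edges\n",
    igraph::vcount(object@graph), nrow(object@selection), object@k,
    igraph::ecount(object@graph)
  ))
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("moduleGenes", "GeneModule", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("moduleScore", "GeneModule", function(x) x@score)

setMethod("show", "GeneModule", function(object) {
  cat(sprintf(
    "GeneModule %s: %d genes, score %.3f (seed %s, core k = %d)\n",
    object@id, length(object@genes), object@score, object@seed, object@coreK
  ))
  invisible(NULL)
})

setMethod("show", "ModuleNetwork", function(object) {
  cat(sprintf(
    "ModuleNetwork: %d modules, %d significant edges (alpha = %g)\n",
    length(object@nodes), nrow(object@edges), object@alpha
  ))
  invisible(NULL)
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf(
    "PowerLawFit: exponent %.3f, correlation %.3f, R-square %.3f\n",
    object@exponent, object@correlation, object@rSquare
  ))
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("shellIndices", "ShellAssignment", function(x) x@shell)

#' @rdname accessors
#' @export
setMethod("coreModuleIds", "ShellAssignment", function(x) x@core)

setMethod("show", "ShellAssignment", function(object) {
  cat(sprintf(
    "ShellAssignment: %d modules, max shell %d, core of %d module(s)\n",
    length(object@shell), if (length(object@shell)) max(object@shell) else 0L,
    length(object@core)
  ))
  invisible(NULL)
})

setMethod("show", "RiskModel", function(object) {
  cat(sprintf(
    "RiskModel: %d positive-sign, %d negative-sign module(s)\n",
    length(object@positive), length(object@negative)
  ))
  invisible(NULL)
})

setMethod("show", "SurvivalComparison", function(object) {
  cat(sprintf(
    "SurvivalComparison: %d samples in %d groups; log-rank p = %.3g%s\n",
    length(object@groups), length(unique(object@groups)), object@logrankP,
    if (!is.na(object@hazardRatio)) sprintf(", HR = %.3g", object@hazardRatio) else ""
  ))
  invisible(NULL)
})

setMethod("show", "StabilityResult", function(object) {
  cat(sprintf(
    "StabilityResult: %d replicates; median indicators %s; MWW p = %.3g\n",
    nrow(object@pValues),
    paste(sprintf("%s = %.2f", colnames(object@indicators),
                  apply(object@indicators, 2, stats::median)), collapse = ", "),
    object@mwwP
  ))
  invisible(NULL)
})

setMethod("show", "TypingResult", function(object) {
  cat(sprintf(
    "TypingResult: selected k = %d (mean silhouette %.3f); cluster sizes: %s\n",
    object@selectedK,
    object@silhouetteByK[as.character(object@selectedK)],
    paste(object@clusterSizes, collapse = "/")
  ))
  invisible(NULL)
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d genes x %d samples, %d planted module(s), %d cross-talk pair(s), seed %d\n",
    object@nGenes, object@nSamples, length(object@moduleSizes),
    nrow(object@crossTalk), object@seed
  ))
  invisible(NULL)
})
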