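#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' \code{methValues} returns the numeric matrix held by a
#' [MethylationMatrix-class]; \code{valueKind} its value-kind tag;
#' \code{featureNames} and \code{sampleNames} its dimnames.
#' \code{selectionEdges}, \code{simpleGraph}, \code{nodeCount} and
#' \code{selectionEdgeCount} expose the two views of a
#' [CoMethylationNetwork-class].  \code{moduleGenes} and \code{moduleScore}
#' access a [GeneModule-class]; \code{shellIndices} and
#' \code{coreModuleIds} a [ShellAssignment-class].
#'
#' @param x an object of the documented class.
#' @return The slot contents described above.
#' @name accessors
#' @aliases methValues valueKind featureNames sampleNames selectionEdges
#'   simpleGraph nodeCount selectionEdgeCount moduleGenes moduleScore
#'   shellIndices coreModuleIds
#' @examples
#' m <- MethylationMatrix(matrix(runif(6), 3, 2,
#'   dimnames = list(paste0("g", 1:3), c("s1", "s2"))), "beta")
#' valueKind(m)
#' featureNames(m)
NULL

#' @rdname accessors
#' @export
setGeneric("methValues", function(x) standardGeneric("methValues"))

#' @rdname accessors
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname accessors
#' @export
setGeneric("selectionEdges", function(x) standardGeneric("selectionEdges"))

#' @rdname accessors
#' @export
setGeneric("simpleGraph", function(x) standardGeneric("simpleGraph"))

#' @rdname accessors
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname accessors
#' @export
setGeneric("selectionEdgeCount", function(x) standardGeneric("selectionEdgeCount"))

#' @rdname accessors
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))

#' @rdname accessors
#' @export
setGeneric("moduleScore", function(x) standardGeneric("moduleScore"))

#' @rdname accessors
#' @export
setGeneric("shellIndices", function(x) standardGeneric("shellIndices"))

#' @rdname accessors
#' @export
setGeneric("coreModuleIds", function(x) standardGeneric("coreModuleIds"))
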