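#' K-shell decomposition of a module network
#'
#' Standard k-shell pruning: iteratively remove nodes of degree <= s
#' (repeating until stable) for s = 1, 2, ...; a node's shell index is the
#' s at which it is removed.  Isolated nodes sit in shell 0.  The modules
#' of the maximal shell form the network core.
#'
#' @param net a [ModuleNetwork-class] or an \pkg{igraph} graph.
#' @return A [ShellAssignment-class].  If the network has no edges at all,
#'   the core is empty and a warning is raised.
#' @examples
#' g <- igraph::make_star(6, mode = "undirected") # star: all nodes shell 1
#' igraph::V(g)$name <- letters[1:6]
#' shellIndices(kshellDecomposition(g))
#' @export
kshellDecomposition <- function(net) {
  g <- if (is(net, "ModuleNetwork")) moduleNetworkGraph(net) else net
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0L) stop("network is empty")
  nms <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  shell <- stats::setNames(as.integer(igraph::coreness(g)), nms)
  maxShell <- max(shell)
  if (maxShell == 0L) {
    warning("all modules are isolated: the core set is empty")
    core <- character()
  } else {
    core <- sort(nms[shell == maxShell])
  }
  new("ShellAssignment", shell = shell, core = core)
}

#' Extract the core gene modules
#'
#' Applies [kshellDecomposition()] to the module network and returns the
#' modules lying in the maximal shell, together with their gene sets.
#'
#' @param net a [ModuleNetwork-class].
#' @param mods the list of [GeneModule-class] objects the network was built
#'   from.
#' @return List of the core [GeneModule-class]s.  The shell assignment is
#'   attached as \code{attr(, "shells")}; the module count and the size of
#'   the union of their gene sets are logged.
#' @export
coreModules <- function(net, mods) {
  sets <- moduleGeneSets(mods)
  shells <- kshellDecomposition(net)
  missing <- setdiff(coreModuleIds(shells), names(sets))
  if (length(missing)) {
    stop("module(s) absent from the module list: ", fewIds(missing))
  }
  core <- mods[match(coreModuleIds(shells), names(sets))]
  genes <- unique(unlist(lapply(core, moduleGenes)))
  stageLog("core", sprintf(
    "%d core module(s) in shell %d, %d genes in total",
    length(core), if (length(shells@shell)) max(shells@shell) else 0L,
    length(genes)
  ))
  attr(core, "shells") <- shells
  core
}
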