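fullPrecision <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Read a methylation / expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds unique feature ids
#' and whose first row holds unique sample ids.  Beta matrices are validated
#' to \eqn{[0,1]}; missing cells are preserved as \code{NA}.
#'
#' @param path file path.
#' @param kind value kind: \code{"beta"}, \code{"M"} or \code{"expression"}.
#' @return A [MethylationMatrix-class].
#' @seealso [writeMethylationMatrix()]
#' @export
readMethylationMatrix <- function(path, kind = c("beta", "M", "expression")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path,
    sep = "\t", header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, quote = "", comment.char = ""
  )
  if (ncol(df) < 2L) stop("matrix file needs an id column and at least one sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature ids: ", fewIds(unique(ids[duplicated(ids)])))
  }
  samples <- colnames(df)[-1L] # before subsetting, which uniquifies names
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ", fewIds(unique(samples[duplicated(samples)])))
  }
  v <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(v) <- "double"
  dimnames(v) <- list(ids, samples)
  MethylationMatrix(v, kind)
}

#' Write a methylation / expression matrix to TSV
#'
#' Values are written at full double precision so that
#' \code{readMethylationMatrix(writeMethylationMatrix(m, f))} is an exact
#' round trip.
#'
#' @param m a [MethylationMatrix-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMethylationMatrix <- function(m, path) {
  stopifnot(is(m, "MethylationMatrix"))
  v <- methValues(m)
  chr <- matrix(fullPrecision(v), nrow = nrow(v), dimnames = dimnames(v))
  df <- data.frame(id = rownames(v), chr, check.names = FALSE)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(path)
}

#' Read a probe annotation table
#'
#' Reads a tab-separated annotation with one row per probe.  The canonical
#' column names are \code{probe}, \code{chromosome}, \code{gene},
#' \code{region}, \code{snp}, \code{crossReactive}; \code{columnMap} maps
#' them onto another dialect (e.g. the Illumina 450K manifest's
#' \code{IlmnID}/\code{CHR}/\code{UCSC_RefGene_Name}/\code{UCSC_RefGene_Group}
#' headers).
#'
#' @param path file path.
#' @param columnMap optional named character vector mapping canonical names
#'   to the file's column names, e.g.
#'   \code{c(probe = "IlmnID", chromosome = "CHR", ...)}.
#' @return A validated data.frame with canonical columns; chromosome labels
#'   are normalized to \code{chr*} form and flags to logical.
#' @export
readProbeAnnotation <- function(path, columnMap = NULL) {
  df <- utils::read.table(path,
    sep = "\t", header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, quote = "", comment.char = ""
  )
  if (!is.null(columnMap)) {
    for (canon in names(columnMap)) {
      src <- columnMap[[canon]]
      if (!src %in% colnames(df)) {
        stop("column '", src, "' (mapped to '", canon, "') not found in ", path)
      }
      df[[canon]] <- df[[src]]
    }
  }
  checkProbeAnnotation(df)
}

#' Read a clinical (survival) table
#'
#' Expects tab-separated columns \code{sample}, \code{time} (days, > 0) and
#' \code{status} (1 = death observed, 0 = censored).
#'
#' @param path file path.
#' @return A validated data.frame with those three columns.
#' @export
readClinicalTable <- function(path) {
  df <- utils::read.table(path,
    sep = "\t", header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, quote = "", comment.char = ""
  )
  checkClinicalTable(df)
}

# shared validation for clinical data.frames
checkClinicalTable <- function(df) {
  need <- c("sample", "time", "status")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("clinical table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample ids: ", fewIds(unique(df$sample[duplicated(df$sample)])))
  }
  if (any(!is.finite(df$time) | df$time <= 0)) {
    stop("survival times must be positive")
  }
  if (!all(df$status %in% c(0, 1))) stop("event status must be 0/1")
  df$status <- as.integer(df$status)
  df[, need]
}

#' Write a network to disk
#'
#' Writes either view of a [CoMethylationNetwork-class] or a
#' [ModuleNetwork-class] as an edge list (\code{source}, \code{target},
#' \code{weight}, plus \code{pValue} for module networks) or as GraphML.
#' An empty network produces a header-only file with a warning.
#'
#' @param net a \code{CoMethylationNetwork} or \code{ModuleNetwork}.
#' @param path output file path.
#' @param format \code{"tsv"} (edge list) or \code{"graphml"}.
#' @param view for co-methylation networks, \code{"simple"} (deduplicated
#'   undirected graph; weight is the correlation) or \code{"selection"}
#'   (the directed top-k selection edges).
#' @return \code{path}, invisibly.
#' @seealso [readEdgeList()]
#' @export
writeNetwork <- function(net, path, format = c("tsv", "graphml"),
                         view = c("simple", "selection")) {
  format <- match.arg(format)
  view <- match.arg(view)
  if (is(net, "CoMethylationNetwork")) {
    if (view == "selection") {
      ed <- data.frame(
        source = net@selection$gene, target = net@selection$neighbor,
        weight = net@selection$r, stringsAsFactors = FALSE
      )
      g <- igraph::graph_from_data_frame(ed, directed = TRUE)
    } else {
      g <- simpleGraph(net)
      el <- igraph::as_edgelist(g)
      ed <- data.frame(
        source = el[, 1L], target = el[, 2L],
        weight = igraph::E(g)$weight, stringsAsFactors = FALSE
      )
    }
  } else if (is(net, "ModuleNetwork")) {
    ed <- data.frame(
      source = net@edges$moduleA, target = net@edges$moduleB,
      weight = net@edges$crossEdges, pValue = net@edges$pValue,
      stringsAsFactors = FALSE
    )
    g <- igraph::graph_from_data_frame(ed,
      directed = FALSE,
      vertices = data.frame(name = net@nodes)
    )
  } else {
    stop("unsupported network object of class ", class(net)[1L])
  }
  if (!nrow(ed)) warning("writing an empty network: ", path)
  if (format == "tsv") {
    num <- vapply(ed, is.numeric, logical(1L))
    ed[num] <- lapply(ed[num], fullPrecision)
    utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge-list TSV as an undirected simple graph
#'
#' @param path file written by [writeNetwork()] (or any TSV with
#'   \code{source} and \code{target} columns; \code{weight}/\code{pValue}
#'   columns become edge attributes).
#' @return An undirected simple \pkg{igraph} graph.
#' @export
readEdgeList <- function(path) {
  df <- utils::read.table(path,
    sep = "\t", header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, quote = "", comment.char = ""
  )
  if (!all(c("source", "target") %in% colnames(df))) {
    stop("edge list needs 'source' and 'target' columns")
  }
  if (!nrow(df)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  igraph::simplify(igraph::graph_from_data_frame(df, directed = FALSE),
    edge.attr.comb = "first"
  )
}

#' Write / read module membership tables
#'
#' Modules are stored as a two-column TSV of (module id, gene).
#'
#' @param modules list of [GeneModule-class] objects.
#' @param path file path.
#' @return \code{writeModuleTable} returns \code{path} invisibly;
#'   \code{readModuleTable} returns a list of \code{GeneModule}s (scores and
#'   seeds are not stored in the table and come back as \code{NA}).
#' @export
writeModuleTable <- function(modules, path) {
  df <- do.call(rbind, lapply(modules, function(mod) {
    data.frame(module = mod@id, gene = mod@genes, stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- data.frame(module = character(), gene = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeModuleTable
#' @export
readModuleTable <- function(path) {
  df <- utils::read.table(path,
    sep = "\t", header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, quote = "", comment.char = ""
  )
  if (!all(c("module", "gene") %in% colnames(df))) {
    stop("module table needs 'module' and 'gene' columns")
  }
  ids <- unique(df$module)
  lapply(ids, function(id) {
    new("GeneModule",
      id = as.character(id), genes = df$gene[df$module == id],
      seed = NA_character_, score = NA_real_, coreK = NA_integer_
    )
  })
}

pipelineConfigDefaults <- function() {
  list(
    beta = NULL, annotation = NULL, clinical = NULL, expression = NULL,
    promoterClasses = promoterRegionClasses,
    epsilon = 1e-6,
    neighborCount = 4L,
    nodeScoreCutoff = 0.2, degreeCutoff = 2L, haircut = TRUE, fluff = FALSE,
    moduleSizeFloor = 5L,
    permutations = 1000L, alpha = 0.05,
    kRange = 2:8, restarts = 50L,
    replicates = 100L,
    seed = 1L
  )
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills in defaults, rejects unknown keys and
#' validates every numeric parameter (neighbor count >= 1, alpha in (0,1),
#' permutations >= 1, integer seed, ...).
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @param overrides named list of values overriding the file (used by the
#'   command-line interface to let flags win over the config).
#' @return A named list of validated parameters.
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  cfg <- pipelineConfigDefaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(user)) stop("config must be a YAML mapping")
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(cfg, user)

  checkInt <- function(x, nm, lower) {
    if (!is.numeric(x) || length(x) != 1L || x != round(x) || x < lower) {
      stop("config key '", nm, "' must be an integer >= ", lower)
    }
    as.integer(x)
  }
  cfg$neighborCount <- checkInt(cfg$neighborCount, "neighborCount", 1L)
  cfg$permutations <- checkInt(cfg$permutations, "permutations", 1L)
  cfg$moduleSizeFloor <- checkInt(cfg$moduleSizeFloor, "moduleSizeFloor", 1L)
  cfg$degreeCutoff <- checkInt(cfg$degreeCutoff, "degreeCutoff", 0L)
  cfg$replicates <- checkInt(cfg$replicates, "replicates", 1L)
  cfg$restarts <- checkInt(cfg$restarts, "restarts", 1L)
  cfg$seed <- checkInt(cfg$seed, "seed", -.Machine$integer.max)
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("config key 'alpha' must lie in (0, 1)")
  }
  if (!is.numeric(cfg$epsilon) || cfg$epsilon <= 0 || cfg$epsilon >= 0.5) {
    stop("config key 'epsilon' must lie in (0, 0.5)")
  }
  if (!is.numeric(cfg$kRange) || any(cfg$kRange != round(cfg$kRange)) ||
        any(cfg$kRange < 2L)) {
    stop("config key 'kRange' must be integers >= 2")
  }
  cfg$kRange <- sort(unique(as.integer(cfg$kRange)))
  if (!is.logical(cfg$haircut) || !is.logical(cfg$fluff)) {
    stop("config keys 'haircut' and 'fluff' must be true/false")
  }
  cfg
}
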