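#' Promoter-associated 450K annotation categories
#'
#' Default set of region classes counted as "promoter" when restricting
#' probes: TSS200, TSS1500, 5'UTR and 1stExon.
#' @export
promoterRegionClasses <- c("TSS200", "TSS1500", "5'UTR", "1stExon")

chromosomeVocabulary <- c(
  paste0("chr", c(1:22, "X", "Y")), c(1:22, "X", "Y")
)

normalizeChromosome <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

# Validate a probe annotation data.frame; returns it with normalized types.
checkProbeAnnotation <- function(a) {
  need <- c("probe", "chromosome", "gene", "region", "snp", "crossReactive")
  miss <- setdiff(need, colnames(a))
  if (length(miss)) {
    stop("probe annotation is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(a$probe)) {
    stop(
      "duplicate probe ids in annotation: ",
      fewIds(unique(a$probe[duplicated(a$probe)]))
    )
  }
  bad <- !a$chromosome %in% chromosomeVocabulary
  if (any(bad)) {
    stop(
      "chromosome labels outside the declared vocabulary: ",
      fewIds(unique(a$chromosome[bad]))
    )
  }
  a$chromosome <- normalizeChromosome(a$chromosome)
  for (fl in c("snp", "crossReactive")) {
    v <- a[[fl]]
    if (is.logical(v)) next
    if (is.numeric(v) && all(v %in% c(0, 1))) {
      a[[fl]] <- as.logical(v)
    } else if (is.character(v) && all(toupper(v) %in% c("TRUE", "FALSE", "0", "1"))) {
      a[[fl]] <- toupper(v) %in% c("TRUE", "1")
    } else {
      stop("annotation column '", fl, "' must be boolean")
    }
  }
  a$gene <- as.character(a$gene)
  a$gene[is.na(a$gene)] <- ""
  a
}

#' Filter probes of a 450K-style methylation matrix
#'
#' Applies the standard probe-level exclusions, in a fixed order so that the
#' per-criterion removal counts are reproducible: (1) probes with a missing
#' beta value in any sample; (2) probes on the X or Y chromosome; (3)
#' SNP-affected probes; (4) cross-reactive probes; (5) probes outside the
#' promoter region classes. A probe matching several criteria is counted
#' once, under the first criterion that catches it.
#'
#' @param m probe-level [MethylationMatrix-class] (beta values).
#' @param annotation probe annotation data.frame with columns \code{probe},
#'   \code{chromosome}, \code{gene}, \code{region}, \code{snp},
#'   \code{crossReactive} (see [readProbeAnnotation()]).
#' @param promoterClasses region classes counted as promoter-associated.
#' @return The filtered \code{MethylationMatrix}; the per-criterion removal
#'   counts are attached as \code{attr(, "removalCounts")} and logged.
#' @examples
#' b <- matrix(runif(4), 2, 2, dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' ann <- data.frame(
#'   probe = c("cg1", "cg2"), chromosome = c("chr1", "chrX"),
#'   gene = c("G1", "G2"), region = "TSS200",
#'   snp = FALSE, crossReactive = FALSE
#' )
#' filterProbes(MethylationMatrix(b, "beta"), ann)
#' @export
filterProbes <- function(m, annotation, promoterClasses = promoterRegionClasses) {
  stopifnot(is(m, "MethylationMatrix"))
  a <- checkProbeAnnotation(annotation)
  v <- methValues(m)
  missing <- setdiff(rownames(v), a$probe)
  if (length(missing)) {
    stop("probes absent from the annotation: ", fewIds(missing))
  }
  a <- a[match(rownames(v), a$probe), , drop = FALSE]

  keep <- rep(TRUE, nrow(v))
  counts <- integer(5)
  names(counts) <- c("missingBeta", "sexChromosome", "snpAffected",
                     "crossReactive", "nonPromoter")
  crit <- list(
    missingBeta   = apply(is.na(v), 1L, any),
    sexChromosome = a$chromosome %in% c("chrX", "chrY"),
    snpAffected   = a$snp,
    crossReactive = a$crossReactive,
    nonPromoter   = !a$region %in% promoterClasses
  )
  for (nm in names(crit)) {
    hit <- keep & crit[[nm]]
    counts[nm] <- sum(hit)
    keep <- keep & !hit
  }
  stageLog("preprocess", sprintf(
    "probe filter: %d -> %d probes (removed %s)",
    nrow(v), sum(keep),
    paste(sprintf("%s %d", names(counts), counts), collapse = ", ")
  ))
  out <- new("MethylationMatrix", values = v[keep, , drop = FALSE], kind = m@kind)
  attr(out, "removalCounts") <- counts
  out
}

#' Collapse a probe-level matrix to gene level
#'
#' Averages the beta values of all probes annotated to the same gene symbol,
#' per sample, on the beta scale (averaging precedes any M transformation).
#' Probes without a gene symbol are dropped with a warning.
#'
#' @param m probe-level [MethylationMatrix-class].
#' @param annotation probe annotation (see [filterProbes()]).
#' @return Gene-level \code{MethylationMatrix} with one row per gene symbol;
#'   columns are unchanged.
#' @examples
#' b <- matrix(c(0.2, 0.4), 2, 1, dimnames = list(c("cg1", "cg2"), "s1"))
#' ann <- data.frame(
#'   probe = c("cg1", "cg2"), chromosome = "chr1", gene = "G1",
#'   region = "TSS200", snp = FALSE, crossReactive = FALSE
#' )
#' methValues(collapseToGenes(MethylationMatrix(b, "beta"), ann)) # 0.3
#' @export
collapseToGenes <- function(m, annotation) {
  stopifnot(is(m, "MethylationMatrix"))
  a <- checkProbeAnnotation(annotation)
  v <- methValues(m)
  missing <- setdiff(rownames(v), a$probe)
  if (length(missing)) {
    stop("probes absent from the annotation: ", fewIds(missing))
  }
  gene <- a$gene[match(rownames(v), a$probe)]
  empty <- !nzchar(gene)
  if (any(empty)) {
    warning(
      sum(empty), " probe(s) without a gene symbol dropped: ",
      fewIds(rownames(v)[empty])
    )
    v <- v[!empty, , drop = FALSE]
    gene <- gene[!empty]
  }
  if (!nrow(v)) stop("no probes with a gene symbol left to collapse")
  sums <- rowsum(v, group = gene, reorder = TRUE)
  n <- as.vector(table(gene)[rownames(sums)])
  out <- sums / n
  stageLog("preprocess", sprintf(
    "collapsed %d probes to %d genes", length(gene), nrow(out)
  ))
  new("MethylationMatrix", values = out, kind = m@kind)
}

#' Convert beta values to M values
#'
#' The variance-stabilizing logit2 transform M = log2(beta / (1 - beta)).
#' Beta values are clipped to \code{[epsilon, 1 - epsilon]} first so that M
#' stays finite at the boundaries.
#'
#' @param b a beta-value [MethylationMatrix-class] or a numeric
#'   vector/matrix of beta values in \eqn{[0,1]}.
#' @param epsilon clip bound in (0, 0.5).
#' @return Object of the same shape holding M values (kind \code{"M"} for a
#'   \code{MethylationMatrix} input).
#' @examples
#' betaToM(c(0.5, 0.8, 2 / 3)) # 0, 2, 1
#' @seealso [mToBeta()] for the exact inverse within the clip range.
#' @export
betaToM <- function(b, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 || epsilon >= 0.5) {
    stop("epsilon must lie in (0, 0.5)")
  }
  if (is(b, "MethylationMatrix")) {
    if (valueKind(b) != "beta") stop("input matrix does not hold beta values")
    v <- betaToM(methValues(b), epsilon)
    return(new("MethylationMatrix", values = v, kind = "M"))
  }
  if (any(!is.na(b) & (b < 0 | b > 1))) stop("beta values must lie in [0, 1]")
  x <- pmin(pmax(b, epsilon), 1 - epsilon)
  out <- log2(x / (1 - x))
  attributes(out) <- attributes(b)
  out
}

#' Convert M values back to beta values
#'
#' Inverse of [betaToM()]: beta = 2^M / (1 + 2^M).
#'
#' @param m an M-value [MethylationMatrix-class] or numeric vector/matrix.
#' @return Beta values of the same shape.
#' @examples
#' mToBeta(c(0, 2, 1)) # 0.5, 0.8, 2/3
#' @export
mToBeta <- function(m) {
  if (is(m, "MethylationMatrix")) {
    if (valueKind(m) != "M") stop("input matrix does not hold M values")
    v <- mToBeta(methValues(m))
    return(new("MethylationMatrix", values = v, kind = "beta"))
  }
  p <- 2^m
  out <- p / (1 + p)
  attributes(out) <- attributes(m)
  out
}
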