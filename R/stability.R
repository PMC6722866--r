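asValueMatrix <- function(m) {
  if (is(m, "MethylationMatrix")) methValues(m) else as.matrix(m)
}

# Univariate Cox Wald p-value for one covariate; NA when the gene is
# constant, the fit fails or does not converge.
univariateCoxP <- function(surv, x, returnCoef = FALSE) {
  if (stats::sd(x) == 0) {
    return(if (returnCoef) c(NA_real_, NA_real_) else NA_real_)
  }
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(surv ~ x, ties = "breslow",
                      model = FALSE, x = FALSE, y = FALSE),
      warning = function(w) {
        if (grepl("iterations|converge|infinite", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || is.na(fit$coefficients[1L])) {
    return(if (returnCoef) c(NA_real_, NA_real_) else NA_real_)
  }
  beta <- fit$coefficients[1L]
  se <- sqrt(diag(fit$var))[1L]
  p <- stats::pchisq((beta / se)^2, df = 1L, lower.tail = FALSE)
  if (returnCoef) c(beta, p) else p
}

#' Select genes prognostic for survival
#'
#' Fits, for each gene, a univariate Cox proportional-hazards regression of
#' overall survival on the gene's value (Breslow tie handling, no
#' covariates) and returns the genes whose Wald p-value falls below
#' \code{alpha}.  Constant genes are skipped with a warning and are never
#' selected; genes whose fit fails are skipped and logged.
#'
#' @param m gene-by-sample [MethylationMatrix-class] or numeric matrix.
#' @param clinical clinical data.frame with columns \code{sample},
#'   \code{time}, \code{status}; must cover the matrix samples.
#' @param alpha significance level.
#' @return Character vector of selected gene ids.  The number of genes that
#'   entered the screen is attached as \code{attr(, "universe")}.
#' @export
selectPrognosticGenes <- function(m, clinical, alpha = 0.05) {
  v <- asValueMatrix(m)
  clinical <- checkClinicalTable(clinical)
  idx <- match(colnames(v), clinical$sample)
  if (anyNA(idx)) {
    stop("samples missing from the clinical table: ",
         fewIds(colnames(v)[is.na(idx)]))
  }
  cl <- clinical[idx, ]
  if (sum(cl$status) < 2L) stop("need at least 2 observed events")
  surv <- survival::Surv(cl$time, cl$status)

  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("skipping constant gene(s): ", fewIds(rownames(v)[sds == 0]))
  }
  p <- rep(NA_real_, nrow(v))
  for (i in which(sds > 0)) {
    p[i] <- univariateCoxP(surv, v[i, ])
  }
  failed <- sds > 0 & is.na(p)
  if (any(failed)) {
    stageLog("stability", sprintf(
      "%d gene(s) skipped (Cox fit failed): %s",
      sum(failed), fewIds(rownames(v)[failed])
    ))
  }
  out <- rownames(v)[!is.na(p) & p < alpha]
  attr(out, "universe") <- nrow(v)
  out
}

#' Hypergeometric significance of a gene-set overlap
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between two gene sets drawn from a common universe:
#' P(X >= |A intersect B|) with population \code{universeSize}, success
#' states |A| and draws |B|.
#'
#' @param setA,setB character vectors of gene ids.
#' @param universeSize size of the common universe (>= both set sizes).
#' @return The p-value, in (0, 1].
#' @examples
#' overlapSignificance(letters[1:3], letters[1:3], 10) # 1/choose(10,3)
#' @export
overlapSignificance <- function(setA, setB, universeSize) {
  setA <- unique(as.character(setA))
  setB <- unique(as.character(setB))
  if (length(setA) > universeSize || length(setB) > universeSize) {
    stop("set sizes exceed the universe size")
  }
  ov <- length(intersect(setA, setB))
  stats::phyper(ov - 1L, length(setA), universeSize - length(setA),
                length(setB), lower.tail = FALSE)
}

#' Compare the prognostic stability of two data types
#'
#' The resampling procedure behind the "methylation is more stable than
#' expression" comparison: in each replicate the samples are split at
#' random into two equal halves (the same split is reused for both data
#' types), prognostic genes are selected independently in each half by
#' univariate Cox screening, and the significance of the overlap of the two
#' selections is scored by the hypergeometric test with the data type's
#' full gene count as universe.  The per-replicate stability indicator is
#' \code{-log10} of that p-value; the two indicator vectors are compared by
#' a two-sided Mann-Whitney-Wilcoxon test.
#'
#' @param m1,m2 the two gene-by-sample matrices (e.g. methylation M values
#'   and expression); must share the clinical table's samples.
#' @param clinical clinical data.frame (\code{sample}, \code{time},
#'   \code{status}).
#' @param reps number of random splits.
#' @param alpha per-gene selection level.
#' @param seed integer seed; the routine is deterministic given it.
#' @param names labels for the two data types (used in the result).
#' @return A [StabilityResult-class].
#' @export
stabilityComparison <- function(m1, m2, clinical, reps = 100L, alpha = 0.05,
                                seed = NULL,
                                names = c("data1", "data2")) {
  v1 <- asValueMatrix(m1)
  v2 <- asValueMatrix(m2)
  clinical <- checkClinicalTable(clinical)
  samples <- clinical$sample
  if (!setequal(colnames(v1), samples) || !setequal(colnames(v2), samples)) {
    stop("both matrices must share the clinical table's sample set")
  }
  v1 <- v1[, samples, drop = FALSE]
  v2 <- v2[, samples, drop = FALSE]
  n <- length(samples)
  if (n %% 2L == 1L) {
    stageLog("stability", "odd sample count: one half receives the extra sample")
  }
  if (reps < 2L) warning("fewer than 2 replicates: the MWW comparison is degenerate")

  pv <- matrix(NA_real_, nrow = reps, ncol = 2L,
               dimnames = list(NULL, names))
  localSeed(seed, {
    for (r in seq_len(reps)) {
      perm <- sample(n)
      halfA <- samples[perm[seq_len(ceiling(n / 2))]]
      halfB <- samples[perm[(ceiling(n / 2) + 1L):n]]
      for (d in 1:2) {
        v <- if (d == 1L) v1 else v2
        selA <- selectPrognosticGenes(v[, halfA, drop = FALSE], clinical, alpha)
        selB <- selectPrognosticGenes(v[, halfB, drop = FALSE], clinical, alpha)
        pv[r, d] <- overlapSignificance(selA, selB, nrow(v))
      }
    }
  })
  ind <- -log10(pv)
  mww <- if (all(ind[, 1L] == ind[, 2L])) {
    1
  } else {
    suppressWarnings(stats::wilcox.test(ind[, 1L], ind[, 2L]))$p.value
  }
  new("StabilityResult", pValues = pv, indicators = ind, mwwP = mww)
}
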