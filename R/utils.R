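#' Derive a stage-specific random seed
#'
#' Stochastic stages of the pipeline each draw their random numbers from an
#' independent substream derived from the single global seed and the stage
#' name, so that adding, removing or reordering stages does not perturb the
#' results of the others.
#'
#' @param seed integer global seed.
#' @param stage character scalar naming the stage (e.g. \code{"network"}).
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @examples
#' deriveSeed(1L, "modnet")
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed))
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps the result a valid R integer
  h <- (abs(seed) %% m)
  for (ch in utf8ToInt(stage)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. `seed = NULL` uses the current stream.
localSeed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# One-line stage log. Quiet by default inside test suites via the usual
# message() machinery; callers can suppressMessages().
stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
}

# first few offenders, for error messages
fewIds <- function(x, n = 5L) {
  x <- as.character(x)
  if (length(x) > n) {
    paste0(paste(x[seq_len(n)], collapse = ", "), ", ... (", length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}
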