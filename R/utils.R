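#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rbinom rnorm rpois runif quantile shapiro.test fisher.test
#'   chisq.test loess predict sd
NULL

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific child seed from a pipeline seed
#'
#' All stochastic stages of the pipeline draw their seed from a single
#' top-level seed through this splitting rule, so any stage can be re-run in
#' isolation and reproduce its part of a full run. The rule is a fixed linear
#' congruence on the top-level seed and a small stage index, reduced modulo
#' 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param seed Integer top-level seed.
#' @param stage Integer stage index (>= 0), or a known stage name
#'   ("population", "depths", "replicate").
#' @param rep Optional replicate number folded into the child seed.
#' @return An integer seed.
#' @export
split_seed <- function(seed, stage = 0L, rep = 0L) {
  stage_ids <- c(population = 1L, depths = 2L, replicate = 3L)
  if (is.character(stage)) {
    if (!stage %in% names(stage_ids)) {
      stop("unknown stage name: ", stage, call. = FALSE)
    }
    stage <- stage_ids[[stage]]
  }
  m <- 2147483647 # 2^31 - 1
  x <- (as.numeric(seed) %% m) * 48271 + as.numeric(stage) * 16807 +
    as.numeric(rep) * 69621 + 1
  as.integer(x %% m)
}
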