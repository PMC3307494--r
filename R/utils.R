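#' @keywords internal
"_PACKAGE"

#' @importFrom stats predict coef residuals simulate rpois rbinom plogis rgamma
#' @importFrom utils read.delim write.table head
#' @importFrom graphics plot axis abline points legend hist
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Structured non-fatal log message: clean-up never aborts a job unless a
# required set becomes empty, so recoverable problems surface as warnings.
lr_warn <- function(fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...), class = "litrank_warning"))
}

lr_stop <- function(fmt, ..., class = "litrank_error") {
  stop(errorCondition(sprintf(fmt, ...), class = class))
}
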