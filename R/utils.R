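#' @keywords internal
"_PACKAGE"

#' @useDynLib normdev, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef dnorm glm lm optim p.adjust pchisq pnorm qnorm
#'   quasibinomial rbinom rexp rnorm rpois runif sd var
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
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
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
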