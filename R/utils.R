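#' @useDynLib dsrpp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx var sd rgamma rexp runif rnorm rpois smooth.spline
#'   predict quantile lm coef median
#' @importFrom utils read.csv write.csv head tail
NULL

# Per-trial substream seeds derived from one root seed. Drawn with
# replacement so the first n seeds do not change when n_trials grows.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) {
    return(sample.int(.Machine$integer.max, n, replace = TRUE))
  }
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max, n, replace = TRUE)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
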