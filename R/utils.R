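#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor cor.test cov lm mahalanobis median optim
#'   pchisq pbinom predict pt qlogis quantile rbinom rnorm runif sd
#'   setNames t.test var binom.test dbinom
#' @importFrom utils read.table write.table
#' @importFrom tools md5sum
#' @importFrom graphics plot abline par
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a child RNG seed from a master seed and a stream label
#'
#' Every stage of the pipeline draws its randomness from an independent
#' stream whose seed is a deterministic function of the master seed and a
#' human-readable label, so that re-running any single stage reproduces its
#' output bit-for-bit regardless of what ran before it.
#'
#' @param seed master integer seed.
#' @param ... labels (character or integer) identifying the stream.
#' @return an integer in [0, 2^31 - 2] usable with [set.seed()].
#' @export
child_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## index <-> (i,j,k) helpers for 3D arrays stored column-major
vox_coords <- function(idx, dim) {
  k <- (idx - 1L) %/% (dim[1] * dim[2])
  r <- (idx - 1L) %% (dim[1] * dim[2])
  cbind(i = r %% dim[1] + 1L, j = r %/% dim[1] + 1L, k = k + 1L)
}
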