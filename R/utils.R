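#' @useDynLib hybridsi, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom var sd cor fft quantile median
#' @importFrom utils modifyList
NULL

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  x
}

check_count <- function(x, name, lower = 1L) {
  check_scalar(x, name, lower = lower)
  if (x != round(x)) stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  as.integer(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

l2sq <- function(x) sum(x * x)

l1 <- function(x) sum(abs(x))

# Deep-copy a parameter environment (used for best-snapshot bookkeeping).
copy_env <- function(e) {
  as.environment(as.list(e, all.names = TRUE))
}
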