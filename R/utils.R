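#' @useDynLib chemevol, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef lm median nls optim plogis qlogis qnorm quantile
#'   rbinom rlnorm rmultinom runif sd setNames vcov var
#' @importFrom utils read.csv write.csv packageVersion modifyList
NULL

LN2 <- log(2)

abort <- function(fmt, ..., class = "chemevol_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "chemevol_error",
                                                   "error", "condition")))
}

assert_scalar_num <- function(x, name, lower = -Inf, strict = FALSE,
                              allow_zero_len = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort("'%s' must be a single finite number", name)
  if (strict && x <= lower)
    abort("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict && x < lower)
    abort("'%s' must be >= %g (got %g)", name, lower, x)
  invisible(x)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators are pure
#' functions of their inputs and do not disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a distinct 31-bit sub-seed from (seed, index) without consuming RNG
sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 9973) %% 2147483647)
}

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)
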