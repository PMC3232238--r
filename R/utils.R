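`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# log density of the inverse-gamma(shape, rate) distribution
dinvgamma_log <- function(x, shape, rate) {
  ifelse(x > 0,
         shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x,
         -Inf)
}

rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
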