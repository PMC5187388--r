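# Internal helpers: argument checks and explicit seed handling.
#
# All stochastic functions take a `seed` argument. A non-NULL seed is applied
# locally (the caller's RNG state is restored on exit), so no function leaks
# global RNG state. Child seeds for sub-simulations are derived from the master
# seed so that independent streams never reuse draws.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE, integerish = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stopf("`%s` must be a single number, not NULL", name)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  if (integerish && abs(x - round(x)) > 1e-8)
    stopf("`%s` must be a whole number, got %s", name, x)
  invisible(NULL)
}

# Evaluate `expr` under `seed`, restoring the previous RNG state afterwards.
# seed = NULL means "use (and advance) the global RNG", R's usual behaviour.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_number(seed, "seed", integerish = TRUE)
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

# n reproducible child seeds (< 2^31) derived from one master seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max, n)))
}
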