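# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a finite numeric scalar", name)
  if (x < lower || x > upper)
    stopf("`%s` = %g is outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}

# symmetrize (guards tiny asymmetries from floating point)
symm <- function(M) (M + t(M)) / 2

log2det <- function(M) {
  ld <- determinant(M, logarithm = TRUE)
  if (ld$sign <= 0) return(NA_real_)
  as.numeric(ld$modulus) / log(2)
}
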