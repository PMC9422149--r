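`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a locally seeded RNG, restoring the caller's RNG state
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# error function, as used by the erf-recursion kernel coefficients
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
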