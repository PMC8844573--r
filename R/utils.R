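# Internal helpers.

# Run expr under a private RNG stream: seeds the generator, restores whatever
# global .Random.seed existed before. Every simulator routes its randomness
# through this so identical spec + seed gives bit-identical output and no
# call disturbs the caller's RNG state.
withSeed <- function(seed, expr) {
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
  expr
}

# sd/sqrt(n); NA for n < 2 (undefined-marked, never 0)
semOf <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2L) return(NA_real_)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
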