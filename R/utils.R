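# internal helpers shared across modules

# Evaluate expr with a temporarily seeded RNG, restoring global state after.
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# sub-seed derivation; keeps results independent of call ordering and
# below .Machine$integer.max
deriveSeed <- function(seed, index, stream = 0L) {
  (as.numeric(seed) * 69069 + index * 10007 + stream * 97) %% 2147483647
}

isBinaryMask <- function(x) {
  is.numeric(x) && all(x == 0 | x == 1)
}

stopifNotBinary <- function(x, what = "mask") {
  if (!isBinaryMask(x)) stop(what, " must contain only values in {0, 1}")
  invisible(TRUE)
}

clip01 <- function(x, eps) pmin(pmax(x, eps), 1 - eps)
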