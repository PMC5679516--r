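# Derive a reproducible sub-seed for a named stage from one master seed.
# Keeps results < 2^31 so set.seed() always accepts them.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_whole <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
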