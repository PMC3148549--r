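## Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' Mixes a master seed with a stream index through a linear-congruential step
#' modulo 2^31 - 1, so that independent pipeline stages (chunks, iterations,
#' stages of a cohort simulation) each get their own deterministic RNG stream
#' and results do not depend on how work is split across calls.
#'
#' @param seed Integer master seed.
#' @param index Non-negative integer stream index.
#' @return A single integer seed in [0, 2^31 - 2].
#' @keywords internal
deriveSeed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(index), length(index) == 1L, is.finite(index))
  m <- 2147483647
  s <- (abs(seed) %% m) * 69069 + (abs(index) %% m) * 1013904223
  as.integer(s %% m)
}

## Evaluate `expr` under a given seed without disturbing the caller's RNG
## state. A NULL seed evaluates expr as-is.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

## Canonical chromosome sort key: autosomes 1..22 then X.
chromOrder <- function(chrom) {
  match(as.character(chrom), c(as.character(1:22), "X"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
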