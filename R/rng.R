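#' Derive a substream seed from a master seed and a stream name
#'
#' Every stochastic step in the pipeline draws from its own named substream of
#' the single run seed, so changing one stage's draws never perturbs another's.
#' The fold is a simple 31-based string hash combined with the master seed,
#' reduced modulo 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed master integer seed.
#' @param name substream name, e.g. `"phantom"`, `"array_layout"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  m <- 2^31 - 1
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 31 + cc) %% m
  as.integer((as.numeric(seed) %% m * 48271 + h) %% m)
}

#' Isolated random-number stream
#'
#' A small RNG handle isolated from the global `.Random.seed`: each draw swaps
#' its private state in and out, so package code never perturbs (or depends
#' on) the caller's RNG.
#'
#' @param seed integer seed (e.g. from [substream_seed()]).
#' @return List of draw functions `runif(n, min, max)`, `rnorm(n, mean, sd)`,
#'   `sample_int(n, size)` sharing one private stream.
#' @export
local_rng <- function(seed) {
  state <- NULL
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, globalenv())
    val <- expr
    state <<- get(".Random.seed", globalenv())
    val
  }
  list(
    runif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    sample_int = function(n, size) with_state(sample.int(n, size))
  )
}
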