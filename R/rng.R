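# Self-contained seeded RNG stream.
#
# All stochastic code in the package draws from one of these streams so that
# simulator output is reproducible from its seed alone and never perturbs
# (or is perturbed by) the caller's global RNG state.

#' Create an isolated seeded random stream
#'
#' Returns a list of draw functions (`norm`, `unif`, `int`, `bern`) backed
#' by a private Mersenne-Twister state. Draws advance only this stream;
#' the global `.Random.seed` is left untouched.
#'
#' @param seed Integer seed.
#' @return A list of draw functions plus `spawn(offset)` to derive a child
#'   stream deterministically.
#' @export
local_rng <- function(seed) {
  seed <- as.integer(seed)
  env <- new.env(parent = emptyenv())
  swap_in <- function() {
    env$outer <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed, kind = "Mersenne-Twister")
    else assign(".Random.seed", env$state, globalenv())
  }
  swap_out <- function() {
    env$state <- get(".Random.seed", globalenv())
    if (is.null(env$outer)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", env$outer, globalenv())
  }
  draw <- function(f, ...) {
    swap_in(); on.exit(swap_out())
    f(...)
  }
  list(
    norm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    unif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    int = function(n, max) draw(function(n, max) sample.int(max, n, replace = TRUE), n, max),
    bern = function(n, p) draw(function(n, p) stats::runif(n) < p, n, p),
    spawn = function(offset) local_rng((seed * 48271L + as.integer(offset)) %% 2147483562L + 1L)
  )
}
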