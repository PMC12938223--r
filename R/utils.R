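#' @import methods
#' @importFrom stats fft rnorm runif sd wilcox.test
#' @importFrom utils write.csv head
NULL

MAX_SEED <- 2147483629

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, evaluates `expr`, and restores the
#' previous state, so seeded internals never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% MAX_SEED))
  expr
}

# Deterministically fold integer tags into a derived seed (< 2^31). All
# products stay below 2^53 so double arithmetic is exact.
deriveSeed <- function(seed, ...) {
  tags <- c(...)
  h <- as.numeric(seed) %% MAX_SEED
  for (t in tags) h <- (h * 7919 + as.numeric(t) + 1) %% MAX_SEED
  as.integer(h)
}

# A named random stream: an independent Mersenne-Twister state advanced in
# isolation from the global RNG and from other streams. Batch shuffling and
# random target positions draw from separate streams so ablation arms see
# identical shuffles.
rngStream <- function(seed, id = 0L) {
  env <- new.env(parent = emptyenv())
  withSeed(deriveSeed(seed, 104729, id), {
    env$state <- get(".Random.seed", envir = globalenv())
  })
  class(env) <- "rngStream"
  env
}

# Evaluate expr using (and advancing) the stream's RNG state.
streamEval <- function(stream, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  expr
}

streamSeed <- function(stream) {
  streamEval(stream, sample.int(MAX_SEED, 1L))
}

stopifnotFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(what, " must contain only finite values", call. = FALSE)
  invisible(TRUE)
}

# Polynomial rolling hash over a character representation; used only to
# stamp the run manifest with a config fingerprint.
configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
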