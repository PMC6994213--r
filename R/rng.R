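#' Derive a deterministic child seed from a run seed and a stream name
#'
#' All randomness in the package flows from a single integer run seed through
#' named child streams (goal sampling, bootstrap, environment noise,
#' optimizer), so that every run is bit-reproducible. Child seeds are obtained
#' by a small polynomial hash of the stream name mixed with the parent seed;
#' the result always fits in a 32-bit signed integer.
#'
#' @param seed parent integer seed
#' @param name character stream name, e.g. `"goal"` or `"env"`
#' @param offset optional integer offset (e.g. an experiment index) mixed in
#'   after the name hash
#' @return an integer seed in `[0, 2^31)`
#' @export
child_seed <- function(seed, name, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- abs(as.double(seed)) %% 2147483647
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% 2147483629
  }
  h <- (h + abs(as.double(offset))) %% 2147483629
  as.integer(h)
}

#' Create an independent, named random stream
#'
#' A stream owns its own Mersenne-Twister state; drawing from one stream never
#' perturbs the global RNG state or any other stream.
#'
#' @param seed integer seed for this stream
#' @return an object of class `rng_stream`
#' @export
rng_stream <- function(seed) {
  stream <- new.env(parent = emptyenv())
  stream$seed <- as.integer(seed)
  stream$state <- NULL
  class(stream) <- "rng_stream"
  stream
}

# Evaluate `expr` under the stream's RNG state, capturing the advanced state
# afterwards and restoring whatever global state existed before.
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  genv <- globalenv()
  had_old <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_old) get(".Random.seed", envir = genv) else NULL
  if (is.null(stream$state)) {
    set.seed(stream$seed)
  } else {
    assign(".Random.seed", stream$state, envir = genv)
  }
  on.exit({
    stream$state <- get(".Random.seed", envir = genv)
    if (had_old) {
      assign(".Random.seed", old, envir = genv)
    } else {
      rm(".Random.seed", envir = genv)
    }
  })
  expr
}

#' Draw from a random stream
#'
#' @param stream an [rng_stream()]
#' @param fun a base random generator such as [stats::runif]
#' @param ... arguments passed to `fun`
#' @return the draw, with the stream state advanced
#' @export
stream_draw <- function(stream, fun, ...) {
  with_stream(stream, fun(...))
}
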