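#' Seedable random streams
#'
#' Every stochastic branch in the package consumes an explicit, named random
#' stream rather than the global generator, so that paired experiment arms
#' (e.g. an intact and a lesioned agent) can share environment randomness
#' while agent-internal randomness stays isolated. A stream is a small
#' environment holding its own generator state; drawing from a stream never
#' disturbs the global `.Random.seed`.
#'
#' @param seed integer seed for the stream.
#' @return an object of class `rng_stream`.
#' @examples
#' s <- rng_stream(42)
#' stream_runif(s, 3)
#' @export
rng_stream <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  e <- new.env(parent = emptyenv())
  old <- .global_seed_get()
  set.seed(as.integer(seed %% .Machine$integer.max))
  e$state <- get(".Random.seed", envir = globalenv())
  .global_seed_set(old)
  class(e) <- "rng_stream"
  e
}

.global_seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

.global_seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate an expression under a stream's generator state
#'
#' Swaps the stream's state into the global generator, evaluates `expr`,
#' captures the advanced state back into the stream, and restores whatever
#' global state existed before.
#'
#' @param stream an [rng_stream()].
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- .global_seed_get()
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    .global_seed_set(old)
  })
  expr
}

#' @rdname with_stream
#' @param n,min,max as in [stats::runif()].
#' @export
stream_runif <- function(stream, n, min = 0, max = 1)
  with_stream(stream, stats::runif(n, min, max))

#' @rdname with_stream
#' @param x,size,replace,prob as in [base::sample()].
#' @export
stream_sample <- function(stream, x, size = 1, replace = FALSE, prob = NULL)
  with_stream(stream, sample(x, size, replace = replace, prob = prob))

#' Derive named child streams from a master seed
#'
#' Fans a master seed out into independent named substreams (e.g. `setup`,
#' `agent1`, `agent2`, `game`), so that two runs differing only in one
#' component still share all other randomness.
#'
#' @param seed master integer seed.
#' @param names character vector of substream names.
#' @return named list of [rng_stream()] objects.
#' @export
stream_split <- function(seed, names) {
  root <- rng_stream(seed)
  seeds <- with_stream(root, sample.int(.Machine$integer.max, length(names)))
  out <- lapply(seeds, rng_stream)
  names(out) <- names
  out
}
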