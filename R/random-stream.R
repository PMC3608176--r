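#' Reproducible random streams
#'
#' A \code{RandomStream} is an independent, resumable source of randomness:
#' the same seed always yields the same draw sequence, and drawing from one
#' stream never disturbs the global RNG state or any other stream.  All
#' stochastic operations in the package (move sampling, start selection,
#' perturbation fixtures) take a stream argument, which is what makes whole
#' framework runs bit-reproducible from a single master seed.
#'
#' @param seed integer seed.
#' @return an object of class \code{RandomStream}.
#' @examples
#' rs <- randomStream(42)
#' streamEval(rs, runif(2))
#' @export
randomStream <- function(seed) {
  seed <- as.integer(seed)
  if (length(seed) != 1L || is.na(seed)) stop("seed must be a single integer")
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", envir = globalenv())
  env$seed <- seed
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(env) <- "RandomStream"
  env
}

#' Evaluate an expression under a stream's RNG state
#'
#' Swaps the stream's saved RNG state in, evaluates \code{expr}, saves the
#' advanced state back into the stream, and restores the global RNG state.
#'
#' @param stream a \code{RandomStream}.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
streamEval <- function(stream, expr) {
  stopifnot(inherits(stream, "RandomStream"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  value <- expr
  stream$state <- get(".Random.seed", envir = globalenv())
  value
}

# Derive a child seed (below 2^31) from a stream, for sub-streams.
streamChildSeed <- function(stream) {
  streamEval(stream, sample.int(.Machine$integer.max, 1L))
}
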