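# Independent per-device random substreams.
#
# Every simulated device draws noise from its own stream, seeded from the
# root seed and the device's role name. Adding or removing a device from a
# setup therefore never perturbs the noise seen by any other device, and a
# fixed root seed gives bit-identical sensor output across runs.

#' Derive a child seed from a root seed and a role name
#'
#' Deterministic polynomial hash of the role string folded into the root
#' seed, reduced modulo 2^31 - 1 so the result is always a valid R seed.
#'
#' @param root_seed Non-negative integer root seed.
#' @param role Character scalar, e.g. the device's role name.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root_seed, role) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, root_seed >= 0,
            is.character(role), length(role) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(root_seed) %% m
  for (ch in utf8ToInt(role)) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

# Save the global RNG state (or NULL if none exists yet).
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.restore_seed <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Create an independent random-number stream
#'
#' The stream captures an RNG state initialized from `seed` and evolves it
#' only through [rng_draw()], leaving the global RNG untouched.
#'
#' @param seed Integer seed for the stream.
#' @return An object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  old <- .save_seed()
  set.seed(seed)
  st <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  .restore_seed(old)
  env <- new.env(parent = emptyenv())
  env$state <- st
  class(env) <- "rng_stream"
  env
}

#' Evaluate an expression using a stream's RNG state
#'
#' Swaps the stream's state into the global RNG, evaluates `expr`, saves the
#' advanced state back into the stream, and restores the caller's RNG.
#'
#' @param stream An [rng_stream()] object.
#' @param expr Expression drawing random numbers.
#' @return The value of `expr`.
#' @export
rng_draw <- function(stream, expr) {
  old <- .save_seed()
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    .restore_seed(old)
  })
  expr
}
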