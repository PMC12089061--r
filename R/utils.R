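#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded package internals never perturb the user's random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Population (ddof 0) standard deviation
#'
#' The package-wide convention for noise estimates.
#' @keywords internal
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Derive a stage seed from a global seed
#'
#' Deterministic fan-out used by [run_experiment()] and the command-line
#' tools: stage k of global seed s gets `(s * 7919 + k * 104729) mod 2^31`.
#' @param seed global integer seed
#' @param stage nonnegative integer stage index
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 7919 + as.double(stage) * 104729) %% 2147483647)
}

stop_nn <- function(class, message, ...) {
  stop(structure(
    class = c(class, "nativenoise_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}
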