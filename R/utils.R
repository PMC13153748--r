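`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a deterministic RNG substream
#'
#' Derives an independent RNG state from `(seed, index)` so that per-unit
#' randomness (e.g. one patient's visit history) does not depend on how many
#' other units are simulated. The caller's RNG state is restored on exit.
#'
#' @param seed integer master seed.
#' @param index integer substream index (may be negative).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_substream <- function(seed, index, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  s <- (abs(as.numeric(seed)) %% 1000003) * 2011 + as.numeric(index) * 7
  set.seed(as.integer(s %% 2147483647))
  expr
}

stop_shareduse <- function(..., class) {
  stop(structure(
    class = c(class, "shareduse_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
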