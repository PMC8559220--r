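#' Spawn independent per-stage child seeds from one global seed
#'
#' Each pipeline stage draws its randomness from its own child seed so that a
#' stage can be replayed in isolation without consuming the random stream of
#' any other stage.
#'
#' @param seed Integer global seed.
#' @param stages Character vector of stage names.
#' @return Named integer vector of child seeds, one per stage.
#' @export
spawn_seeds <- function(seed, stages) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stages))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  out <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(out) <- stages
  out
}

#' Stable content hash of an R object
#'
#' @param x Any serializable R object.
#' @return Character scalar hash.
#' @export
object_hash <- function(x) rlang::hash(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

## assert helper with sprintf-style message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

## z-score that maps zero-variance input to zeros instead of NaN
safe_scale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x > 0
}
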