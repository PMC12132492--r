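#' Run code with a temporary RNG state
#'
#' Seeds the R RNG, evaluates `code`, and restores the previous
#' `.Random.seed`, so seeded routines do not perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a per-stage seed from a global seed
#'
#' Fixed integer derivation so each pipeline stage is independently
#' reproducible from one global seed. Result stays below 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character) or integer offset.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  offset <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 10000L
  } else {
    as.integer(stage)
  }
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
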